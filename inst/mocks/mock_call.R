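#!/usr/bin/env Rscript
# Mock per-region variant caller: naive pileup over one region shard.
suppressMessages(library(regionpipe))
mock_call_cli(commandArgs(trailingOnly = TRUE))
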