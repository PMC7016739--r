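#!/usr/bin/env Rscript
# Mock sequential index-rebuild stage between the two mapping passes.
suppressMessages(library(regionpipe))
mock_index_rebuild_cli(commandArgs(trailingOnly = TRUE))
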