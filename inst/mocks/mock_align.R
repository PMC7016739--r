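#!/usr/bin/env Rscript
# Mock aligner stage: places reads at the origin encoded in their names.
suppressMessages(library(regionpipe))
mock_align_cli(commandArgs(trailingOnly = TRUE))
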