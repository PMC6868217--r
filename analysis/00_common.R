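# Shared plumbing for the analysis drivers: output location, seed
# handling, and config serialization so every artifact is reproducible
# from the JSON written next to it.

suppressMessages(library(mtlattice))
suppressMessages(library(jsonlite))

analysis_args <- function(default_seed = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  seed <- default_seed
  i <- 1
  while (i <= length(args)) {
    if (args[i] == "--seed") { seed <- as.integer(args[i + 1]); i <- i + 2 }
    else stop("unknown argument: ", args[i])
  }
  list(seed = seed)
}

out_dir <- function(name) {
  d <- file.path("results", name)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_config <- function(dir, config) {
  write_json(config, file.path(dir, "config.json"), auto_unbox = TRUE,
             digits = NA)
}
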