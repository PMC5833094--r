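# Shared configuration of the analysis workflow.  Every numbered script
# sources this file and regenerates the same deterministic simulated study
# (cheap at desk scale), so the scripts can be run independently or in
# order.  Small summary tables are written under results/analysis/.

suppressMessages(library(episcreen))

ANALYSIS_SEED <- 20260927L %% 100000L   # fixed study seed, < 2^31

study_config <- function() {
  sim_config(seed = ANALYSIS_SEED)      # defaults = the emulated design
}

results_dir <- function() {
  d <- file.path("results", "analysis")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_table <- function(df, name) {
  path <- file.path(results_dir(), name)
  data.table::fwrite(df, path, sep = "\t")
  cat("  wrote", path, "\n")
}
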