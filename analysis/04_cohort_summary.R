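#!/usr/bin/env Rscript

# Stage 4: cohort-level evolutionary summary. Re-runs the pipeline over
# the written inputs (cheap, and keeps this stage self-contained), then
# tabulates per-patient dissemination calls and cohort medians with
# bootstrap 95% confidence intervals: clones per cancer, fraction of
# clones that disseminated, mutation time of the first disseminated clone,
# and the dissemination interval of monophyletic polyclonal cancers.

suppressPackageStartupMessages(library(cloneseed))

in_dir <- "results/cohort_inputs"
params <- pipeline_params(seed = 1L)
dirs <- list.dirs(in_dir, recursive = FALSE)

patients <- lapply(dirs, function(d) list(
  mutations = read_tsv_table(file.path(d, "mutations.tsv")),
  segments = read_tsv_table(file.path(d, "segments.tsv")),
  samples = read_tsv_table(file.path(d, "samples.tsv")),
  patient_id = basename(d)))

res <- run_cohort(patients, params = params, out_dir = "results/cohort")

cat("cohort table (first rows):\n")
print(utils::head(res$table))
cat("\ncohort summary (median and bootstrap 95% CI):\n")
print(res$summary, digits = 3)
cat("\nwrote results/cohort/cohort_table.tsv and cohort_summary.tsv\n")
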