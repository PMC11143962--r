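#!/usr/bin/env Rscript

# Stage 1: generate the synthetic multi-site cohort that stands in for the
# (non-public) patient sequencing data: 23 deeply sequenced cancers, each
# sampled at 2-3 anatomical sites with known clone trees, dissemination
# modes and seeding directions. Inputs for the later stages are written as
# plain TSV plus a JSON ground-truth file per patient.

suppressPackageStartupMessages(library(cloneseed))

seed <- 1L
out_dir <- "results/cohort_inputs"

patients <- simulate_cohort(23L, seed = seed, noise = "binomial")
for (p in patients)
  write_patient(p, file.path(out_dir, p$patient_id))

modes <- vapply(patients, function(p) p$truth$mode, character(1))
origin <- vapply(patients, function(p) p$truth$origin_model, character(1))
cat("simulated", length(patients), "patients into", out_dir, "\n")
cat("dissemination modes generated:\n")
print(table(modes))
cat("polyclonal-origin patients:", sum(origin == "polyclonal_origin"), "\n")
cat("samples per patient:",
    paste(range(vapply(patients, function(p) nrow(p$samples), integer(1))),
          collapse = "-"), "\n")
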