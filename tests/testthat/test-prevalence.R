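test_that("CCF formula inverts the purity/copy-number dilution", {
  expect_equal(compute_ccf(0.5, 1, 2, 1), 1.0)
  expect_equal(compute_ccf(0.25, 0.5, 2, 1), 1.0)
  # vaf * (p*cn + (1-p)*2) / (p*m) = 0.4 * (2.4 + 0.4) / 1.6 = 0.7
  expect_equal(compute_ccf(0.4, 0.8, 3, 2), 0.7)
  expect_equal(compute_ccf(0.9, 0.5, 2, 1, cap = 1.5), 1.5)  # capped
  expect_error(compute_ccf(0.5, 0, 2, 1), "purity")
})

test_that("CCF is the exact inverse of the read-emission expectation", {
  set.seed(9)
  for (i in 1:50) {
    purity <- runif(1, 0.3, 1)
    prev <- runif(1)
    cn <- sample(1:5, 1)
    m <- sample(seq_len(max(1, cn - 1)), 1)
    vaf <- expected_vaf(purity, cn, m, prev)
    expect_equal(compute_ccf(vaf, purity, cn, m), prev, tolerance = 1e-12)
  }
})

test_that("multiplicity picks the nearest expectation, ties to smaller m", {
  expect_equal(estimate_multiplicity(2 / 3, 1, 3, 1), 2L)  # E[vaf|m=2] = 2/3
  expect_equal(estimate_multiplicity(1 / 3, 1, 3, 1), 1L)
  expect_equal(estimate_multiplicity(0.5, 1, 2, 1), 1L)    # major count 1
  # equidistant between m=1 (1/4) and m=2 (1/2) on a 4:2 segment: smaller m
  expect_equal(estimate_multiplicity(0.375, 1, 4, 2, band = 0.2), 1L)
  # far from every expectation: falls back to 1
  expect_equal(estimate_multiplicity(0.05, 1, 4, 0, band = 0.02), 1L)
})

test_that("aberration calls are median-centered and LOH needs minor 0", {
  segs <- data.frame(
    chrom = paste0("chr", 1:5), start = 1, end = c(10, 10, 10, 10, 1000),
    cn_total = c(4, 2, 1, 2, 2), cn_minor = c(1, 0, 0, 1, 1),
    sample_id = "s1")
  called <- call_aberrations(segs)
  expect_equal(called$call, c("gain", "neutral", "loss", "neutral", "neutral"))
  expect_equal(called$sample_median, rep(2, 5))
  expect_equal(call_loh(segs$cn_minor), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_true(call_loh(0.005))   # rounding tolerance
})

test_that("timing states need a gain for the early/late distinction", {
  expect_equal(assign_timing(1.0, 2, 2), "clonal_early")
  expect_equal(assign_timing(1.0, 1, 2), "clonal_late")
  expect_equal(assign_timing(1.0, 1, 1), "clonal_NA")
  expect_equal(assign_timing(0.4, 1, 1), "subclonal")
  # a 2:1 or 1:1 segment (major allele count 1) can never yield early/late
  for (ccf in c(0.95, 1.0, 1.4))
    expect_false(assign_timing(ccf, 1, 1) %in% c("clonal_early", "clonal_late"))
})

test_that("patient clonality requires clonal somewhere and presence everywhere", {
  mk <- function(states, present) {
    data.frame(mutation_id = "m", sample_id = paste0("s", seq_along(states)),
               timing_state = states, present = present)
  }
  s5 <- paste0("s", 1:5)
  # clonal in 1 of 5, present in all: clonal
  expect_equal(summarize_patient_clonality(
    mk(c("clonal_NA", rep("subclonal", 4)), rep(TRUE, 5)), s5)$patient_state,
    "clonal")
  # clonal in 1 of 5 but absent from one sample: subclonal
  expect_equal(summarize_patient_clonality(
    mk(c("clonal_NA", rep("subclonal", 4)), c(rep(TRUE, 4), FALSE)),
    s5)$patient_state, "subclonal")
  # subclonal everywhere, present everywhere: subclonal
  expect_equal(summarize_patient_clonality(
    mk(rep("subclonal", 5), rep(TRUE, 5)), s5)$patient_state, "subclonal")
})

test_that("patient clonality is invariant to sample order", {
  set.seed(4)
  states <- expand.grid(mutation_id = paste0("m", 1:6),
                        sample_id = paste0("s", 1:4), stringsAsFactors = FALSE)
  states$timing_state <- sample(c("clonal_NA", "clonal_early", "subclonal"),
                                nrow(states), TRUE)
  states$present <- sample(c(TRUE, FALSE), nrow(states), TRUE, prob = c(.8, .2))
  a <- summarize_patient_clonality(states)
  b <- summarize_patient_clonality(states[sample(nrow(states)), ])
  expect_equal(a, b[match(a$mutation_id, b$mutation_id), ],
               ignore_attr = TRUE)
})

test_that("gene tallies count a gene once per category per sample", {
  df <- data.frame(gene = c("TP53", "TP53", "TP53", "BRCA1"),
                   sample_id = c("s1", "s1", "s2", "s1"),
                   category = c("clonal", "clonal", "clonal", "subclonal"))
  tal <- tally_gene_clonality(df)
  expect_equal(tal$n_samples[tal$gene == "TP53"], 2)  # s1 deduplicated
})

test_that("segment lookup finds covering segments and flags no-calls", {
  segs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(1, 1000, 1), end = c(999, 2000, 500),
                     cn_total = c(2, 3, 4), cn_minor = c(1, 1, 0),
                     sample_id = "s1")
  muts <- data.frame(sample_id = "s1",
                     chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
                     pos = c(50, 1500, 100, 501, 10))
  cn <- lookup_segments(muts, segs)
  expect_equal(cn$cn_total, c(2, 3, 4, NA, NA))
  expect_equal(cn$cn_minor, c(1, 1, 0, NA, NA))
})
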