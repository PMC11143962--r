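test_that("config validation rejects impossible mode combinations", {
  expect_error(sim_config(mode = "polyphyletic_polyclonal", n_clones = 2,
                          n_disseminated = 2), "at least 3|n_clones")
  expect_error(sim_config(mode = "monoclonal", n_disseminated = 2),
               "n_disseminated")
  expect_error(sim_config(purity_range = c(0, 0.9)), "purity_range")
  expect_error(sim_config(n_disseminated = 99), "exceed")
})

test_that("a single-clone cancer yields one node with all mutations truncal", {
  cfg <- sim_config(n_clones = 1, mode = "monoclonal", n_disseminated = 1,
                    n_sites = 2, seed = 5)
  p <- simulate_patient(cfg)
  expect_equal(length(p$truth$tree$parent), 1L)
  expect_true(all(p$truth$mutation_clone == "C1"))
  expect_true(all(p$truth$tree$prevalence == 1))
})

test_that("polyphyletic trees contain disseminated clones in sibling branches", {
  cfg <- sim_config(mode = "polyphyletic_polyclonal", n_clones = 6,
                    n_disseminated = 2, n_sites = 3, seed = 7)
  tree <- simulate_clone_tree(cfg)
  d <- tree$disseminated
  expect_gte(length(d), 2)
  expect_false(ct_is_ancestor(tree, d[1], d[2]))
  expect_false(ct_is_ancestor(tree, d[2], d[1]))
})

test_that("private mutation counts follow the configured Poisson mean", {
  lambda <- 50
  totals <- vapply(1:300, function(i) {
    cfg <- sim_config(n_clones = 5, mutations_per_clone_mean = lambda,
                      seed = 100000 + i)
    sum(simulate_clone_tree(cfg)$n_private)
  }, numeric(1))
  # mean of 5-clone totals ~ Poisson(250); allow 3 standard errors
  se <- sqrt(5 * lambda / length(totals))
  expect_lt(abs(mean(totals) - 5 * lambda), 3 * se)
})

test_that("prevalences satisfy the sum rule exactly and root is fixed at 1", {
  for (seed in c(2, 21, 57)) {
    for (mode in c("monoclonal", "monophyletic_polyclonal",
                   "polyphyletic_polyclonal")) {
      cfg <- sim_config(mode = mode,
                        n_disseminated = if (mode == "monoclonal") 1 else 2,
                        n_sites = 3, seed = seed)
      tree <- assign_prevalences(simulate_clone_tree(cfg), cfg)
      expect_true(check_sum_rule(tree$parent, tree$prevalence, tolerance = 0))
      expect_true(all(tree$prevalence[ct_root(tree), ] == 1))
      # disseminated clones present at >= 2 sites, locals at exactly 1
      sp <- site_prevalence(tree$prevalence, tree$samples, max)
      nst <- rowSums(sp > 0)
      diss <- setdiff(tree$disseminated, ct_root(tree))
      expect_true(all(nst[diss] >= 2))
      locals <- setdiff(seq_along(tree$parent), c(ct_root(tree), diss))
      expect_true(all(nst[locals] == 1))
      # the configured origin site carries the smallest prevalence
      for (d in diss) {
        os <- tree$origin_site[d]
        expect_equal(unname(which.min(sp[d, ])), match(os, colnames(sp)))
      }
    }
  }
})

test_that("a fixed seed reproduces the patient byte for byte", {
  cfg <- sim_config(seed = 11)
  p1 <- simulate_patient(cfg)
  p2 <- simulate_patient(cfg)
  expect_identical(p1, p2)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  write_patient(p1, d1, vcf = TRUE)
  write_patient(p2, d2, vcf = TRUE)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
})

test_that("noise-free emitted VAFs back-transform exactly to the prevalences", {
  cfg <- sim_config(seed = 3, noise = "none", mode = "monophyletic_polyclonal",
                    n_disseminated = 2)
  p <- simulate_patient(cfg)
  m <- p$mutations
  purity <- p$samples$purity[match(m$sample_id, p$samples$sample_id)]
  ccf <- compute_ccf(m$vaf_expected, purity, 2, 1)
  truth_prev <- p$truth$tree$prevalence[
    cbind(p$truth$mutation_clone[m$mutation_id], m$sample_id)]
  expect_lt(max(abs(ccf - truth_prev)), 1e-9)
})

test_that("normal samples stay below the contamination filter by design", {
  cfg <- sim_config(seed = 8, noise = "binomial")
  p <- simulate_patient(cfg)
  n_vaf <- p$mutations$n_alt / p$mutations$n_depth
  expect_lt(stats::quantile(n_vaf, 0.999), 0.01)
})

test_that("gain chromosomes carry 3:1 segments and truncal multiplicity 2", {
  cfg <- sim_config(seed = 13, gain_chroms = "chr1", noise = "none")
  p <- simulate_patient(cfg)
  seg1 <- p$segments[p$segments$chrom == "chr1", ]
  expect_true(all(seg1$cn_total == 3))
  on1 <- grepl("^chr1:", names(p$truth$multiplicity))
  truncal <- p$truth$mutation_clone == "C1"
  expect_true(all(p$truth$multiplicity[on1 & truncal] == 2))
  expect_true(all(p$truth$multiplicity[!on1] == 1))
})

test_that("the cohort generator respects mode composition and sub-seeding", {
  pats <- simulate_cohort(8, seed = 4, noise = "none",
                          include_polyclonal_origin = TRUE)
  expect_length(pats, 8)
  om <- vapply(pats, function(p) p$truth$origin_model, character(1))
  expect_equal(sum(om == "polyclonal_origin"), 1L)
  pats2 <- simulate_cohort(8, seed = 4, noise = "none",
                           include_polyclonal_origin = TRUE)
  expect_identical(pats, pats2)
})
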