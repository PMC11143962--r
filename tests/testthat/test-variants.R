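test_that("somatic filter accepts and rejects the boundary cases", {
  calls <- data.frame(
    t_depth = c(20, 150, 14, 100, 150),
    t_alt   = c(2,  30,  7,  4,   20),
    n_depth = c(20, 120, 20, 100, 120),
    n_alt   = c(0,  5,   0,  0,   10))
  st <- somatic_filter_status(calls)
  expect_true(st[1])   # 10% tumor VAF, clean normal, adequate coverage
  expect_true(st[2])   # relaxed high-depth route: 20% vs 4.2%, ratio 4.8
  expect_false(st[3])  # tumor coverage below 15x
  expect_false(st[4])  # tumor VAF below 5%
  expect_false(st[5])  # normal VAF 8.3%: fails both routes
})

test_that("the relaxed route is a genuine alternative, not a replacement", {
  # passes relaxed only: normal VAF 2% kills the standard route
  call <- data.frame(t_depth = 200, t_alt = 40, n_depth = 200, n_alt = 4)
  expect_true(somatic_filter_status(call))
  # ratio just below 4x: relaxed route must refuse
  call2 <- data.frame(t_depth = 200, t_alt = 39, n_depth = 200, n_alt = 10)
  expect_false(somatic_filter_status(call2))
})

test_that("somatic filter agrees with the brute-force rule transcription", {
  grid <- expand.grid(t_depth = c(0, 10, 14, 15, 20, 99, 100, 150),
                      t_alt_frac = c(0, 0.04, 0.05, 0.1, 0.15, 0.3),
                      n_depth = c(0, 10, 15, 99, 100, 150),
                      n_alt = c(0, 1, 2, 5, 8))
  grid$t_alt <- floor(grid$t_alt_frac * grid$t_depth)
  grid$n_alt <- pmin(grid$n_alt, grid$n_depth)
  got <- somatic_filter_status(grid)
  want <- mapply(oracle_somatic_pass, grid$t_depth, grid$t_alt,
                 grid$n_depth, grid$n_alt)
  expect_equal(got, unname(want))
})

test_that("filters are idempotent and respect the mapping-quality gate", {
  set.seed(42)
  calls <- data.frame(
    t_depth = sample(0:300, 200, TRUE), n_depth = sample(0:300, 200, TRUE))
  calls$t_alt <- floor(runif(200) * calls$t_depth)
  calls$n_alt <- floor(runif(200) * 0.1 * calls$n_depth)
  once <- apply_somatic_filters(calls)
  expect_identical(apply_somatic_filters(once), once)
  calls$mapping_quality_ok <- FALSE
  expect_equal(nrow(apply_somatic_filters(calls)), 0)
})

test_that("pass/fail is monotone in tumor and normal alt counts", {
  base <- expand.grid(t_depth = c(20, 150), n_depth = c(20, 150))
  for (i in seq_len(nrow(base))) {
    td <- base$t_depth[i]; nd <- base$n_depth[i]
    for (na in 0:5) {
      status <- somatic_filter_status(
        data.frame(t_depth = td, t_alt = 0:td, n_depth = nd, n_alt = na))
      # raising t_alt can only turn a failing call into a passing one
      expect_true(all(diff(as.integer(status)) >= 0))
    }
    for (ta in c(2, 10, td)) {
      status <- somatic_filter_status(
        data.frame(t_depth = td, t_alt = ta, n_depth = nd, n_alt = 0:nd))
      # raising n_alt can only turn a passing call into a failing one
      expect_true(all(diff(as.integer(status)) <= 0))
    }
  }
})

test_that("germline filters apply coverage, read-count and VAF floors", {
  calls <- data.frame(depth = c(100, 9, 100, 10, 200),
                      alt   = c(5,   9, 4,   5,  9))
  kept <- apply_germline_filters(calls)
  expect_equal(kept$depth, c(100, 10))  # row 1 at the exact VAF boundary
  expect_equal(kept$alt, c(5, 5))
})

test_that("nonsilent classification follows the effect whitelist", {
  expect_true(all(classify_nonsilent(
    c("missense", "nonsense", "stoploss", "frameshift_indel", "splice_site"))))
  expect_false(any(classify_nonsilent(
    c("synonymous", "inframe_indel", "other"))))
  expect_error(classify_nonsilent(c("missense", NA)), "unannotated")
})

test_that("TMB is nonsilent count per megabase with the >12 threshold", {
  calls <- data.frame(
    sample_id = rep(c("a", "b", "c"), c(100, 1, 700)),
    effect = c(rep(c("missense", "synonymous"), c(55, 45)),
               "synonymous",
               rep(c("missense", "synonymous"), c(650, 50))))
  tmb <- compute_tmb(calls, target_megabases = 50)
  expect_equal(tmb$tmb, c(1.1, 0, 13))
  expect_equal(tmb$hypermutated, c(FALSE, FALSE, TRUE))
  # 12.0 exactly is not hypermutated (threshold is strict)
  tmb600 <- compute_tmb(data.frame(sample_id = "a",
                                   effect = rep("missense", 600)),
                        target_megabases = 50)
  expect_false(tmb600$hypermutated)
  expect_error(compute_tmb(calls, target_megabases = 0), "positive")
})
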