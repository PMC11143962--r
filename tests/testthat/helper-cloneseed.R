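# Shared fixtures and independent oracles for the test suite.

# A small hand-built clone tree: root C1 with chain C2 -> C3 and local C4.
toy_tree <- function() {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    site = c("ovary", "ovary", "omentum"),
    purity = c(0.7, 0.6, 0.8), stringsAsFactors = FALSE)
  prev <- rbind(
    C1 = c(1.0, 1.0, 1.0),
    C2 = c(0.8, 0.75, 0.6),
    C3 = c(0.5, 0.45, 0.3),
    C4 = c(0.2, 0.15, 0.0))
  colnames(prev) <- samples$sample_id
  muts <- list(C1 = paste0("a", 1:6), C2 = paste0("b", 1:4),
               C3 = paste0("c", 1:5), C4 = paste0("d", 1:3))
  clone_tree(c(NA, 1L, 2L, 1L), n_private = c(6L, 4L, 5L, 3L),
             mutations = muts, prevalence = prev, samples = samples)
}

# Literal, row-by-row transcription of the somatic filter rules, kept
# deliberately naive and independent of the vectorized implementation.
oracle_somatic_pass <- function(t_depth, t_alt, n_depth, n_alt) {
  t_vaf <- if (t_depth > 0) t_alt / t_depth else 0
  n_vaf <- if (n_depth > 0) n_alt / n_depth else 0
  standard <- (t_depth >= 15) && (n_depth >= 15) &&
    (t_vaf >= 0.05) && (n_vaf < 0.01)
  relaxed <- (t_vaf >= 0.15) && (t_depth >= 100) && (n_depth >= 100) &&
    (n_vaf <= 0.05) && (t_vaf >= 4 * n_vaf)
  standard || relaxed
}

# Brute-force enumeration oracle: every assignment of a parent to each
# non-root cluster, filtered for acyclicity and the per-sample sum rule.
oracle_enumerate <- function(prev, tolerance = 0.05, root_threshold = 0.9) {
  n <- nrow(prev)
  minp <- apply(prev, 1, min)
  stopifnot(any(minp >= root_threshold))
  cand <- which(minp >= root_threshold)
  root <- cand[which.max(rowMeans(prev)[cand])]
  nonroot <- setdiff(seq_len(n), root)
  if (!length(nonroot)) return(list(stats::setNames(NA_integer_, rownames(prev))))
  choices <- rep(list(seq_len(n)), length(nonroot))
  grid <- as.matrix(expand.grid(choices))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    parent <- rep(NA_integer_, n)
    parent[nonroot] <- grid[g, ]
    if (any(grid[g, ] == nonroot)) next  # self-parenting
    # acyclicity: walk each node to the root
    ok <- TRUE
    for (i in seq_len(n)) {
      j <- i; steps <- 0L
      while (!is.na(parent[j])) {
        j <- parent[j]; steps <- steps + 1L
        if (steps > n) { ok <- FALSE; break }
      }
      if (!ok || j != root) { ok <- FALSE; break }
    }
    if (!ok) next
    # sum rule per node per sample
    for (p in seq_len(n)) {
      kids <- which(!is.na(parent) & parent == p)
      if (!length(kids)) next
      for (s in seq_len(ncol(prev))) {
        if (sum(prev[kids, s]) > prev[p, s] + tolerance) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- stats::setNames(parent, rownames(prev))
  }
  out
}

# Canonical string form of a parent vector, for set comparisons of trees.
tree_key <- function(parent) paste(ifelse(is.na(parent), 0L, parent), collapse = ",")

# Map a truth clone to the fitted clone with the largest Jaccard overlap
# of mutation sets.
match_clone <- function(truth_tree, fitted_tree, clone) {
  tm <- truth_tree$mutations[[clone]]
  ov <- vapply(fitted_tree$mutations, function(fm)
    length(intersect(tm, fm)) / length(union(tm, fm)), numeric(1))
  which.max(ov)
}

# Random prevalence matrix with a guaranteed root cluster; children drawn
# low enough that a handful of valid topologies usually exist.
random_prevalence <- function(n_clusters, n_samples, seed) {
  set.seed(seed)
  prev <- rbind(
    matrix(stats::runif(n_samples, 0.92, 1), nrow = 1),
    matrix(stats::runif((n_clusters - 1) * n_samples, 0, 0.75),
           nrow = n_clusters - 1))
  rownames(prev) <- paste0("K", seq_len(n_clusters))
  colnames(prev) <- paste0("s", seq_len(n_samples))
  prev
}
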