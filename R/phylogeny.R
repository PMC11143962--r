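#' Enumerate clone trees consistent with cluster prevalences
#'
#' Returns every rooted tree over the clusters in which, within tolerance,
#' (i) each parent's prevalence is at least each child's in every sample
#' (clonal ordering) and (ii) the prevalences of each node's children sum to
#' at most the node's own prevalence in every sample (the sum / pigeonhole
#' rule). The root must be a cluster with prevalence of approximately 1 in
#' all samples. Enumeration is exhaustive via depth-first assignment of
#' parents with sum-rule pruning; the recursion is cheap up to the clone
#' numbers seen in deeply sequenced cancers (<= 9).
#'
#' @param prevalence clusters x samples matrix of prevalences in `[0, 1]`.
#' @param tolerance slack, in prevalence units, on both constraint families.
#' @param root_threshold minimum prevalence in every sample for a cluster
#'   to qualify as the root (initial clone).
#' @param max_trees cap on the number of trees returned (with a warning);
#'   degenerate inputs with many near-zero clusters can otherwise explode.
#' @return list of parent vectors (`NA` at the root, clone ids as names).
#'   Errors with class `cloneseed_no_root` when no cluster qualifies as
#'   root, naming the closest candidate.
#' @export
enumerate_trees <- function(prevalence, tolerance = 0.05,
                            root_threshold = 0.9, max_trees = 20000L) {
  prev <- as.matrix(prevalence)
  n <- nrow(prev)
  if (is.null(rownames(prev))) rownames(prev) <- as.character(seq_len(n))
  minprev <- apply(prev, 1, min)
  root_cand <- which(minprev >= root_threshold)
  if (!length(root_cand)) {
    closest <- rownames(prev)[which.max(minprev)]
    stop(structure(class = c("cloneseed_no_root", "error", "condition"),
                   list(message = paste0(
                     "no cluster qualifies as the initial (root) clone; ",
                     "closest candidate: ", closest,
                     " (min prevalence ", round(max(minprev), 3), ")"),
                     call = sys.call(-1), closest = closest)))
  }
  root <- root_cand[which.max(rowMeans(prev)[root_cand])]
  if (n == 1L)
    return(list(stats::setNames(NA_integer_, rownames(prev))))

  ## candidate parents: p dominates c in every sample (within tolerance)
  allowed <- vector("list", n)
  for (ci in seq_len(n)) {
    if (ci == root) next
    allowed[[ci]] <- setdiff(
      which(apply(prev >= matrix(prev[ci, ], n, ncol(prev), byrow = TRUE) -
                    tolerance, 1, all)), ci)
  }
  ## assign high-prevalence clones first: their sums constrain the rest
  ord <- setdiff(order(-rowMeans(prev)), root)

  parent <- rep(NA_integer_, n)
  childsum <- matrix(0, n, ncol(prev))
  trees <- list()
  capped <- FALSE
  recurse <- function(k) {
    if (capped) return()
    if (k > length(ord)) {
      if (is_acyclic(parent, root)) {
        trees[[length(trees) + 1L]] <<- stats::setNames(parent, rownames(prev))
        if (length(trees) >= max_trees) capped <<- TRUE
      }
      return()
    }
    ci <- ord[k]
    for (p in allowed[[ci]]) {
      ns <- childsum[p, ] + prev[ci, ]
      if (all(ns <= prev[p, ] + tolerance)) {
        parent[ci] <<- p
        childsum[p, ] <<- ns
        recurse(k + 1L)
        childsum[p, ] <<- ns - prev[ci, ]
        parent[ci] <<- NA_integer_
      }
    }
  }
  recurse(1L)
  if (capped) warning("tree enumeration capped at ", max_trees, " trees")
  trees
}

is_acyclic <- function(parent, root) {
  n <- length(parent)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(parent[j])) {
      j <- parent[j]
      steps <- steps + 1L
      if (steps > n) return(FALSE)
    }
    if (j != root) return(FALSE)
  }
  TRUE
}

#' Select the most parsimonious clone tree
#'
#' Ranks candidate trees by (1) fewer branching nodes (linear over branched
#' evolution), (2) fewer implied disseminated clones (dissemination of a
#' single clone over multiple), and (3) a deterministic lexicographic
#' tie-break on the sorted parent map. Returns the top-ranked tree together
#' with the full ranked list.
#'
#' @param trees list of parent vectors from [enumerate_trees()].
#' @param prevalence clusters x samples prevalence matrix.
#' @param samples sample metadata (`sample_id`, `site`).
#' @param presence_threshold prevalence above which a clone counts as
#'   present at a site (used to count implied disseminated clones).
#' @return list with `best` (parent vector), `ranking` (ordered list of
#'   all trees) and `scores` (data.frame of ranking criteria).
#' @export
select_model <- function(trees, prevalence, samples,
                         presence_threshold = 0.02) {
  if (!length(trees)) stop("empty tree set: enumeration failed upstream")
  branching <- vapply(trees, ct_branching_count, integer(1))
  ndiss <- vapply(trees, function(par) {
    tr <- structure(list(parent = par, n_private = rep(1L, length(par)),
                         prevalence = prevalence, samples = samples),
                    class = "clone_tree")
    length(designate_clones(tr, presence_threshold)$disseminated)
  }, integer(1))
  key <- vapply(trees, function(p) paste(ifelse(is.na(p), 0L, p),
                                         collapse = ","), character(1))
  o <- order(branching, ndiss, key)
  list(best = trees[[o[1]]], ranking = trees[o],
       scores = data.frame(branching = branching[o], n_disseminated = ndiss[o],
                           key = key[o], stringsAsFactors = FALSE))
}

#' Relative developmental time of each clone in the model
#'
#' The proportion of the cancer's modeled mutations acquired by the time
#' each clone arose: the clone's cumulative (root-lineage) mutation count
#' divided by the total number of mutations in the model.
#'
#' @param tree a `clone_tree` with `n_private` counts.
#' @return numeric vector in `[0, 1]` named by clone.
#' @export
relative_clone_time <- function(tree) {
  ct_cumulative_mutations(tree) / sum(tree$n_private)
}
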