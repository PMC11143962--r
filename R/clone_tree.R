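#' Clone tree container
#'
#' A `clone_tree` is the central data structure of the package: a rooted tree
#' of tumor clones, each carrying a set of private somatic mutations and a
#' cellular-prevalence vector across the sequenced samples. Both the
#' synthetic-truth trees produced by [simulate_patient()] and the fitted
#' models produced by [run_patient()] use this class.
#'
#' @param parent integer vector, one entry per clone; `NA` marks the root,
#'   otherwise the index of the parent clone. Names are clone ids.
#' @param n_private integer vector of private (newly acquired) mutation
#'   counts per clone.
#' @param mutations optional list of character vectors: the private mutation
#'   keys of each clone.
#' @param prevalence optional numeric matrix (clones x samples) of cellular
#'   prevalences in `[0, 1]`.
#' @param samples optional data.frame with columns `sample_id`, `site`,
#'   `purity` describing the sequenced samples (columns of `prevalence`).
#' @return an object of class `clone_tree`.
#' @export
clone_tree <- function(parent, n_private, mutations = NULL,
                       prevalence = NULL, samples = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) stop("a clone tree needs at least one clone")
  if (sum(is.na(parent)) != 1L) stop("exactly one root (parent = NA) required")
  if (is.null(names(parent))) names(parent) <- paste0("C", seq_len(n))
  if (length(n_private) != n) stop("n_private must have one entry per clone")
  if (!is.null(mutations) && length(mutations) != n)
    stop("mutations must have one entry per clone")
  if (!is.null(prevalence)) {
    prevalence <- as.matrix(prevalence)
    if (nrow(prevalence) != n) stop("prevalence must have one row per clone")
    rownames(prevalence) <- names(parent)
  }
  obj <- structure(
    list(parent = parent, n_private = as.integer(n_private),
         mutations = mutations, prevalence = prevalence, samples = samples),
    class = "clone_tree")
  ct_validate(obj)
  obj
}

ct_validate <- function(tree) {
  n <- length(tree$parent)
  root <- ct_root(tree)
  # walk every node to the root; a cycle never reaches it
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(tree$parent[j])) {
      if (seen[j]) stop("cycle detected in clone tree")
      seen[j] <- TRUE
      j <- tree$parent[j]
    }
    if (j != root) stop("node ", i, " does not descend from the root")
  }
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  n <- length(x$parent)
  cat("clone_tree with", n, "clone(s),",
      sum(x$n_private), "mutations\n")
  root <- ct_root(x)
  cat("  root:", names(x$parent)[root], "\n")
  if (!is.null(x$prevalence))
    cat("  samples:", paste(colnames(x$prevalence), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname clone_tree
#' @param tree a `clone_tree`.
#' @export
ct_root <- function(tree) which(is.na(tree$parent))

#' Ancestor indices of a clone (root first, excluding the clone itself)
#' @param tree a `clone_tree`.
#' @param i clone index.
#' @export
ct_ancestors <- function(tree, i) {
  out <- integer(0)
  j <- tree$parent[i]
  while (!is.na(j)) {
    out <- c(j, out)
    j <- tree$parent[j]
  }
  out
}

#' Is clone `a` a strict ancestor of clone `b`?
#' @param tree a `clone_tree`.
#' @param a,b clone indices.
#' @export
ct_is_ancestor <- function(tree, a, b) {
  j <- tree$parent[b]
  while (!is.na(j)) {
    if (j == a) return(TRUE)
    j <- tree$parent[j]
  }
  FALSE
}

#' Cumulative mutation count along the lineage of each clone
#'
#' The cumulative count of a clone is the sum of private mutation counts on
#' the path from the root down to (and including) the clone. This is the
#' quantity on which relative mutation times are defined.
#'
#' @param tree a `clone_tree`.
#' @return integer vector named by clone.
#' @export
ct_cumulative_mutations <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n)
  for (i in seq_len(n))
    out[i] <- sum(tree$n_private[c(ct_ancestors(tree, i), i)])
  names(out) <- names(tree$parent)
  out
}

#' Lineage mutation set of a clone (root-to-clone union of private sets)
#' @param tree a `clone_tree` with a `mutations` list.
#' @param i clone index.
#' @export
ct_lineage_mutations <- function(tree, i) {
  if (is.null(tree$mutations)) stop("tree carries no mutation sets")
  unique(unlist(tree$mutations[c(ct_ancestors(tree, i), i)], use.names = FALSE))
}

#' Number of branching nodes (nodes with two or more children)
#' @param tree a `clone_tree` or a parent vector.
#' @export
ct_branching_count <- function(tree) {
  parent <- if (inherits(tree, "clone_tree")) tree$parent else tree
  tab <- table(parent[!is.na(parent)])
  sum(tab >= 2L)
}

#' Check the sum (pigeonhole) rule on a prevalence matrix
#'
#' In every sample the prevalences of a clone's children may not exceed the
#' clone's own prevalence: a cell belongs to at most one descendant
#' subpopulation.
#'
#' @param parent parent vector (NA at root).
#' @param prevalence clones x samples matrix.
#' @param tolerance slack allowed on each inequality.
#' @return `TRUE` if the rule holds in every sample, else `FALSE` with a
#'   `violations` attribute listing offending (clone, sample) pairs.
#' @export
check_sum_rule <- function(parent, prevalence, tolerance = 0) {
  viol <- list()
  for (p in seq_along(parent)) {
    kids <- which(!is.na(parent) & parent == p)
    if (!length(kids)) next
    for (s in seq_len(ncol(prevalence))) {
      if (sum(prevalence[kids, s]) > prevalence[p, s] + tolerance)
        viol[[length(viol) + 1L]] <- c(clone = p, sample = s)
    }
  }
  ok <- length(viol) == 0L
  attr(ok, "violations") <- viol
  ok
}

#' Mean (or other summary) prevalence per anatomical site
#'
#' @param prevalence clones x samples matrix.
#' @param samples data.frame with `sample_id` and `site`.
#' @param fun summary function applied over the samples of each site.
#' @return clones x sites matrix.
#' @export
site_prevalence <- function(prevalence, samples, fun = mean) {
  sites <- unique(samples$site)
  out <- sapply(sites, function(s) {
    cols <- samples$sample_id[samples$site == s]
    apply(prevalence[, cols, drop = FALSE], 1, fun)
  })
  out <- matrix(out, nrow = nrow(prevalence),
                dimnames = list(rownames(prevalence), sites))
  out
}
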