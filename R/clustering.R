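#' Cluster mutations by their joint CCF profile across samples
#'
#' Groups the mutations of one patient into putative clones from their
#' cancer-cell-fraction vectors over all samples. Exactly repeated profiles
#' (the noise-free case, where every mutation of a clone back-transforms to
#' the same prevalence vector) are grouped directly. Otherwise a Gaussian
#' mixture with diagonal covariance is fitted for k = 1..`k_max` components
#' and the model order is selected by BIC. Near-duplicate components
#' (centers closer than `merge_tol` in max-norm) are merged, and clusters
#' below the minimum size are merged into the nearest center when it is
#' within `merge_tol`, or dropped otherwise.
#'
#' Mutations absent from a sample enter with CCF 0 (at several-hundred-fold
#' depth, absence is informative of prevalence ~0).
#'
#' @param ccf_matrix numeric matrix, mutations x samples, with mutation
#'   keys as rownames; `NA` entries are imputed as 0.
#' @param k_max maximum number of clusters considered.
#' @param min_size minimum mutation-cluster size (default 3).
#' @param seed integer seed (the mixture fit itself is deterministic; the
#'   seed guards auxiliary randomness).
#' @param merge_tol max-norm distance below which centers are considered
#'   the same clone.
#' @return list with `assignment` (named integer vector, `NA` = dropped),
#'   `centers` (clusters x samples, per-sample mean CCF of the members),
#'   `sizes`, and `dropped` (mutation keys).
#' @importFrom mclust Mclust mclustBIC priorControl defaultPrior
#' @export
cluster_mutations <- function(ccf_matrix, k_max = 12L, min_size = 3L,
                              seed = 1L, merge_tol = 0.1) {
  x <- as.matrix(ccf_matrix)
  if (is.null(rownames(x))) rownames(x) <- paste0("M", seq_len(nrow(x)))
  x[is.na(x)] <- 0
  n <- nrow(x)
  if (n < min_size) {
    warning("fewer than min_size mutations: single-cluster fallback")
    assignment <- stats::setNames(rep(1L, n), rownames(x))
    centers <- matrix(colMeans(x), nrow = 1,
                      dimnames = list("1", colnames(x)))
    return(list(assignment = assignment, centers = centers,
                sizes = n, dropped = character(0)))
  }

  ## exact path: collapse identical profiles (noise-free data)
  prof <- apply(round(x, 8), 1, paste, collapse = ",")
  uniq <- unique(prof)
  if (length(uniq) <= k_max) {
    cl <- match(prof, uniq)
  } else {
    set.seed(seed)
    ## the conjugate variance prior guards against degenerate solutions on
    ## zero-variance dimensions (a clone absent from a sample has CCF ~0
    ## everywhere there), which otherwise drive BIC to overfit the model order
    ## NA BICs for model orders that collapse to fewer components are
    ## expected here, not a problem worth surfacing
    fit <- withCallingHandlers(
      Mclust(x, G = seq_len(min(k_max, n - 1L)),
             modelNames = c("EII", "VII", "EEI", "VVI"),
             prior = priorControl(), verbose = FALSE),
      warning = function(w) {
        if (grepl("BIC values equal to NA", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.null(fit)) {
      warning("mixture fit failed: single-cluster fallback")
      cl <- rep(1L, n)
    } else {
      cl <- as.integer(fit$classification)
    }
  }

  centers <- cluster_centers(x, cl)
  ## merge near-duplicate centers (closer than merge_tol in max-norm)
  repeat {
    k <- nrow(centers)
    if (k < 2L) break
    dmin <- Inf; pair <- NULL
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      d <- max(abs(centers[a, ] - centers[b, ]))
      if (d < dmin) { dmin <- d; pair <- c(a, b) }
    }
    if (dmin >= merge_tol) break
    cl[which(cl == pair[2])] <- pair[1]
    cl <- match(cl, sort(unique(cl)))
    centers <- cluster_centers(x, cl)
  }

  ## enforce the minimum cluster size
  repeat {
    sizes <- tabulate(cl[!is.na(cl)], nbins = nrow(centers))
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small) || nrow(centers) == 1L) break
    s <- small[which.min(sizes[small])]
    others <- setdiff(which(sizes > 0), s)
    d <- vapply(others, function(o) max(abs(centers[o, ] - centers[s, ])),
                numeric(1))
    if (min(d) < merge_tol) {
      cl[which(cl == s)] <- others[which.min(d)]
    } else {
      cl[which(cl == s)] <- NA_integer_
    }
    keep <- sort(unique(cl[!is.na(cl)]))
    cl <- match(cl, keep)
    centers <- cluster_centers(x, cl)
  }

  sizes <- tabulate(cl[!is.na(cl)], nbins = nrow(centers))
  assignment <- stats::setNames(cl, rownames(x))
  list(assignment = assignment, centers = centers, sizes = sizes,
       dropped = rownames(x)[is.na(cl)])
}

cluster_centers <- function(x, cl) {
  ks <- sort(unique(cl[!is.na(cl)]))
  centers <- t(vapply(ks, function(k)
    colMeans(x[cl %in% k, , drop = FALSE]), numeric(ncol(x))))
  if (ncol(x) == 1L) centers <- matrix(centers, ncol = 1L)
  dimnames(centers) <- list(as.character(ks), colnames(x))
  centers
}

#' Mean cluster prevalence per sample
#'
#' The cellular prevalence of a putative clone in a sample is the
#' arithmetic mean of its member CCFs there, clipped to `[0, 1]`.
#'
#' @param member_ccf matrix of member CCF vectors (mutations x samples).
#' @return numeric vector of per-sample prevalences.
#' @export
mean_cluster_prevalence <- function(member_ccf) {
  m <- as.matrix(member_ccf)
  pmin(pmax(colMeans(m), 0), 1)
}
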