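#' Tumor-normal somatic filter status
#'
#' Evaluates the two acceptance routes for a somatic candidate call at deep
#' tumor-normal coverage. The standard rule requires >= 15x coverage in both
#' the tumor and the matched normal, a tumor variant allele fraction (VAF)
#' of at least 5%, and a normal VAF strictly below 1%. To accommodate very
#' high sequencing depth (where a handful of contaminating reads in the
#' normal would otherwise veto a true somatic call, e.g. through circulating
#' tumor cells), a relaxed route accepts calls with tumor VAF >= 15%,
#' >= 100x coverage in both samples, normal VAF up to 5% (inclusive), and a
#' tumor VAF at least 4 times the normal VAF. A call passes if either route
#' accepts it and its mapping-quality gate is set.
#'
#' @param calls data.frame with columns `t_depth`, `t_alt`, `n_depth`,
#'   `n_alt` and optionally `mapping_quality_ok` (defaults to `TRUE`).
#' @return logical vector, one entry per call. Zero-depth calls fail
#'   cleanly (no division error surfaces).
#' @export
somatic_filter_status <- function(calls) {
  stopifnot(all(c("t_depth", "t_alt", "n_depth", "n_alt") %in% names(calls)))
  if (any(calls$t_alt > calls$t_depth, na.rm = TRUE) ||
      any(calls$n_alt > calls$n_depth, na.rm = TRUE))
    stop("alt counts exceed depths")
  mq <- if ("mapping_quality_ok" %in% names(calls))
    calls$mapping_quality_ok else TRUE
  t_vaf <- ifelse(calls$t_depth > 0, calls$t_alt / calls$t_depth, 0)
  n_vaf <- ifelse(calls$n_depth > 0, calls$n_alt / calls$n_depth, 0)
  standard <- calls$t_depth >= 15 & calls$n_depth >= 15 &
    t_vaf >= 0.05 & n_vaf < 0.01
  relaxed <- calls$t_depth >= 100 & calls$n_depth >= 100 &
    t_vaf >= 0.15 & n_vaf <= 0.05 & t_vaf >= 4 * n_vaf
  mq & (standard | relaxed)
}

#' Apply the somatic filters, returning the passing calls
#'
#' @inheritParams somatic_filter_status
#' @return the subset of `calls` passing [somatic_filter_status()].
#' @export
apply_somatic_filters <- function(calls) {
  calls[somatic_filter_status(calls), , drop = FALSE]
}

#' Apply the germline variant filters
#'
#' Germline variants in the matched normal are retained with >= 10x
#' coverage, at least 5 variant-supporting reads, and a VAF of at least 5%.
#'
#' @param calls data.frame with columns `depth` and `alt`.
#' @return the passing subset.
#' @export
apply_germline_filters <- function(calls) {
  stopifnot(all(c("depth", "alt") %in% names(calls)))
  vaf <- ifelse(calls$depth > 0, calls$alt / calls$depth, 0)
  keep <- calls$depth >= 10 & calls$alt >= 5 & vaf >= 0.05
  calls[keep, , drop = FALSE]
}

NONSILENT_EFFECTS <- c("missense", "nonsense", "stoploss",
                       "frameshift_indel", "splice_site")

#' Is a mutation nonsilent?
#'
#' Nonsynonymous exonic SNVs (missense, nonsense, stoploss), frameshift
#' indels and splice-site mutations count as nonsilent; synonymous and
#' in-frame indels do not.
#'
#' @param effect character vector of functional annotations.
#' @return logical vector.
#' @export
classify_nonsilent <- function(effect) {
  if (any(is.na(effect)) || any(!nzchar(effect)))
    stop("unannotated input: every call needs a functional effect")
  effect %in% NONSILENT_EFFECTS
}

#' Tumor mutation burden per sample
#'
#' TMB is the number of nonsilent passing mutations per megabase of target
#' territory; samples above 12 mutations/Mb are flagged hypermutated.
#'
#' @param calls filtered somatic calls with columns `sample_id` and
#'   `effect`.
#' @param target_megabases size of the sequencing target in Mb.
#' @param hypermutation_threshold mutations/Mb above which a sample is
#'   called hypermutated.
#' @return data.frame with one row per sample: `sample_id`,
#'   `nonsilent_count`, `target_megabases`, `tmb`, `hypermutated`.
#' @export
compute_tmb <- function(calls, target_megabases = 50,
                        hypermutation_threshold = 12) {
  if (target_megabases <= 0) stop("target_megabases must be positive")
  nonsil <- calls[classify_nonsilent(calls$effect), , drop = FALSE]
  ids <- sort(unique(calls$sample_id))
  cnt <- vapply(ids, function(s) sum(nonsil$sample_id == s), integer(1))
  data.frame(sample_id = ids, nonsilent_count = cnt,
             target_megabases = target_megabases,
             tmb = cnt / target_megabases,
             hypermutated = cnt / target_megabases > hypermutation_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
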