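#' Cancer cell fraction from allele fraction, purity and copy number
#'
#' Inverts the expected-VAF relation for a mutation of multiplicity `m` on a
#' locus of total copy number `cn_total` in a sample of the given tumor
#' purity:
#' `ccf = vaf * (purity * cn_total + (1 - purity) * 2) / (purity * m)`.
#' Values are capped (default 1.5) so that noisy super-clonal estimates stay
#' bounded without being silently truncated to 1.
#'
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param cn_total total copy number at the locus (>= 1).
#' @param multiplicity mutated copies per cancer cell (>= 1).
#' @param cap upper bound applied to the estimate.
#' @return numeric vector of CCF estimates.
#' @export
compute_ccf <- function(vaf, purity, cn_total, multiplicity = 1, cap = 1.5) {
  if (any(purity <= 0)) stop("purity must be positive (non-tumor sample?)")
  if (any(cn_total < 1)) stop("cn_total must be >= 1")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  ccf <- vaf * (purity * cn_total + (1 - purity) * 2) / (purity * multiplicity)
  pmin(ccf, cap)
}

#' Expected VAF of a clonal mutation of given multiplicity
#' @inheritParams compute_ccf
#' @param prevalence cellular prevalence of the carrying clone.
#' @export
expected_vaf <- function(purity, cn_total, multiplicity = 1, prevalence = 1) {
  purity * prevalence * multiplicity / (purity * cn_total + (1 - purity) * 2)
}

#' Nearest-expectation mutation multiplicity
#'
#' Picks the multiplicity `m` in `1..cn_major` whose expected clonal VAF is
#' closest to the observed VAF, provided the nearest expectation lies within
#' a tolerance band; otherwise falls back to `m = 1`. Ties go to the smaller
#' multiplicity. On a 2:1 (major allele count 1) segment the answer is
#' always 1.
#'
#' @inheritParams compute_ccf
#' @param cn_minor minor allele copy number; `cn_major = cn_total - cn_minor`.
#' @param band maximum |observed - expected| VAF for a confident call.
#' @return integer vector of multiplicities.
#' @export
estimate_multiplicity <- function(vaf, purity, cn_total, cn_minor, band = 0.1) {
  n <- max(length(vaf), length(purity), length(cn_total), length(cn_minor))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  cn_total <- rep_len(cn_total, n); cn_minor <- rep_len(cn_minor, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    cn_major <- max(1L, round(cn_total[i] - cn_minor[i]))
    ms <- seq_len(cn_major)
    d <- abs(vaf[i] - expected_vaf(purity[i], cn_total[i], ms))
    best <- ms[which.min(d)]          # which.min takes the first = smaller m
    out[i] <- if (min(d) <= band) best else 1L
  }
  out
}

#' Call copy-number aberrations against the sample median
#'
#' Segments are called gained or lost when their total copy number lies
#' above or below the sample's (length-weighted) median copy number, and
#' neutral when equal.
#'
#' @param segments data.frame with `sample_id`, `chrom`, `start`, `end`,
#'   `cn_total` (and `cn_minor`).
#' @return `segments` with `call` (gain/loss/neutral) and `sample_median`
#'   columns added.
#' @export
call_aberrations <- function(segments) {
  out <- segments
  out$sample_median <- NA_real_
  out$call <- NA_character_
  for (s in unique(segments$sample_id)) {
    i <- which(segments$sample_id == s)
    w <- (segments$end[i] - segments$start[i] + 1)
    med <- weighted_median(segments$cn_total[i], w)
    centered <- segments$cn_total[i] - med
    out$sample_median[i] <- med
    out$call[i] <- ifelse(centered > 0, "gain",
                          ifelse(centered < 0, "loss", "neutral"))
  }
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Loss of heterozygosity call
#'
#' LOH is called in segments whose minor allele copy number is 0 (within a
#' rounding tolerance), covering both copy-neutral (2:0) and deletion (1:0)
#' LOH.
#'
#' @param cn_minor minor allele copy number (vector).
#' @param tol rounding tolerance.
#' @return logical vector.
#' @export
call_loh <- function(cn_minor, tol = 0.01) {
  abs(cn_minor) <= tol
}

#' Sample-wise clonal/subclonal timing state of a mutation
#'
#' A mutation is subclonal when its CCF falls below the clonal threshold.
#' Clonal mutations on a segment carrying a copy gain (major allele count
#' >= 2) are timed relative to the gain: multiplicity >= 2 means the
#' mutation predates the gain (`clonal_early`), multiplicity 1 that it
#' followed it (`clonal_late`). Without a gain the early/late distinction
#' is undefined (`clonal_NA`).
#'
#' @param ccf CCF estimate(s).
#' @param multiplicity estimated multiplicity at the locus.
#' @param cn_major major allele copy number of the covering segment.
#' @param clonal_threshold CCF below which a mutation is subclonal.
#' @return character vector over
#'   `{clonal_early, clonal_late, clonal_NA, subclonal}`.
#' @export
assign_timing <- function(ccf, multiplicity, cn_major, clonal_threshold = 0.9) {
  n <- max(length(ccf), length(multiplicity), length(cn_major))
  ccf <- rep_len(ccf, n)
  multiplicity <- rep_len(multiplicity, n)
  cn_major <- rep_len(cn_major, n)
  ifelse(ccf < clonal_threshold, "subclonal",
         ifelse(cn_major >= 2 & multiplicity >= 2, "clonal_early",
                ifelse(cn_major >= 2, "clonal_late", "clonal_NA")))
}

#' Patient-level clonality from sample-wise timing states
#'
#' A mutation is true clonal for the patient when it was called clonal
#' (early, late or NA) in at least one sample and detected in every tumor
#' sample of the patient; otherwise it is subclonal. The result is invariant
#' to sample order.
#'
#' @param states data.frame with columns `mutation_id`, `sample_id`,
#'   `timing_state` and logical `present`.
#' @param samples character vector of all tumor samples of the patient
#'   (defaults to those observed in `states`).
#' @return data.frame `mutation_id`, `patient_state` (clonal/subclonal).
#' @export
summarize_patient_clonality <- function(states,
                                        samples = unique(states$sample_id)) {
  muts <- unique(states$mutation_id)
  clonal_states <- c("clonal_early", "clonal_late", "clonal_NA")
  res <- vapply(muts, function(m) {
    rows <- states[states$mutation_id == m, , drop = FALSE]
    any_clonal <- any(rows$timing_state %in% clonal_states)
    in_all <- all(samples %in% rows$sample_id[rows$present])
    if (any_clonal && in_all) "clonal" else "subclonal"
  }, character(1))
  data.frame(mutation_id = muts, patient_state = unname(res),
             stringsAsFactors = FALSE)
}

#' Gene-level clonality tallies
#'
#' Counts genes once per clonality category per sample, deduplicating
#' multiple nonsilent mutations of the same gene.
#'
#' @param df data.frame with columns `gene`, `sample_id`, `category`.
#' @return data.frame of unique (gene, sample_id, category) rows with
#'   per-gene-category counts across samples.
#' @export
tally_gene_clonality <- function(df) {
  u <- unique(df[, c("gene", "sample_id", "category")])
  agg <- stats::aggregate(sample_id ~ gene + category, data = u, FUN = length)
  names(agg)[names(agg) == "sample_id"] <- "n_samples"
  agg[order(agg$gene, agg$category), , drop = FALSE]
}

#' Look up the covering copy-number segment of each mutation
#'
#' Matches on sample and chromosome with a binary position search within
#' the sample's sorted segments. Loci outside every segment get `NA`
#' (a no-call marker).
#'
#' @param mutations data.frame with `sample_id`, `chrom`, `pos`.
#' @param segments data.frame with `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `cn_total`, `cn_minor`.
#' @return data.frame with columns `cn_total`, `cn_minor` aligned to
#'   `mutations` rows.
#' @export
lookup_segments <- function(mutations, segments) {
  cn_total <- rep(NA_real_, nrow(mutations))
  cn_minor <- rep(NA_real_, nrow(mutations))
  key_m <- paste(mutations$sample_id, mutations$chrom)
  key_s <- paste(segments$sample_id, segments$chrom)
  for (k in unique(key_m)) {
    mi <- which(key_m == k)
    si <- which(key_s == k)
    if (!length(si)) next
    seg <- segments[si, , drop = FALSE]
    o <- order(seg$start)
    seg <- seg[o, , drop = FALSE]
    j <- findInterval(mutations$pos[mi], seg$start)
    ok <- j >= 1 & ifelse(j >= 1, mutations$pos[mi] <= seg$end[pmax(j, 1)], FALSE)
    cn_total[mi[ok]] <- seg$cn_total[j[ok]]
    cn_minor[mi[ok]] <- seg$cn_minor[j[ok]]
  }
  data.frame(cn_total = cn_total, cn_minor = cn_minor)
}
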