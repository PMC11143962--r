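#' Write / read the tab-delimited mutation and segment dialects
#'
#' The mutation dialect is a long per-sample table with columns `chrom`,
#' `pos`, `ref`, `alt`, `sample_id`, `t_depth`, `t_alt`, `n_depth`,
#' `n_alt`, `effect` (plus any extra columns present); segments carry
#' `chrom`, `start`, `end`, `cn_total`, `cn_minor`, `sample_id` with
#' 1-based inclusive coordinates.
#'
#' @param df a data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulated patient's inputs to a directory
#'
#' Emits `mutations.tsv`, `segments.tsv`, `samples.tsv`, per-sample VCFs
#' and the ground truth as JSON.
#'
#' @param patient a `synthetic_patient` from [simulate_patient()].
#' @param dir output directory (created if needed).
#' @param vcf also write one VCF v4.2 per sample.
#' @export
write_patient <- function(patient, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(patient$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(patient$segments, file.path(dir, "segments.tsv"))
  write_tsv(patient$samples, file.path(dir, "samples.tsv"))
  write_truth_json(patient$truth, file.path(dir, "truth.json"))
  if (vcf) {
    for (s in patient$samples$sample_id) {
      m <- patient$mutations[patient$mutations$sample_id == s, , drop = FALSE]
      write_mutations_vcf(m, file.path(dir, paste0(s, ".vcf")))
    }
  }
  invisible(dir)
}

#' Write per-sample somatic candidates as VCF v4.2
#'
#' Tumor and matched-normal depths and alt counts are carried in the
#' standard `AD` (ref,alt) and `DP` FORMAT fields of a TUMOR and a NORMAL
#' sample column; the functional annotation goes to an `EFF` INFO tag.
#'
#' @param m single-sample mutation table (long dialect rows).
#' @param path output `.vcf` path.
#' @export
write_mutations_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cloneseed",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Functional effect\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")), con)
  if (!nrow(m)) return(invisible(path))
  lines <- paste(
    m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS",
    paste0("EFF=", m$effect), "DP:AD",
    paste0(m$t_depth, ":", m$t_depth - m$t_alt, ",", m$t_alt),
    paste0(m$n_depth, ":", m$n_depth - m$n_alt, ",", m$n_alt),
    sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF written by [write_mutations_vcf()] back into the TSV dialect
#'
#' Uses VariantAnnotation when available (suggested dependency).
#'
#' @param path a `.vcf` file.
#' @param sample_id sample label to attach.
#' @return mutation table in the long dialect.
#' @export
read_mutations_vcf <- function(path, sample_id) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)
  ad <- gt$AD
  rr <- SummarizedExperiment::rowRanges(v)
  t_ad <- do.call(rbind, ad[, "TUMOR"])
  n_ad <- do.call(rbind, ad[, "NORMAL"])
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(unlist(VariantAnnotation::alt(v))),
    sample_id = sample_id,
    t_depth = as.integer(gt$DP[, "TUMOR"]),
    t_alt = t_ad[, 2],
    n_depth = as.integer(gt$DP[, "NORMAL"]),
    n_alt = n_ad[, 2],
    effect = unlist(VariantAnnotation::info(v)$EFF),
    stringsAsFactors = FALSE)
}

#' Serialize simulation truth to JSON
#' @param truth the `truth` element of a `synthetic_patient`.
#' @param path output `.json` path.
#' @export
write_truth_json <- function(truth, path) {
  enc <- function(tr) list(
    parent = as.list(stats::setNames(ifelse(is.na(tr$tree$parent), "root",
                                            names(tr$tree$parent)[tr$tree$parent]),
                                     names(tr$tree$parent))),
    n_private = as.list(stats::setNames(tr$tree$n_private,
                                        names(tr$tree$parent))),
    prevalence = apply(tr$tree$prevalence, 1, as.list),
    mode = tr$mode,
    disseminated = names(tr$tree$parent)[tr$disseminated],
    origin_site = as.list(stats::setNames(tr$origin_site,
                                          names(tr$tree$parent))))
  obj <- if (!is.null(truth$components))
    list(origin_model = truth$origin_model,
         components = lapply(truth$components, enc))
  else c(list(origin_model = truth$origin_model), enc(truth))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Serialize a dissemination report to JSON
#' @param report a `dissemination_report`.
#' @param path output `.json` path.
#' @export
write_report_json <- function(report, path) {
  nm <- names(report$tree$parent)
  obj <- list(
    patient_id = report$patient_id,
    origin_model = report$origin_model,
    mode = report$mode,
    n_clones = report$n_clones,
    initial = nm[report$initial],
    disseminated = as.list(nm[report$disseminated]),
    local = as.list(nm[report$local]),
    directions = as.list(report$directions),
    mutation_times = as.list(report$mutation_times),
    interval = report$interval,
    interval_method = report$interval_method,
    site_complexity = as.list(report$site_complexity),
    pairwise_modeled = report$pairwise_modeled,
    no_dissemination = report$no_dissemination,
    parent = as.list(stats::setNames(
      ifelse(is.na(report$tree$parent), "root", nm[report$tree$parent]), nm)),
    prevalence = apply(report$tree$prevalence, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Newick export of a clone tree
#'
#' Writes the fitted topology as a Newick string with clone labels; branch
#' lengths are the private mutation counts, so path lengths read as
#' mutation-time numerators.
#'
#' @param tree a `clone_tree`.
#' @return a Newick string (terminated with `;`).
#' @export
as_newick <- function(tree) {
  nm <- names(tree$parent)
  build <- function(i) {
    kids <- which(!is.na(tree$parent) & tree$parent == i)
    lab <- paste0(nm[i], ":", tree$n_private[i])
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(build(ct_root(tree)), ";")
}
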