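#' Pipeline parameters with defaults
#'
#' One place for every tunable of the pipeline. All thresholds are in CCF /
#' prevalence units unless noted.
#'
#' @param target_mb exome target territory (Mb), the TMB denominator.
#' @param clonal_threshold CCF below which a mutation is subclonal in a
#'   sample.
#' @param ccf_cap cap applied to CCF estimates.
#' @param min_cluster_size minimum mutation-cluster size.
#' @param k_max maximum number of clusters considered.
#' @param merge_tol max-norm distance for cluster merging.
#' @param sum_tolerance slack for the sum-rule and clonal-ordering tests.
#' @param root_threshold minimum prevalence everywhere for the root cluster.
#' @param presence_threshold prevalence above which a clone is present at a
#'   site.
#' @param direction_margin minimum prevalence gap for a direction call.
#' @param rescue_min_alt,rescue_min_vaf sensitivity rescue for presence
#'   testing: a mutation counts as present in a sample when it passed the
#'   somatic filters there or has at least this many alt reads at at least
#'   this VAF (presence testing must be more sensitive than discovery).
#' @param multiplicity_band tolerance band for multiplicity estimation.
#' @param bootstrap_B bootstrap replicates for cohort confidence intervals.
#' @param seed seed for the clustering and bootstrap stages.
#' @return a named list of parameters.
#' @export
pipeline_params <- function(target_mb = 50,
                            clonal_threshold = 0.9,
                            ccf_cap = 1.5,
                            min_cluster_size = 3L,
                            k_max = 12L,
                            merge_tol = 0.1,
                            sum_tolerance = 0.05,
                            root_threshold = 0.9,
                            presence_threshold = 0.02,
                            direction_margin = 0.05,
                            rescue_min_alt = 2L,
                            rescue_min_vaf = 0.01,
                            multiplicity_band = 0.1,
                            bootstrap_B = 1000L,
                            seed = 1L) {
  as.list(environment())
}

wide_matrix <- function(df, value, keys, samp) {
  m <- matrix(NA_real_, length(keys), length(samp),
              dimnames = list(keys, samp))
  m[cbind(match(df$mutation_id, keys), match(df$sample_id, samp))] <- df[[value]]
  m
}

#' Run the full dissemination analysis for one patient
#'
#' Executes the pipeline stages in order: tumor-normal somatic filtering;
#' presence testing with a sensitivity rescue; polyclonal-origin detection
#' from inter-site mutation sharing (independent site groups are modeled as
#' separate cancers); purity- and copy-number-adjusted CCF estimation with
#' nearest-expectation multiplicities; sample-wise clonal/subclonal timing
#' and patient-level clonality; mutation clustering; exhaustive clone-tree
#' enumeration under the sum rule with parsimony model selection (falling
#' back to pairwise site models when no full model exists); and
#' dissemination designation, mode, seeding direction, mutation times and
#' the dissemination interval.
#'
#' @param mutations long per-sample somatic candidate table (columns
#'   `chrom`, `pos`, `ref`, `alt`, `sample_id`, `t_depth`, `t_alt`,
#'   `n_depth`, `n_alt`, `effect`; `mutation_id` added if missing).
#' @param segments allele-specific copy-number segments (`chrom`, `start`,
#'   `end`, `cn_total`, `cn_minor`, `sample_id`).
#' @param samples sample metadata (`sample_id`, `site`, `purity`).
#' @param params a [pipeline_params()] list.
#' @param patient_id label carried into the report.
#' @return a `dissemination_report`: mode, origin model, clone
#'   designations, per-clone seeding directions and mutation times, the
#'   dissemination interval, the fitted `clone_tree`, per-sample TMB and
#'   the patient-level clonality table.
#' @export
run_patient <- function(mutations, segments, samples,
                        params = pipeline_params(), patient_id = "P1") {
  stopifnot(nrow(samples) >= 1L)
  if (!"mutation_id" %in% names(mutations))
    mutations$mutation_id <- with(mutations, paste(chrom, pos, ref, alt, sep = ":"))
  samp <- samples$sample_id

  ## stage 1: somatic filtering and presence testing
  pass_vec <- somatic_filter_status(mutations)
  vaf_vec <- ifelse(mutations$t_depth > 0, mutations$t_alt / mutations$t_depth, 0)
  present_vec <- pass_vec |
    (mutations$t_alt >= params$rescue_min_alt & vaf_vec >= params$rescue_min_vaf)
  keys_all <- unique(mutations$mutation_id)
  pass <- wide_matrix(transform(mutations, v = as.numeric(pass_vec)),
                      "v", keys_all, samp) > 0
  present <- wide_matrix(transform(mutations, v = as.numeric(present_vec)),
                         "v", keys_all, samp) > 0
  pass[is.na(pass)] <- FALSE
  present[is.na(present)] <- FALSE
  discovered <- keys_all[rowSums(pass) > 0]
  if (length(discovered) < params$min_cluster_size)
    stop("patient ", patient_id, ": fewer than ", params$min_cluster_size,
         " mutations survive the somatic filters")

  ## stage 2: cancer origin (split independent site groups)
  origin <- detect_polyclonal_origin(present[discovered, , drop = FALSE], samples)

  ## stage 3-6 per origin group
  mut_info <- mutations[!duplicated(mutations$mutation_id),
                        c("mutation_id", "chrom", "pos")]
  components <- lapply(origin$site_groups, function(grp) {
    s_sub <- samples[samples$site %in% grp, , drop = FALSE]
    in_grp <- rowSums(pass[discovered, s_sub$sample_id, drop = FALSE]) > 0
    analyze_component(discovered[in_grp], mutations, mut_info, segments,
                      s_sub, present, params, patient_id)
  })
  names(components) <- vapply(origin$site_groups, paste, character(1),
                              collapse = "+")

  ## patient-level clonality: clonal in >= 1 sample AND present in all
  ## tumor samples of the patient
  states <- do.call(rbind, lapply(components, `[[`, "states"))
  states$present <- present[cbind(match(states$mutation_id, keys_all),
                                  match(states$sample_id, samp))]
  clonality <- summarize_patient_clonality(states, samples = samp)

  ## headline component: the one modeling dissemination across >= 2 sites
  n_sites_grp <- vapply(origin$site_groups, length, integer(1))
  head_i <- if (any(n_sites_grp >= 2L)) which(n_sites_grp >= 2L)[1] else 1L
  head <- components[[head_i]]

  tmb <- compute_tmb(apply_somatic_filters(mutations), params$target_mb)

  structure(
    list(patient_id = patient_id,
         origin_model = origin$origin_model,
         site_groups = origin$site_groups,
         mode = head$mode,
         initial = head$initial, disseminated = head$disseminated,
         local = head$local, directions = head$directions,
         mutation_times = head$mutation_times,
         interval = head$interval, interval_method = head$interval_method,
         n_clones = head$n_clones,
         site_complexity = head$site_complexity,
         pairwise_modeled = head$pairwise_modeled,
         no_dissemination = head$no_dissemination,
         tree = head$tree, clusters = head$clusters,
         components = components, clonality = clonality, tmb = tmb,
         params = params),
    class = "dissemination_report")
}

analyze_component <- function(keys, mutations, mut_info, segments, samples,
                              present, params, patient_id) {
  samp <- samples$sample_id
  sub <- mutations[mutations$mutation_id %in% keys &
                     mutations$sample_id %in% samp, , drop = FALSE]
  t_alt <- wide_matrix(sub, "t_alt", keys, samp)
  t_depth <- wide_matrix(sub, "t_depth", keys, samp)
  vaf <- ifelse(!is.na(t_depth) & t_depth > 0, t_alt / t_depth, 0)
  vaf[is.na(vaf)] <- 0

  ## copy number, multiplicity and CCF per (mutation, sample)
  long <- data.frame(
    mutation_id = rep(keys, times = length(samp)),
    sample_id = rep(samp, each = length(keys)),
    stringsAsFactors = FALSE)
  long$chrom <- mut_info$chrom[match(long$mutation_id, mut_info$mutation_id)]
  long$pos <- mut_info$pos[match(long$mutation_id, mut_info$mutation_id)]
  cn <- lookup_segments(long, segments[segments$sample_id %in% samp, ])
  cn$cn_total[is.na(cn$cn_total)] <- 2    # uncovered locus: assume diploid
  cn$cn_minor[is.na(cn$cn_minor)] <- 1
  purity <- samples$purity[match(long$sample_id, samples$sample_id)]
  long$vaf <- vaf[cbind(match(long$mutation_id, keys),
                        match(long$sample_id, samp))]
  long$multiplicity <- estimate_multiplicity(long$vaf, purity, cn$cn_total,
                                             cn$cn_minor,
                                             band = params$multiplicity_band)
  long$ccf <- compute_ccf(long$vaf, purity, cn$cn_total, long$multiplicity,
                          cap = params$ccf_cap)
  long$timing_state <- assign_timing(long$ccf, long$multiplicity,
                                     round(cn$cn_total - cn$cn_minor),
                                     clonal_threshold = params$clonal_threshold)
  ccf <- matrix(long$ccf, nrow = length(keys),
                dimnames = list(keys, samp))

  ## clustering into putative clones
  clusters <- cluster_mutations(ccf, k_max = params$k_max,
                                min_size = params$min_cluster_size,
                                seed = params$seed,
                                merge_tol = params$merge_tol)
  prev <- pmin(pmax(clusters$centers, 0), 1)
  members <- split(names(clusters$assignment),
                   clusters$assignment)[rownames(prev)]

  ## clone-tree enumeration with pairwise-site fallback
  pairwise <- FALSE
  trees <- tryCatch(
    enumerate_trees(prev, tolerance = params$sum_tolerance,
                    root_threshold = params$root_threshold),
    cloneseed_no_root = function(e) NULL)
  if (is.null(trees) || !length(trees)) {
    pw <- pairwise_site_models(prev, samples, params)
    if (is.null(pw))
      stop("patient ", patient_id, ": no clonality model found, ",
           "even per site pair")
    pairwise <- TRUE
    trees <- pw
  }
  sel <- select_model(trees, prev, samples,
                      presence_threshold = params$presence_threshold)
  tree <- clone_tree(sel$best,
                     n_private = vapply(members, length, integer(1)),
                     mutations = members, prevalence = prev,
                     samples = samples)

  des <- designate_clones(tree, presence_threshold = params$presence_threshold)
  mode <- if (des$no_dissemination) NA_character_ else
    classify_mode(tree, des$disseminated)
  times <- mutation_times(tree)
  intv <- dissemination_interval(tree, des$disseminated, mode)
  directions <- vapply(des$disseminated, function(d) {
    sp <- des$site_prev[d, des$site_presence[d, ], drop = TRUE]
    infer_direction(sp, margin = params$direction_margin,
                    is_initial = d == des$initial)
  }, character(1))
  names(directions) <- names(tree$parent)[des$disseminated]

  list(mode = mode, initial = des$initial,
       disseminated = des$disseminated, local = des$local,
       directions = directions, mutation_times = times,
       interval = intv$interval, interval_method = intv$interval_method,
       n_clones = length(tree$parent),
       site_complexity = compare_site_complexity(des),
       pairwise_modeled = pairwise, no_dissemination = des$no_dissemination,
       tree = tree, clusters = clusters, designation = des,
       states = long[, c("mutation_id", "sample_id", "timing_state")])
}

## When no tree over all samples exists, model each site pair separately
## (clonal ordering tested on the pair's samples only) and hand the union
## of pairwise-consistent trees to the parsimony selection.
pairwise_site_models <- function(prev, samples, params) {
  sites <- unique(samples$site)
  if (length(sites) < 2L) return(NULL)
  out <- list()
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a >= b) next
    cols <- samples$sample_id[samples$site %in% sites[c(a, b)]]
    tr <- tryCatch(
      enumerate_trees(prev[, cols, drop = FALSE],
                      tolerance = params$sum_tolerance,
                      root_threshold = params$root_threshold),
      cloneseed_no_root = function(e) NULL)
    if (!is.null(tr)) out <- c(out, tr)
  }
  if (!length(out)) return(NULL)
  out
}

#' Cohort-level summary of dissemination reports
#'
#' Medians with bootstrap 95% confidence intervals of the number of clones
#' per cancer, the fraction of clones disseminated, the mutation time of
#' the first (or only) disseminated clone, and the dissemination interval
#' of monophyletic polyclonal cancers. Patients without a dissemination
#' call are excluded from the medians and counted separately.
#'
#' @param reports list of `dissemination_report` objects.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list with `table` (one row per patient) and `summary`
#'   (statistic, median, ci_lo, ci_hi, n).
#' @export
summarize_cohort <- function(reports, B = 1000L, seed = 1L) {
  stopifnot(length(reports) >= 1L)
  tab <- do.call(rbind, lapply(reports, function(r) {
    diss_times <- r$mutation_times[r$disseminated]
    data.frame(
      patient_id = r$patient_id, mode = r$mode,
      origin_model = r$origin_model,
      n_clones = r$n_clones,
      n_disseminated = length(r$disseminated),
      frac_disseminated = length(r$disseminated) / r$n_clones,
      time_first_diss = if (length(diss_times)) min(diss_times) else NA_real_,
      time_last_diss = if (length(diss_times)) max(diss_times) else NA_real_,
      interval = r$interval, interval_method = r$interval_method,
      no_dissemination = isTRUE(r$no_dissemination),
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  ok <- !tab$no_dissemination
  stat <- function(name, x) {
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(statistic = name, median = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = 0L, stringsAsFactors = FALSE))
    ci <- boot_ci_median(x, B = B, seed = seed)
    data.frame(statistic = name, median = stats::median(x),
               ci_lo = ci[1], ci_hi = ci[2], n = length(x),
               stringsAsFactors = FALSE)
  }
  summary <- rbind(
    stat("clones_per_cancer", tab$n_clones[ok]),
    stat("fraction_disseminated", tab$frac_disseminated[ok]),
    stat("time_first_dissemination", tab$time_first_diss[ok]),
    stat("interval_monophyletic",
         tab$interval[ok & tab$mode %in% "monophyletic_polyclonal"]))
  summary$n_excluded <- sum(!ok)
  list(table = tab, summary = summary)
}

boot_ci_median <- function(x, B = 1000L, seed = 1L) {
  if (length(x) < 2L) return(c(NA_real_, NA_real_))
  set.seed(seed)
  meds <- vapply(seq_len(B), function(i)
    stats::median(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  stats::quantile(meds, c(0.025, 0.975), names = FALSE)
}

#' Run the pipeline over a cohort of (synthetic or real) patients
#'
#' @param patients list of patient input lists (each with `mutations`,
#'   `segments`, `samples` and optionally `patient_id`), e.g. from
#'   [simulate_cohort()].
#' @param params a [pipeline_params()] list.
#' @param out_dir if given, per-patient reports (JSON), the cohort table
#'   and the cohort summary (TSV) are written there deterministically.
#' @return list with `reports`, `table` and `summary`.
#' @export
run_cohort <- function(patients, params = pipeline_params(), out_dir = NULL) {
  reports <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    pid <- if (!is.null(p$patient_id)) p$patient_id else sprintf("P%02d", i)
    run_patient(p$mutations, p$segments, p$samples, params, patient_id = pid)
  })
  cs <- summarize_cohort(reports, B = params$bootstrap_B, seed = params$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in reports)
      write_report_json(r, file.path(out_dir, paste0(r$patient_id, ".json")))
    write_tsv(cs$table, file.path(out_dir, "cohort_table.tsv"))
    write_tsv(cs$summary, file.path(out_dir, "cohort_summary.tsv"))
  }
  list(reports = reports, table = cs$table, summary = cs$summary)
}
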