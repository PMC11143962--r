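#' Simulation configuration for a synthetic multi-site tumor
#'
#' Builds and validates the configuration for one synthetic patient. The
#' defaults emulate a deeply sequenced multi-site high-grade serous carcinoma:
#' 2-3 anatomical sites, several samples per patient, tumor purity drawn from
#' 0.40-0.90, and ~670x mean sequencing depth, with a clone tree whose
#' per-site cellular prevalences obey the sum rule by construction.
#'
#' @param n_clones number of clones including the root (initial) clone.
#' @param mutations_per_clone_mean Poisson mean of private mutations per
#'   clone (a floor of 3 is applied so every clone is detectable in
#'   principle, matching the minimum mutation-cluster size used downstream).
#' @param n_sites number of anatomical sites (2 or 3).
#' @param samples_per_site integer scalar or vector (length `n_sites`) of
#'   samples per site.
#' @param depth_mean mean sequencing depth of tumor and normal samples.
#' @param purity_range range from which per-sample tumor purity is drawn.
#' @param mode dissemination mode to simulate: `"monoclonal"`,
#'   `"monophyletic_polyclonal"` or `"polyphyletic_polyclonal"`.
#' @param n_disseminated number of disseminated clones (1 for monoclonal).
#' @param noise `"none"` (rounded expected read counts) or `"binomial"`.
#' @param seed integer; fully determines the simulated patient.
#' @param site_names site labels; defaults to ovarian/omental/ascites labels.
#' @param jitter_sd multiplicative log-normal jitter applied per sample to
#'   the site-level prevalence vector (default 0 = multi-region samples of a
#'   site share the site's prevalences exactly).
#' @param polyclonal_origin simulate two independently initiated cancers
#'   occupying disjoint site sets with no shared mutations (requires
#'   `n_sites = 3`).
#' @param gain_chroms chromosomes given a 3:1 copy-number state in every
#'   sample; truncal mutations there are placed on the gained allele
#'   (multiplicity 2), exercising early/late timing calls.
#' @param normal_error sequencing error rate applied to the matched normal
#'   (default 0.001, safely below the 1% contamination filter).
#' @param target_mb exome target territory in megabases (TMB denominator).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_clones = 5L,
                       mutations_per_clone_mean = 40,
                       n_sites = 2L,
                       samples_per_site = 2L,
                       depth_mean = 670,
                       purity_range = c(0.4, 0.9),
                       mode = c("monophyletic_polyclonal", "monoclonal",
                                "polyphyletic_polyclonal"),
                       n_disseminated = 2L,
                       noise = c("binomial", "none"),
                       seed = 1L,
                       site_names = NULL,
                       jitter_sd = 0,
                       polyclonal_origin = FALSE,
                       gain_chroms = character(0),
                       normal_error = 0.001,
                       target_mb = 50) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  n_clones <- as.integer(n_clones)
  n_sites <- as.integer(n_sites)
  n_disseminated <- as.integer(n_disseminated)
  if (is.null(site_names))
    site_names <- c("ovary_left", "omentum", "ascites")[seq_len(n_sites)]
  if (length(site_names) != n_sites) stop("site_names must match n_sites")
  if (length(samples_per_site) == 1L)
    samples_per_site <- rep(as.integer(samples_per_site), n_sites)
  if (length(samples_per_site) != n_sites)
    stop("samples_per_site must be scalar or length n_sites")
  if (n_sites < 1L || n_sites > 3L) stop("n_sites must be 1, 2 or 3")
  if (any(purity_range <= 0) || any(purity_range > 1) ||
      purity_range[1] > purity_range[2])
    stop("purity_range must be an increasing pair within (0, 1]")
  if (mutations_per_clone_mean <= 0)
    stop("mutations_per_clone_mean must be positive")
  if (n_disseminated > n_clones)
    stop("n_disseminated cannot exceed n_clones")
  if (mode == "monoclonal") {
    if (n_disseminated != 1L) stop("monoclonal mode means n_disseminated = 1")
  } else {
    if (n_disseminated < 2L)
      stop("polyclonal modes need n_disseminated >= 2")
    if (n_clones < n_disseminated + 1L)
      stop("need n_clones >= n_disseminated + 1 (the root does not disseminate in polyclonal modes)")
    if (mode == "polyphyletic_polyclonal" && n_clones < 3L)
      stop("polyphyletic mode needs at least 3 clones")
  }
  if (mode != "monoclonal" && n_sites < 2L)
    stop("polyclonal dissemination needs at least 2 sites")
  if (polyclonal_origin && n_sites != 3L)
    stop("polyclonal_origin simulation requires n_sites = 3")
  structure(
    list(n_clones = n_clones,
         mutations_per_clone_mean = mutations_per_clone_mean,
         n_sites = n_sites, samples_per_site = samples_per_site,
         depth_mean = depth_mean, purity_range = purity_range,
         mode = mode, n_disseminated = n_disseminated, noise = noise,
         seed = as.integer(seed), site_names = site_names,
         jitter_sd = jitter_sd, polyclonal_origin = polyclonal_origin,
         gain_chroms = gain_chroms, normal_error = normal_error,
         target_mb = target_mb),
    class = "sim_config")
}

# sample() that never falls into the 1:x trap for length-1 vectors
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

#' Simulate a clone-tree topology for a given dissemination mode
#'
#' The root is always clone 1. Disseminated clones are placed so that the
#' requested mode is realizable: a single clone (possibly the root itself)
#' for monoclonal seeding, a root-to-leaf chain for monophyletic polyclonal
#' seeding, and at least two sibling branches for polyphyletic seeding.
#' Ancestors of a disseminated clone are always the root or disseminated
#' themselves, so that multi-site presence is consistent down the lineage.
#' Remaining clones attach uniformly at random and will evolve locally.
#' Private mutation counts are Poisson draws with a floor of 3.
#'
#' @param config a [sim_config()].
#' @return a `clone_tree` with `disseminated` (clone indices) and `mode`
#'   fields set; prevalences are assigned by [assign_prevalences()].
#' @export
simulate_clone_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_clones
  parent <- rep(NA_integer_, n)
  placed <- 1L
  if (config$mode == "monoclonal") {
    if (n == 1L) {
      disseminated <- 1L
    } else if (stats::runif(1) < 0.5) {
      disseminated <- 1L          # the initial clone itself seeded the sites
    } else {
      disseminated <- 2L          # one subclone, direct child of the root
      parent[2L] <- 1L
      placed <- c(placed, 2L)
    }
  } else if (config$mode == "monophyletic_polyclonal") {
    disseminated <- seq(2L, config$n_disseminated + 1L)
    parent[disseminated] <- disseminated - 1L   # chain off the root
    placed <- c(placed, disseminated)
  } else {
    disseminated <- seq(2L, config$n_disseminated + 1L)
    parent[2L] <- 1L
    parent[3L] <- 1L              # guaranteed sibling pair
    placed <- c(placed, 2L, 3L)
    for (d in disseminated[-c(1L, 2L)]) {
      parent[d] <- resample(c(1L, placed[placed %in% disseminated]))
      placed <- c(placed, d)
    }
  }
  for (i in setdiff(seq_len(n), placed)) {
    parent[i] <- resample(placed)
    placed <- c(placed, i)
  }
  n_private <- pmax(stats::rpois(n, config$mutations_per_clone_mean), 3L)
  tree <- clone_tree(parent, n_private)
  tree$disseminated <- disseminated
  tree$mode <- config$mode
  tree
}

#' Assign per-site, per-sample cellular prevalences to a simulated tree
#'
#' Prevalences are allocated per site by stick-breaking from the root
#' downward, so the sum rule holds exactly by construction. Disseminated
#' clones receive positive prevalence at every site, with the designated
#' origin site scaled down (factor drawn from 0.25-0.45) so the
#' smallest-prevalence direction rule is recoverable. Local clones are
#' confined to a single site drawn from their parent's support. All non-root
#' prevalences stay below 0.88 so that only truncal mutations reach the
#' clonal range in every sample.
#'
#' @param tree output of [simulate_clone_tree()].
#' @param config the same [sim_config()].
#' @return the tree with `prevalence` (clones x samples), `samples`
#'   (metadata incl. purity), `support` (per-clone site sets) and
#'   `origin_site` (per-clone seeding origin, `NA` when undetermined).
#' @export
assign_prevalences <- function(tree, config) {
  stopifnot(inherits(tree, "clone_tree"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(tree$parent)
  sites <- config$site_names
  ns <- length(sites)
  diss <- as.integer(tree$disseminated)
  root <- unname(ct_root(tree))

  ## --- site support ---------------------------------------------------
  support <- vector("list", n)
  support[[root]] <- sites
  for (d in setdiff(diss, root)) support[[d]] <- sites
  depth_order <- order(vapply(seq_len(n), function(i)
    length(ct_ancestors(tree, i)), integer(1)))
  for (i in depth_order) {
    if (!is.null(support[[i]])) next
    support[[i]] <- resample(support[[tree$parent[i]]])   # local: one site
  }

  ## --- origin sites (seeding direction truth) -------------------------
  origin <- rep(NA_character_, n)
  if (config$mode == "monoclonal") {
    if (!identical(diss, root) && ns >= 2L) origin[diss] <- resample(sites)
  } else if (config$mode == "monophyletic_polyclonal") {
    origin[diss] <- resample(sites)      # one seeding route for the chain
  } else {
    oo <- resample(sites, 2L)
    origin[diss[1L]] <- oo[1L]
    origin[diss[2L]] <- oo[2L]
    for (d in diss[-c(1L, 2L)]) {
      anc <- intersect(ct_ancestors(tree, d), diss)
      origin[d] <- if (length(anc)) origin[anc[length(anc)]] else resample(sites)
    }
  }

  ## --- target prevalence of disseminated clones (per site) ------------
  dval <- matrix(0, nrow = n, ncol = ns, dimnames = list(names(tree$parent), sites))
  dval[root, ] <- 1
  site_factor <- stats::runif(ns, 0.9, 1)
  nonroot_diss <- setdiff(diss, root)
  if (length(nonroot_diss)) {
    if (config$mode == "polyphyletic_polyclonal") {
      base <- stats::runif(length(nonroot_diss), 0.45, 0.60)
      names(base) <- as.character(nonroot_diss)
      for (k in seq_along(nonroot_diss)) {
        d <- nonroot_diss[k]
        if (tree$parent[d] != root)      # chained under another disseminated
          base[k] <- base[as.character(tree$parent[d])] * stats::runif(1, 0.55, 0.7)
      }
      of <- stats::runif(length(nonroot_diss), 0.25, 0.45)
      for (k in seq_along(nonroot_diss)) {
        d <- nonroot_diss[k]
        dval[d, ] <- base[k] * site_factor
        dval[d, origin[d]] <- base[k] * of[k]
      }
      ## keep sibling sums under the root budget at every site
      rk <- nonroot_diss[tree$parent[nonroot_diss] == root]
      for (s in seq_len(ns)) {
        tot <- sum(dval[rk, s])
        if (tot > 0.85) dval[rk, s] <- dval[rk, s] * 0.85 / tot
      }
    } else {
      ## monoclonal subclone or monophyletic chain: multiplicative decay
      b <- stats::runif(1, 0.78, 0.85)
      of <- stats::runif(1, 0.25, 0.45)
      for (d in nonroot_diss) {           # chain order = index order
        dval[d, ] <- b * site_factor
        if (!is.na(origin[d])) dval[d, origin[d]] <- b * of
        b <- b * stats::runif(1, 0.60, 0.75)
      }
    }
  }

  ## --- stick-breaking allocation of local clones ----------------------
  val <- matrix(0, nrow = n, ncol = ns, dimnames = dimnames(dval))
  val[root, ] <- 1
  for (i in depth_order) {
    kids <- which(!is.na(tree$parent) & tree$parent == i)
    if (!length(kids)) next
    dk <- intersect(kids, nonroot_diss)
    val[dk, ] <- dval[dk, , drop = FALSE]
    lk <- setdiff(kids, dk)
    for (s in seq_len(ns)) {
      ls <- lk[vapply(lk, function(k) sites[s] %in% support[[k]], logical(1))]
      if (!length(ls)) next
      budget <- 0.88 * val[i, s] - sum(val[dk, s])
      if (budget <= 0.01) { val[ls, s] <- 0; next }
      w <- stats::runif(length(ls), 0.5, 1)
      val[ls, s] <- budget * stats::runif(1, 0.55, 0.85) * w / sum(w)
    }
  }

  ## --- per-sample expansion -------------------------------------------
  sample_site <- rep(sites, times = config$samples_per_site)
  nsamp <- length(sample_site)
  sample_id <- sprintf("S%02d_%s", seq_len(nsamp), sample_site)
  purity <- round(stats::runif(nsamp, config$purity_range[1],
                               config$purity_range[2]), 3)
  prev <- val[, match(sample_site, sites), drop = FALSE]
  colnames(prev) <- sample_id
  if (config$jitter_sd > 0) {
    jit <- matrix(exp(stats::rnorm(n * nsamp, 0, config$jitter_sd)),
                  nrow = n)
    prev <- prev * jit
    prev[root, ] <- 1
    ## restore the sum rule top-down: rescale offending sibling sets
    for (i in depth_order) {
      kids <- which(!is.na(tree$parent) & tree$parent == i)
      if (!length(kids)) next
      for (s in seq_len(nsamp)) {
        tot <- sum(prev[kids, s])
        if (tot > prev[i, s]) prev[kids, s] <- prev[kids, s] * prev[i, s] / tot
      }
    }
    prev <- pmin(prev, 1)
  }

  tree$prevalence <- prev
  tree$samples <- data.frame(sample_id = sample_id, site = sample_site,
                             purity = purity, stringsAsFactors = FALSE)
  tree$support <- support
  tree$origin_site <- origin
  tree
}

CHROMS <- paste0("chr", 1:22)

#' Emit read-level mutation tables and copy-number segments
#'
#' For every private mutation of clone `c` observed in sample `s`, the
#' expected variant allele fraction is
#' `purity_s * prevalence(c, s) * multiplicity /
#'  (purity_s * cn_total + (1 - purity_s) * 2)`.
#' With `noise = "binomial"` alt counts are Binomial(depth, VAF) draws at
#' Poisson-distributed depths; with `noise = "none"` they are rounded
#' expectations at fixed depth, and the exact expected VAF is retained in
#' the `vaf_expected` column for loss-free back-transformation. Matched
#' normals carry a 0.1% error rate. Copy-number segments are diploid
#' heterozygous (2:1) except on `gain_chroms`, which are 3:1 with truncal
#' mutations on the gained allele.
#'
#' @param tree tree with prevalences from [assign_prevalences()].
#' @param config the same [sim_config()].
#' @param chrom_offset shift applied to chromosome assignment (used to keep
#'   independent cancers of a polyclonal-origin patient locus-disjoint).
#' @param mut_prefix prefix for mutation positions, same purpose.
#' @return list with `mutations` (long per-sample table), `segments`,
#'   `samples`, and per-mutation truth columns (`clone`, `multiplicity`).
#' @export
emit_reads <- function(tree, config, chrom_offset = 0L, mut_prefix = 0L) {
  stopifnot(inherits(tree, "clone_tree"), !is.null(tree$prevalence))
  set.seed(config$seed + 2L)
  n <- length(tree$parent)
  m_tot <- sum(tree$n_private)
  clone_of <- rep(seq_len(n), times = tree$n_private)
  idx <- seq_len(m_tot)
  chrom <- CHROMS[((idx - 1L + chrom_offset) %% length(CHROMS)) + 1L]
  pos <- 1000L + 1500L * ((idx - 1L) %/% length(CHROMS)) + mut_prefix
  bases <- c("A", "C", "G", "T")
  ref <- resample(bases, m_tot, replace = TRUE)
  alt <- vapply(ref, function(r) resample(setdiff(bases, r)), character(1))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  effects <- c("missense", "synonymous", "nonsense", "frameshift_indel",
               "splice_site", "inframe_indel", "stoploss", "other")
  eff_p <- c(0.50, 0.25, 0.05, 0.06, 0.04, 0.04, 0.02, 0.04)
  effect <- resample(effects, m_tot, replace = TRUE, prob = eff_p)

  gained <- chrom %in% config$gain_chroms
  multiplicity <- ifelse(gained & clone_of == ct_root(tree), 2L, 1L)
  cn_total_mut <- ifelse(gained, 3, 2)

  samples <- tree$samples
  seg_chrom_end <- max(pos) + 10000L
  segments <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    data.frame(chrom = CHROMS, start = 1L, end = seg_chrom_end,
               cn_total = ifelse(CHROMS %in% config$gain_chroms, 3, 2),
               cn_minor = 1, sample_id = sid, stringsAsFactors = FALSE)
  }))

  rows <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    p <- samples$purity[si]
    prev <- tree$prevalence[clone_of, sid]
    vaf <- p * prev * multiplicity / (p * cn_total_mut + (1 - p) * 2)
    if (config$noise == "binomial") {
      t_depth <- pmax(stats::rpois(m_tot, config$depth_mean), 1L)
      t_alt <- stats::rbinom(m_tot, t_depth, vaf)
      n_depth <- pmax(stats::rpois(m_tot, config$depth_mean), 1L)
      n_alt <- stats::rbinom(m_tot, n_depth, config$normal_error)
    } else {
      t_depth <- rep(round(config$depth_mean), m_tot)
      t_alt <- round(t_depth * vaf)
      n_depth <- rep(round(config$depth_mean), m_tot)
      n_alt <- round(n_depth * config$normal_error)
    }
    rows[[si]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, sample_id = sid,
      t_depth = t_depth, t_alt = t_alt, n_depth = n_depth, n_alt = n_alt,
      effect = effect, mapping_quality_ok = TRUE, vaf_expected = vaf,
      mutation_id = key, stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL

  tree$mutations <- split(key, clone_of)[as.character(seq_len(n))]
  names(tree$mutations) <- names(tree$parent)
  list(mutations = mutations, segments = segments, samples = samples,
       mutation_clone = stats::setNames(names(tree$parent)[clone_of], key),
       multiplicity = stats::setNames(multiplicity, key),
       tree = tree)
}

#' Simulate one synthetic multi-site patient with known ground truth
#'
#' Chains [simulate_clone_tree()], [assign_prevalences()] and
#' [emit_reads()]. With `polyclonal_origin = TRUE` two independent cancers
#' are simulated on disjoint site sets (one ovarian-only, one spanning the
#' two extraovarian sites) with locus-disjoint mutation sets, emulating a
#' polyclonal cancer origin.
#'
#' @param config a [sim_config()].
#' @param patient_id label stored in the truth object.
#' @return a `synthetic_patient`: list with `mutations`, `segments`,
#'   `samples` and `truth` (tree(s), mode, disseminated clones, origin
#'   sites, per-mutation clone map).
#' @export
simulate_patient <- function(config, patient_id = "P1") {
  stopifnot(inherits(config, "sim_config"))
  if (config$polyclonal_origin) return(simulate_polyclonal_patient(config, patient_id))
  tree <- simulate_clone_tree(config)
  tree <- assign_prevalences(tree, config)
  em <- emit_reads(tree, config)
  structure(
    list(patient_id = patient_id,
         mutations = em$mutations, segments = em$segments,
         samples = em$samples,
         truth = list(tree = em$tree, mode = config$mode,
                      disseminated = em$tree$disseminated,
                      origin_site = em$tree$origin_site,
                      mutation_clone = em$mutation_clone,
                      multiplicity = em$multiplicity,
                      origin_model = "monoclonal_origin",
                      config = config)),
    class = "synthetic_patient")
}

simulate_polyclonal_patient <- function(config, patient_id = "P1") {
  sites <- config$site_names
  ## cancer A: confined to the ovarian site; cancer B: disseminates between
  ## the two extraovarian sites
  cfg_a <- sim_config(
    n_clones = max(2L, config$n_clones - config$n_disseminated),
    mutations_per_clone_mean = config$mutations_per_clone_mean,
    n_sites = 1L, samples_per_site = config$samples_per_site[1L],
    depth_mean = config$depth_mean, purity_range = config$purity_range,
    mode = "monoclonal", n_disseminated = 1L, noise = config$noise,
    seed = config$seed, site_names = sites[1L],
    normal_error = config$normal_error, target_mb = config$target_mb)
  mode_b <- if (config$mode == "polyphyletic_polyclonal")
    "polyphyletic_polyclonal" else "monophyletic_polyclonal"
  cfg_b <- sim_config(
    n_clones = config$n_clones,
    mutations_per_clone_mean = config$mutations_per_clone_mean,
    n_sites = 2L, samples_per_site = config$samples_per_site[2:3],
    depth_mean = config$depth_mean, purity_range = config$purity_range,
    mode = mode_b, n_disseminated = max(2L, config$n_disseminated),
    noise = config$noise, seed = config$seed + 101L, site_names = sites[2:3],
    normal_error = config$normal_error, target_mb = config$target_mb)
  pa <- simulate_patient(cfg_a, paste0(patient_id, "a"))
  pb <- simulate_patient(cfg_b, paste0(patient_id, "b"))
  ## keep the two cancers locus-disjoint and sample ids unique
  shift <- 10000000L
  shift_key <- function(keys) {
    vapply(strsplit(keys, ":", fixed = TRUE), function(p)
      paste(p[1], as.integer(p[2]) + shift, p[3], p[4], sep = ":"),
      character(1))
  }
  pb$mutations$pos <- pb$mutations$pos + shift
  pb$mutations$mutation_id <- with(pb$mutations, paste(chrom, pos, ref, alt, sep = ":"))
  pb$segments$end <- pb$segments$end + shift
  names(pb$truth$mutation_clone) <- shift_key(names(pb$truth$mutation_clone))
  names(pb$truth$multiplicity) <- shift_key(names(pb$truth$multiplicity))
  pb$truth$tree$mutations <- lapply(pb$truth$tree$mutations, shift_key)
  fix_ids <- function(x, tag) {
    x$sample_id <- paste0(tag, x$sample_id)
    x
  }
  pa$mutations <- fix_ids(pa$mutations, "A_")
  pa$segments <- fix_ids(pa$segments, "A_")
  pa$samples <- fix_ids(pa$samples, "A_")
  pb$mutations <- fix_ids(pb$mutations, "B_")
  pb$segments <- fix_ids(pb$segments, "B_")
  pb$samples <- fix_ids(pb$samples, "B_")
  colnames(pa$truth$tree$prevalence) <- paste0("A_", colnames(pa$truth$tree$prevalence))
  pa$truth$tree$samples$sample_id <- paste0("A_", pa$truth$tree$samples$sample_id)
  colnames(pb$truth$tree$prevalence) <- paste0("B_", colnames(pb$truth$tree$prevalence))
  pb$truth$tree$samples$sample_id <- paste0("B_", pb$truth$tree$samples$sample_id)
  structure(
    list(patient_id = patient_id,
         mutations = rbind(pa$mutations, pb$mutations),
         segments = rbind(pa$segments, pb$segments),
         samples = rbind(pa$samples, pb$samples),
         truth = list(components = list(A = pa$truth, B = pb$truth),
                      mode = mode_b,       # dissemination among extraovarian sites
                      origin_model = "polyclonal_origin",
                      config = config)),
    class = "synthetic_patient")
}

#' Simulate a synthetic cohort of multi-site patients
#'
#' Default composition over 23 patients mirrors a disseminated HGSC cohort:
#' 6 monoclonal, 11 monophyletic-polyclonal and 5 polyphyletic-polyclonal
#' cancers plus 1 patient with a polyclonal cancer origin. Clone numbers are
#' drawn from 3-9, polyphyletic cancers are given 3 sampled sites, and each
#' patient receives an independent sub-seed derived from the master seed.
#'
#' @param n_patients cohort size.
#' @param seed master seed; patient `i` uses `seed + 1000 * i`.
#' @param noise passed to [sim_config()].
#' @param mutations_per_clone_mean passed to [sim_config()].
#' @param include_polyclonal_origin include one polyclonal-origin patient.
#' @return list of `synthetic_patient` objects.
#' @export
simulate_cohort <- function(n_patients = 23L, seed = 1L, noise = "binomial",
                            mutations_per_clone_mean = 40,
                            include_polyclonal_origin = TRUE) {
  set.seed(seed)
  pool <- rep(rep(c("monoclonal", "monophyletic_polyclonal",
                    "polyphyletic_polyclonal"), times = c(6, 11, 5)),
              ceiling(n_patients / 22))
  modes <- resample(pool, n_patients)
  poly_origin <- rep(FALSE, n_patients)
  if (include_polyclonal_origin && n_patients >= 2L) {
    i <- resample(seq_len(n_patients))
    poly_origin[i] <- TRUE
    modes[i] <- "monophyletic_polyclonal"
  }
  lapply(seq_len(n_patients), function(i) {
    mode <- modes[i]
    n_clones <- resample(3:9)
    n_sites <- if (mode == "polyphyletic_polyclonal" || poly_origin[i]) 3L
               else resample(2:3, prob = c(0.85, 0.15))
    n_diss <- switch(mode,
      monoclonal = 1L,
      monophyletic_polyclonal = min(resample(2:3), n_clones - 1L),
      polyphyletic_polyclonal = min(resample(2:3), n_clones - 1L))
    spp <- c(resample(2:3), resample(1:2, n_sites - 1L, replace = TRUE))
    cfg <- sim_config(
      n_clones = n_clones, mutations_per_clone_mean = mutations_per_clone_mean,
      n_sites = n_sites, samples_per_site = spp, mode = mode,
      n_disseminated = n_diss, noise = noise,
      seed = seed + 1000L * i, polyclonal_origin = poly_origin[i])
    simulate_patient(cfg, sprintf("P%02d", i))
  })
}
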