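#' Designate initial, disseminated and local clones
#'
#' The root of the selected model is the initial (truncal) clone. Non-root
#' clones present at two or more anatomical sites are disseminated; clones
#' confined to a single site are local. When no non-root clone is shared
#' across sites but more than one site was sampled, the initial clone
#' itself is the disseminated clone (seeding occurred before subclonal
#' development). A clone is "present" at a site when any sample of the site
#' carries it above the presence threshold.
#'
#' @param tree a `clone_tree` with `prevalence` and `samples`.
#' @param presence_threshold prevalence (CCF units) above which a clone
#'   counts as present in a sample.
#' @return list with `initial`, `disseminated`, `local`, `undetected`
#'   (clone indices), `site_presence` (clones x sites logical),
#'   `site_prev` (clones x sites mean prevalence) and `no_dissemination`
#'   (TRUE for degenerate single-site input).
#' @export
designate_clones <- function(tree, presence_threshold = 0.02) {
  stopifnot(!is.null(tree$prevalence), !is.null(tree$samples))
  root <- unname(ct_root(tree))
  pres <- site_prevalence(tree$prevalence, tree$samples, fun = max) >=
    presence_threshold
  sprev <- site_prevalence(tree$prevalence, tree$samples, fun = mean)
  nsite <- rowSums(pres)
  nonroot <- setdiff(seq_along(tree$parent), root)
  disseminated <- nonroot[nsite[nonroot] >= 2L]
  no_diss <- FALSE
  if (!length(disseminated)) {
    if (nsite[root] >= 2L) {
      disseminated <- root       # monoclonal seeding of the initial clone
    } else {
      no_diss <- TRUE            # single sampled site: nothing to call
    }
  }
  local <- nonroot[nsite[nonroot] == 1L]
  undetected <- nonroot[nsite[nonroot] == 0L]
  list(initial = root, disseminated = disseminated, local = local,
       undetected = undetected, site_presence = pres, site_prev = sprev,
       no_dissemination = no_diss)
}

#' Classify the dissemination mode of a cancer
#'
#' One disseminated clone means monoclonal dissemination. With several,
#' the mode is monophyletic polyclonal when every pair of disseminated
#' clones lies on a single root-to-leaf path (each pair in an
#' ancestor-descendant relation), and polyphyletic polyclonal when at
#' least two disseminated clones evolved on separate branches.
#'
#' @param tree a `clone_tree`.
#' @param disseminated integer indices of disseminated clones.
#' @return one of `"monoclonal"`, `"monophyletic_polyclonal"`,
#'   `"polyphyletic_polyclonal"`, or `NA` with a warning for an empty set.
#' @export
classify_mode <- function(tree, disseminated) {
  if (!length(disseminated)) {
    warning("no disseminated clones: mode undefined")
    return(NA_character_)
  }
  if (length(disseminated) == 1L) return("monoclonal")
  for (a in disseminated) for (b in disseminated) {
    if (a < b && !ct_is_ancestor(tree, a, b) && !ct_is_ancestor(tree, b, a))
      return("polyphyletic_polyclonal")
  }
  "monophyletic_polyclonal"
}

#' Detect a polyclonal cancer origin from inter-site mutation sharing
#'
#' A cancer has a polyclonal origin when some pair of sampled sites shares
#' no filtered somatic mutation at all: the tumors at those sites arose
#' independently. Sites are partitioned into origin groups (connected
#' components of the sharing graph), which downstream modeling treats as
#' separate cancers.
#'
#' @param presence logical matrix, mutations x samples (detected or not).
#' @param samples data.frame with `sample_id` and `site`.
#' @return list with `origin_model` (`"monoclonal_origin"` or
#'   `"polyclonal_origin"`), `shared` (sites x sites shared-mutation
#'   counts) and `site_groups` (list of site-label vectors).
#' @export
detect_polyclonal_origin <- function(presence, samples) {
  sites <- unique(samples$site)
  k <- length(sites)
  if (k < 2L)
    return(list(origin_model = "monoclonal_origin",
                shared = NULL, site_groups = list(sites)))
  site_pres <- vapply(sites, function(s) {
    cols <- samples$sample_id[samples$site == s]
    rowSums(presence[, cols, drop = FALSE]) > 0
  }, logical(nrow(presence)))
  shared <- crossprod(site_pres)  # mutations present at both sites
  adj <- shared > 0
  ## connected components of the sharing graph
  comp <- rep(NA_integer_, k)
  cid <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  groups <- split(sites, comp)
  names(groups) <- NULL
  list(origin_model = if (cid > 1L) "polyclonal_origin" else "monoclonal_origin",
       shared = shared, site_groups = groups)
}

#' Infer the seeding direction of a disseminated clone
#'
#' Among the sites where the clone is present, the site with the strictly
#' smallest mean prevalence is taken as the origin of seeding: the clone
#' rose to high prevalence where it landed and remained a minor population
#' where it left from. The direction is undetermined when the smallest two
#' prevalences are tied within the margin, or for an initial clone at
#' prevalence ~1 everywhere.
#'
#' @param site_prev named numeric vector: the clone's mean prevalence per
#'   site, restricted to sites where it is present.
#' @param margin minimum gap between the two smallest prevalences.
#' @param is_initial whether this is the initial (root) clone.
#' @return a site label, or `"undetermined"`.
#' @export
infer_direction <- function(site_prev, margin = 0.05, is_initial = FALSE) {
  if (length(site_prev) < 2L) return("undetermined")
  if (is_initial && all(site_prev >= 0.9)) return("undetermined")
  o <- order(site_prev)
  if (site_prev[o[2]] - site_prev[o[1]] <= margin) return("undetermined")
  names(site_prev)[o[1]]
}

#' Relative mutation time of a clone
#'
#' The clone's cumulative (root-lineage) mutation count relative to the
#' latest developed clone of the cancer (the clone with the largest
#' cumulative count). The latest clone has mutation time 1 by definition.
#'
#' @param tree a `clone_tree`.
#' @return numeric vector in `[0, 1]` named by clone.
#' @export
mutation_times <- function(tree) {
  cum <- ct_cumulative_mutations(tree)
  cum / max(cum)
}

#' Evolutionary time interval of dissemination
#'
#' Monoclonal dissemination has interval 0. For monophyletic polyclonal
#' dissemination the interval is the mutation-time span between the first
#' and last disseminated clone. For polyphyletic dissemination, where
#' branched clones are not comparable on one lineage, the interval is the
#' largest number of mutations unique to either of two mutually
#' non-ancestral disseminated clones (the symmetric difference of their
#' root-lineage mutation sets), relative to the total number of modeled
#' mutations.
#'
#' @param tree a `clone_tree` (with `mutations` sets for the polyphyletic
#'   branch; falls back to cumulative counts via the lowest common
#'   ancestor when sets are absent).
#' @param disseminated indices of disseminated clones.
#' @param mode output of [classify_mode()].
#' @return list with `interval` and `interval_method`.
#' @export
dissemination_interval <- function(tree, disseminated, mode) {
  if (is.na(mode) || mode == "monoclonal")
    return(list(interval = 0, interval_method = "monophyletic_span"))
  if (mode == "monophyletic_polyclonal") {
    mt <- mutation_times(tree)[disseminated]
    return(list(interval = max(mt) - min(mt),
                interval_method = "monophyletic_span"))
  }
  total <- sum(tree$n_private)
  best <- 0
  for (a in disseminated) for (b in disseminated) {
    if (a >= b) next
    if (ct_is_ancestor(tree, a, b) || ct_is_ancestor(tree, b, a)) next
    if (!is.null(tree$mutations)) {
      la <- ct_lineage_mutations(tree, a)
      lb <- ct_lineage_mutations(tree, b)
      uniq <- length(setdiff(la, lb)) + length(setdiff(lb, la))
    } else {
      cum <- ct_cumulative_mutations(tree)
      lca <- lowest_common_ancestor(tree, a, b)
      uniq <- (cum[a] - cum[lca]) + (cum[b] - cum[lca])
    }
    best <- max(best, uniq / total)
  }
  list(interval = best, interval_method = "polyphyletic_unique_fraction")
}

lowest_common_ancestor <- function(tree, a, b) {
  pa <- c(ct_ancestors(tree, a), a)
  pb <- c(ct_ancestors(tree, b), b)
  common <- intersect(pa, pb)
  common[length(common)]
}

#' Unique (site-private) subclone counts per site
#'
#' For each site, the number of clones present at that site and absent
#' from every other: a per-patient measure of site-level architectural
#' complexity (ovarian tumors of disseminated cancers tend to carry more
#' site-private subclones than extraovarian tumors).
#'
#' @param designation output of [designate_clones()].
#' @return named integer vector over sites.
#' @export
compare_site_complexity <- function(designation) {
  pres <- designation$site_presence
  private <- rowSums(pres) == 1L
  counts <- colSums(pres & private)
  counts
}
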