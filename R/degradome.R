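#' Candidate and kinetically verified degrader targets
#'
#' Two-step target discovery: candidate targets come from the volcano
#' contrast (significantly decreased proteins plus the most strongly
#' decreased ones, see [volcano()]); a candidate is verified when its chase
#' profile under the degrader co-treatment is classified \code{decaying} —
#' i.e. the depletion seen in the endpoint contrast is backed by
#' degradation kinetics.
#'
#' @param volcano_rows a [volcano()] result (or any data frame with a
#'   \code{candidates} attribute / \code{significant} and \code{difference}
#'   columns).
#' @param classes_treat a [classify_profiles()] table for the degrader
#'   co-treatment arm.
#' @return List with character vectors \code{candidates} and
#'   \code{verified} (verified is a subset of candidates).
#' @export
discover_targets <- function(volcano_rows, classes_treat) {
  cand <- attr(volcano_rows, "candidates")
  if (is.null(cand)) {
    cand <- volcano_rows$protein_id[volcano_rows$significant &
                                      volcano_rows$difference < 0]
  }
  decaying <- classes_treat$protein_id[classes_treat$label == "decaying"]
  list(candidates = cand, verified = intersect(cand, decaying))
}

#' Proteasome-inhibition rescue check
#'
#' Confirms proteasome-mediated degradation: a verified target treated with
#' the degrader alone should be depleted relative to the vehicle control,
#' and pre-incubation with a proteasome inhibitor (bortezomib) should
#' restore its level. Ratios are computed on linear-scale, non-imputed mean
#' intensities at a single rescue endpoint:
#' \code{r_protac = mean(PROTAC) / mean(CON)} and
#' \code{r_rescue = mean(BORT_PROTAC) / mean(CON)}. A target is rescued when
#' \code{r_protac <= depletion_threshold} (there was depletion to rescue)
#' and \code{r_rescue >= rescue_threshold}.
#'
#' The thresholds are operational cut-offs of this package (the underlying
#' assay is usually read qualitatively from bar plots); both are exposed in
#' the run configuration.
#'
#' @param x a linear-scale, non-imputed [lfq_matrix()] containing the rescue
#'   arms.
#' @param targets character vector of protein ids to assess.
#' @param endpoint_h rescue endpoint in hours (default 4).
#' @param depletion_threshold maximum \code{r_protac} counting as depleted
#'   (default 0.7).
#' @param rescue_threshold minimum \code{r_rescue} counting as restored
#'   (default 0.8).
#' @param protac_arm,bort_arm,control_arm condition labels of the degrader-
#'   only, inhibitor-plus-degrader and vehicle arms.
#' @param design optional design override.
#' @return Data frame with one row per assessed target: \code{protein_id},
#'   \code{r_protac}, \code{r_rescue}, \code{depleted}, \code{rescued}.
#' @export
rescue_check <- function(x, targets, endpoint_h = 4,
                         depletion_threshold = 0.7, rescue_threshold = 0.8,
                         protac_arm = "PROTAC", bort_arm = "BORT_PROTAC",
                         control_arm = "CON", design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "linear") stopf("rescue check uses linear-scale intensities")
  if (isTRUE(x$imputed)) stopf("rescue check must use non-imputed intensities")
  design <- design %||% x$design
  arms <- c(protac_arm, bort_arm, control_arm)
  for (arm in arms) {
    if (!length(design_samples(design, arm, endpoint_h))) {
      stopf("design lacks arm '%s' at the rescue endpoint t = %s h",
            arm, endpoint_h)
    }
  }
  arm_mean <- function(arm, p) {
    s <- design_samples(design, arm, endpoint_h)
    mean(x$values[p, s], na.rm = TRUE)
  }
  targets <- intersect(targets, protein_ids(x))
  r_protac <- vapply(targets, function(p) {
    arm_mean(protac_arm, p) / arm_mean(control_arm, p)
  }, numeric(1))
  r_rescue <- vapply(targets, function(p) {
    arm_mean(bort_arm, p) / arm_mean(control_arm, p)
  }, numeric(1))
  depleted <- !is.na(r_protac) & r_protac <= depletion_threshold
  data.frame(
    protein_id = targets,
    r_protac = unname(r_protac),
    r_rescue = unname(r_rescue),
    depleted = unname(depleted),
    rescued = unname(depleted & !is.na(r_rescue) &
                       r_rescue >= rescue_threshold),
    stringsAsFactors = FALSE
  )
}

#' Overlaps between per-condition decaying protein sets
#'
#' Tabulates which proteins decay naturally (translation-inhibitor arm) or
#' are degraded (degrader co-treatment arms): per-condition decaying sets,
#' all intersection cardinalities over condition subsets, and the proteins
#' unique to each condition — the counts behind Venn/upset displays.
#'
#' @param classes named list of [classify_profiles()] tables (names =
#'   condition labels; at least 2).
#' @return List with \code{sets} (named list of decaying protein-id
#'   vectors), \code{unique_sets} (per condition, members in no other set),
#'   and \code{overlap_counts} (data frame: one row per non-empty condition
#'   subset with its intersection cardinality).
#' @export
compare_decaying_sets <- function(classes) {
  if (length(classes) < 2L) stopf("need at least 2 conditions to compare")
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stopf("'classes' must be a named list (condition labels)")
  }
  sets <- lapply(classes, function(cl) cl$protein_id[cl$label == "decaying"])
  conds <- names(sets)
  unique_sets <- lapply(conds, function(cn) {
    others <- unlist(sets[setdiff(conds, cn)], use.names = FALSE)
    setdiff(sets[[cn]], others)
  })
  names(unique_sets) <- conds

  subsets <- unlist(lapply(seq_along(conds), function(k) {
    utils::combn(conds, k, simplify = FALSE)
  }), recursive = FALSE)
  overlap_counts <- data.frame(
    conditions = vapply(subsets, paste, character(1), collapse = "&"),
    n = vapply(subsets, function(s) {
      length(Reduce(intersect, sets[s]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  list(sets = sets, unique_sets = unique_sets,
       overlap_counts = overlap_counts)
}

#' Median half-life per condition over its unique decaying set
#'
#' Summarizes half-life distributions per condition over the proteins
#' unique to that condition's decaying/degraded set, after dropping
#' undefined half-lives and those beyond the reporting cap (default 60 h:
#' longer half-lives cannot be estimated reliably from a short chase).
#'
#' @param fits named list of [fit_first_order()] tables per condition.
#' @param unique_sets named list of protein-id vectors per condition (e.g.
#'   from [compare_decaying_sets()]; any protein sets work).
#' @return Data frame with \code{condition}, \code{n} (proteins entering
#'   the median) and \code{median_t_half} (h; \code{NA} when no protein
#'   survives the exclusions).
#' @export
summarize_half_lives <- function(fits, unique_sets) {
  conds <- names(unique_sets)
  rows <- lapply(conds, function(cn) {
    f <- fits[[cn]]
    if (is.null(f)) stopf("no fits supplied for condition '%s'", cn)
    f <- f[f$protein_id %in% unique_sets[[cn]] & !is.na(f$t_half) &
             !f$excluded_long, , drop = FALSE]
    data.frame(condition = cn, n = nrow(f),
               median_t_half = if (nrow(f)) stats::median(f$t_half)
                               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a per-protein degradome report
#'
#' One row per protein with its volcano statistics, per-condition profile
#' class and half-life, candidate/verified/rescued membership and the
#' half-life reduction where available.
#'
#' @param volcano_rows a [volcano()] result.
#' @param classes named list of [classify_profiles()] tables.
#' @param fits named list of [fit_first_order()] tables.
#' @param targets result of [discover_targets()].
#' @param rescue optional [rescue_check()] result.
#' @param delta optional [delta_half_life()] result.
#' @return A data frame keyed by \code{protein_id}.
#' @export
degradome_report <- function(volcano_rows, classes, fits, targets,
                             rescue = NULL, delta = NULL) {
  out <- data.frame(protein_id = volcano_rows$protein_id,
                    difference = volcano_rows$difference,
                    t_mod = volcano_rows$t_mod,
                    significant = volcano_rows$significant,
                    stringsAsFactors = FALSE)
  for (cn in names(classes)) {
    cl <- classes[[cn]]
    out[[paste0("class_", cn)]] <-
      cl$label[match(out$protein_id, cl$protein_id)]
  }
  for (cn in names(fits)) {
    f <- fits[[cn]]
    out[[paste0("t_half_", cn)]] <-
      f$t_half[match(out$protein_id, f$protein_id)]
  }
  out$candidate <- out$protein_id %in% targets$candidates
  out$verified <- out$protein_id %in% targets$verified
  if (!is.null(rescue)) {
    out$rescued <- out$protein_id %in% rescue$protein_id[rescue$rescued]
  }
  if (!is.null(delta)) {
    idx <- match(out$protein_id, delta$protein_id)
    out$delta_t_half <- delta$delta[idx]
    out$delta_rank <- delta$rank[idx]
  }
  out
}
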