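#' Protein fraction remaining (PFR)
#'
#' Expresses every linear-scale intensity as a percentage of the protein's
#' pre-chase baseline, the mean intensity over the vehicle-control (CON)
#' replicates at time 0:
#' \deqn{PFR(p, s) = 100 \cdot I(p, s) / \overline{I}_{CON, t0}(p).}
#' Proteins with no present CON t0 value have no baseline and are dropped.
#' PFR must be computed on non-imputed data — kinetic profiles with imputed
#' dropouts would fabricate decay — and the function refuses an imputed
#' matrix.
#'
#' @param x a linear-scale, non-imputed [lfq_matrix()].
#' @param design optional design override; defaults to the design in \code{x}.
#' @return An object of class \code{pfr_matrix}: list with \code{pfr}
#'   (proteins x samples percentage matrix, \code{NA} where the intensity was
#'   missing), \code{baseline} (named vector of mean CON t0 intensities) and
#'   \code{design}.
#' @export
compute_pfr <- function(x, design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "linear") stopf("PFR requires the linear intensity scale")
  if (isTRUE(x$imputed)) {
    stopf("refusing to compute PFR from an imputed matrix: kinetic profiles must use observed intensities only")
  }
  design <- design %||% x$design
  base_samples <- design_samples(design, "CON", 0)
  if (!length(base_samples)) stopf("design has no CON samples at t = 0")
  bs <- x$values[, base_samples, drop = FALSE]
  baseline <- rowMeans(bs, na.rm = TRUE)
  baseline[rowSums(!is.na(bs)) == 0L] <- NA_real_
  keep <- !is.na(baseline)
  pfr <- 100 * x$values[keep, , drop = FALSE] / baseline[keep]
  structure(list(pfr = pfr, baseline = baseline[keep], design = design),
            class = "pfr_matrix")
}

#' @export
print.pfr_matrix <- function(x, ...) {
  cat(sprintf("PFR matrix: %d proteins x %d samples (%% of CON t0 baseline)\n",
              nrow(x$pfr), ncol(x$pfr)))
  invisible(x)
}

#' Classify chase profiles as stable, decaying, incomplete or other
#'
#' Applies the strict profile filter to one condition's chase window (all
#' timepoints > 0). Per protein, in order:
#' \itemize{
#'   \item \code{incomplete} — any replicate at any chase timepoint missing
#'     (the 3-of-3 detection requirement);
#'   \item \code{stable} — every replicate PFR at every chase timepoint lies
#'     within the stability band (default 80–120\%);
#'   \item \code{decaying} — the per-timepoint mean PFR decreases strictly
#'     across the ascending chase grid (a continuous intensity decrease);
#'   \item \code{other} — everything else.
#' }
#' The labels are mutually exclusive and exhaustive over the proteins that
#' have PFR rows.
#'
#' @param pfr a [compute_pfr()] result.
#' @param condition condition label to classify.
#' @param stability_band numeric length-2 vector, default \code{c(80, 120)}.
#' @param decrease_tolerance relative tolerance for the strict decrease:
#'   timepoint means must satisfy \code{m[i+1] < m[i] * (1 + tol)}; the
#'   default 0 demands a strict decrease.
#' @param band_mode apply the stability band to every replicate value
#'   (\code{"replicate"}, default, the stricter reading) or to the
#'   per-timepoint mean (\code{"mean"}).
#' @return A data frame with columns \code{protein_id}, \code{condition},
#'   \code{label}.
#' @export
classify_profiles <- function(pfr, condition, stability_band = c(80, 120),
                              decrease_tolerance = 0,
                              band_mode = c("replicate", "mean")) {
  stopifnot(inherits(pfr, "pfr_matrix"))
  band_mode <- match.arg(band_mode)
  design <- pfr$design
  if (!condition %in% design$condition) {
    stopf("condition '%s' not in design", condition)
  }
  tps <- chase_timepoints(design, condition)
  if (!length(tps)) stopf("condition '%s' has no chase timepoints", condition)
  sample_sets <- lapply(tps, function(tp) design_samples(design, condition, tp))
  all_samples <- unlist(sample_sets)

  m <- pfr$pfr[, all_samples, drop = FALSE]
  labels <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    vals <- m[i, ]
    if (anyNA(vals)) { labels[i] <- "incomplete"; next }
    tp_means <- vapply(sample_sets, function(s) mean(pfr$pfr[i, s]), numeric(1))
    in_band <- if (band_mode == "replicate") {
      all(vals >= stability_band[1] & vals <= stability_band[2])
    } else {
      all(tp_means >= stability_band[1] & tp_means <= stability_band[2])
    }
    if (in_band) { labels[i] <- "stable"; next }
    decreasing <- all(tp_means[-1] < tp_means[-length(tp_means)] *
                        (1 + decrease_tolerance))
    labels[i] <- if (decreasing) "decaying" else "other"
  }
  data.frame(protein_id = rownames(m), condition = condition, label = labels,
             stringsAsFactors = FALSE)
}

#' Half-life from a first-order degradation rate
#'
#' \deqn{t_{1/2} = \ln(2) / k_{deg}} for \eqn{k_{deg} > 0}; non-positive
#' rates have no half-life and map to \code{NA} (undefined is a value here,
#' not an error).
#'
#' @param kdeg numeric vector of degradation rate constants (1/h).
#' @return Numeric vector of half-lives in hours.
#' @export
half_life_from_rate <- function(kdeg) {
  out <- rep(NA_real_, length(kdeg))
  pos <- !is.na(kdeg) & kdeg > 0
  out[pos] <- log(2) / kdeg[pos]
  out
}

#' Fit first-order decay kinetics per protein
#'
#' The kinetic core of the package. With protein synthesis blocked, protein
#' intensity follows \eqn{I(t) = I_0 e^{-k_{deg} t}}, so \eqn{\ln I} is
#' linear in time with slope \eqn{-k_{deg}}. For every protein the function
#' runs ordinary least squares of \eqn{\ln(\mathrm{intensity})} on the chase
#' time (hours) over all individual replicate observations of one condition
#' (no pre-averaging), with a free intercept. The baseline CON t0 sample is
#' not part of any condition's chase window. Fits need at least 3 present
#' observations spanning at least 2 distinct timepoints; proteins below that
#' are reported with \code{NA} estimates.
#'
#' Half-lives longer than \code{max_half_life_h} (default 60 h) cannot be
#' determined reliably from a short chase and are flagged
#' \code{excluded_long}; the estimates are retained and the flag is applied
#' at the summary stages.
#'
#' @param x a linear-scale, non-imputed [lfq_matrix()].
#' @param condition condition label whose chase window is fitted.
#' @param proteins optional character vector restricting the fit set
#'   (default: all proteins in \code{x}).
#' @param max_half_life_h reporting cap on the half-life (default 60).
#' @param design optional design override.
#' @return An object of class \code{decay_fits}: a data frame with columns
#'   \code{protein_id}, \code{condition}, \code{kdeg} (1/h), \code{t_half}
#'   (h, \code{NA} when \code{kdeg <= 0}), \code{intercept} (ln intensity at
#'   t = 0), \code{r2}, \code{n_points}, \code{excluded_long}. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals} and \code{plot}.
#' @examples
#' sim <- make_fixture("tiny_clean")
#' fits <- fit_first_order(sim$lfq, "CHX")
#' head(coef(fits))
#' @export
fit_first_order <- function(x, condition, proteins = NULL,
                            max_half_life_h = 60, design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "linear") stopf("decay fitting requires the linear intensity scale")
  if (isTRUE(x$imputed)) {
    stopf("refusing to fit kinetics on an imputed matrix: fits must use observed intensities only")
  }
  design <- design %||% x$design
  if (!condition %in% design$condition) {
    stopf("condition '%s' not in design", condition)
  }
  tps <- chase_timepoints(design, condition)
  samples <- design$sample_id[design$condition == condition &
                                design$timepoint_h > 0]
  times <- design$timepoint_h[match(samples, design$sample_id)]
  proteins <- proteins %||% protein_ids(x)
  v <- x$values[proteins, samples, drop = FALSE]

  m <- length(proteins)
  kdeg <- intercept <- r2 <- rep(NA_real_, m)
  n_points <- integer(m)
  pts <- vector("list", m)
  for (i in seq_len(m)) {
    y <- log(v[i, ])
    ok <- is.finite(y)
    n_points[i] <- sum(ok)
    if (n_points[i] < 3L || length(unique(times[ok])) < 2L) next
    tt <- times[ok]; yy <- y[ok]
    fit <- stats::lm.fit(cbind(1, tt), yy)
    slope <- fit$coefficients[2]
    # an exactly constant series has slope 0, not floating-point dust
    if (max(yy) == min(yy)) slope <- 0
    intercept[i] <- fit$coefficients[1]
    kdeg[i] <- -slope
    sst <- sum((yy - mean(yy))^2)
    r2[i] <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
    pts[[i]] <- data.frame(protein_id = proteins[i], timepoint_h = tt,
                           log_intensity = yy,
                           fitted = intercept[i] - kdeg[i] * tt,
                           stringsAsFactors = FALSE)
  }
  t_half <- half_life_from_rate(kdeg)
  out <- data.frame(
    protein_id = proteins, condition = condition,
    kdeg = kdeg, t_half = t_half, intercept = intercept, r2 = r2,
    n_points = n_points,
    excluded_long = !is.na(t_half) & t_half > max_half_life_h,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "timepoints") <- tps
  attr(out, "max_half_life_h") <- max_half_life_h
  attr(out, "points") <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  class(out) <- c("decay_fits", "data.frame")
  out
}

#' @export
print.decay_fits <- function(x, ...) {
  fitted <- !is.na(x$kdeg)
  cat(sprintf("First-order decay fits: %d proteins, condition %s\n",
              nrow(x), x$condition[1] %||% "?"))
  cat(sprintf("  fitted: %d; kdeg > 0: %d; t1/2 > %g h (flagged): %d\n",
              sum(fitted), sum(x$kdeg > 0, na.rm = TRUE),
              attr(x, "max_half_life_h") %||% 60, sum(x$excluded_long)))
  th <- x$t_half[!is.na(x$t_half) & !x$excluded_long]
  if (length(th)) {
    cat(sprintf("  median t1/2 (defined, <= cap): %.2f h over %d proteins\n",
                stats::median(th), length(th)))
  }
  invisible(x)
}

#' @export
summary.decay_fits <- function(object, ...) {
  th <- object$t_half[!is.na(object$t_half) & !object$excluded_long]
  structure(list(
    condition = object$condition[1],
    n = nrow(object),
    n_fitted = sum(!is.na(object$kdeg)),
    n_decaying_rate = sum(object$kdeg > 0, na.rm = TRUE),
    n_excluded_long = sum(object$excluded_long),
    half_life_quartiles = if (length(th)) stats::quantile(th, c(.25, .5, .75))
                          else NULL,
    median_r2 = stats::median(object$r2, na.rm = TRUE)
  ), class = "summary.decay_fits")
}

#' @export
print.summary.decay_fits <- function(x, ...) {
  cat(sprintf("Condition %s: %d proteins, %d fitted, %d with kdeg > 0, %d beyond the half-life cap\n",
              x$condition, x$n, x$n_fitted, x$n_decaying_rate,
              x$n_excluded_long))
  if (!is.null(x$half_life_quartiles)) {
    q <- x$half_life_quartiles
    cat(sprintf("  t1/2 quartiles [h]: %.2f / %.2f / %.2f;  median r2 = %.3f\n",
                q[1], q[2], q[3], x$median_r2))
  }
  invisible(x)
}

#' @export
coef.decay_fits <- function(object, ...) {
  out <- cbind(intercept = object$intercept, kdeg = object$kdeg)
  rownames(out) <- object$protein_id
  out
}

#' Predicted intensities from decay fits
#'
#' @param object a [fit_first_order()] result.
#' @param times numeric vector of chase times (h); defaults to the fitted
#'   chase grid.
#' @param proteins optional subset of protein ids.
#' @param type \code{"linear"} for intensities, \code{"log"} for ln
#'   intensities.
#' @param ... unused.
#' @return Matrix of predictions, proteins x times.
#' @export
predict.decay_fits <- function(object, times = NULL, proteins = NULL,
                               type = c("linear", "log"), ...) {
  type <- match.arg(type)
  times <- times %||% attr(object, "timepoints")
  idx <- if (is.null(proteins)) seq_len(nrow(object))
         else match(proteins, object$protein_id)
  if (anyNA(idx)) stopf("unknown protein id(s)")
  eta <- outer(object$intercept[idx], times,
               function(b0, t) b0) - outer(object$kdeg[idx], times, `*`)
  dimnames(eta) <- list(object$protein_id[idx], times)
  if (type == "log") eta else exp(eta)
}

#' @export
residuals.decay_fits <- function(object, ...) {
  pts <- attr(object, "points")
  if (is.null(pts)) return(numeric(0))
  stats::setNames(pts$log_intensity - pts$fitted,
                  paste0(pts$protein_id, "@", pts$timepoint_h, "h"))
}

#' Plot a fitted decay profile
#'
#' Draws the observed ln-intensities and the fitted first-order decay line
#' for one protein.
#'
#' @param x a [fit_first_order()] result.
#' @param protein protein id to plot (default: the first fitted protein).
#' @param ... passed to [plot()].
#' @return Invisibly, the per-point data used.
#' @export
plot.decay_fits <- function(x, protein = NULL, ...) {
  pts <- attr(x, "points")
  if (is.null(pts) || !nrow(pts)) stopf("no fitted points to plot")
  protein <- protein %||% pts$protein_id[1]
  pp <- pts[pts$protein_id == protein, , drop = FALSE]
  if (!nrow(pp)) stopf("protein '%s' has no fitted points", protein)
  row <- x[x$protein_id == protein, ]
  plot(pp$timepoint_h, pp$log_intensity,
       xlab = "chase time [h]", ylab = "ln(LFQ intensity)",
       main = sprintf("%s (%s): t1/2 = %s h", protein, row$condition,
                      ifelse(is.na(row$t_half), "undefined",
                             format(row$t_half, digits = 3))), ...)
  graphics::abline(a = row$intercept, b = -row$kdeg, lty = 2)
  invisible(pp)
}

#' Half-life differences between two conditions
#'
#' Joins two [fit_first_order()] tables (reference, e.g. the translation-
#' inhibitor-only arm, and treatment, e.g. the degrader co-treatment) on the
#' proteins whose half-life is defined and below the reporting cap in both,
#' and ranks by the half-life reduction
#' \deqn{\Delta t_{1/2} = t_{1/2}^{ref} - t_{1/2}^{treat}.}
#' Positive values mark proteins whose degradation the treatment
#' accelerated; ranking by magnitude orders the degradome by potency.
#'
#' @param fits_ref,fits_treat \code{decay_fits} tables for the reference and
#'   treatment condition.
#' @return Data frame with columns \code{protein_id}, \code{t_half_ref},
#'   \code{t_half_treat}, \code{delta}, \code{rank}, sorted by \code{delta}
#'   descending (ties broken by protein id).
#' @export
delta_half_life <- function(fits_ref, fits_treat) {
  usable <- function(f) {
    f[!is.na(f$t_half) & !f$excluded_long, c("protein_id", "t_half")]
  }
  a <- usable(fits_ref); b <- usable(fits_treat)
  m <- merge(a, b, by = "protein_id", suffixes = c("_ref", "_treat"))
  m <- m[order(-(m$t_half_ref - m$t_half_treat), m$protein_id), , drop = FALSE]
  out <- data.frame(
    protein_id = m$protein_id,
    t_half_ref = m$t_half_ref,
    t_half_treat = m$t_half_treat,
    delta = m$t_half_ref - m$t_half_treat,
    rank = seq_len(nrow(m)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
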