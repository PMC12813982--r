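#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops every protein flagged as a reversed-sequence decoy, a common
#' contaminant, or identified only by a modification site. Row order of the
#' remaining proteins is preserved. Idempotent.
#'
#' @param x an [lfq_matrix()] with populated flags.
#' @return The filtered \code{lfq_matrix}. The number of removed rows per
#'   category is reported via \code{message()}.
#' @export
filter_decoys <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  fl <- x$flags
  drop <- fl$reverse | fl$contaminant | fl$only_by_site
  message(sprintf(
    "filter_decoys: removed %d of %d (%d reverse, %d contaminant, %d only-by-site)",
    sum(drop), nrow(fl), sum(fl$reverse), sum(fl$contaminant),
    sum(fl$only_by_site)))
  if (all(drop)) warnf("all proteins were flagged; result is empty")
  subset_lfq(x, proteins = rownames(x$values)[!drop])
}

#' Log2-transform a linear-scale LFQ matrix
#'
#' @param x a linear-scale [lfq_matrix()]. Applying the transform twice is an
#'   error (guarded by the scale flag).
#' @return The matrix on log2 scale; missing values stay missing.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "linear") stopf("matrix is already on %s scale", x$scale)
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Replicate-completeness screen
#'
#' Returns the set of proteins detected (non-missing) in every replicate of
#' every timepoint of every requested condition — the "three out of three
#' replicates in all time points" rule that defines the fully detected
#' protein set.
#'
#' @param x an [lfq_matrix()].
#' @param conditions character vector of condition labels to screen over;
#'   defaults to all conditions in the design.
#' @param design optional [sample_design()]; defaults to the design carried
#'   by \code{x}.
#' @return Character vector of protein ids passing the screen, in matrix
#'   row order.
#' @export
completeness_filter <- function(x, conditions = NULL, design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  design <- design %||% x$design
  conditions <- conditions %||% unique(design$condition)
  absent <- setdiff(conditions, design$condition)
  if (length(absent)) {
    stopf("condition(s) not in design: %s", paste(absent, collapse = ", "))
  }
  samples <- design$sample_id[design$condition %in% conditions]
  samples <- intersect(samples, colnames(x$values))
  ok <- rowSums(is.na(x$values[, samples, drop = FALSE])) == 0L
  rownames(x$values)[ok]
}

#' Left-censored missing-value imputation
#'
#' Replaces every missing cell with a draw from a normal distribution
#' shifted below the observed intensity distribution of its sample column:
#' \deqn{N(\mu_s - d\,\sigma_s, \; (w\,\sigma_s)^2)}
#' where \eqn{\mu_s} and \eqn{\sigma_s} are the mean and standard deviation
#' of the present log2 values in sample column \eqn{s}, \eqn{d} is the
#' downshift (default 1.8 standard deviations) and \eqn{w} the width
#' (default 0.3 standard deviations). This models intensity-dependent
#' dropout at the detection limit. Present values are untouched; output is
#' fully deterministic given the seed.
#'
#' @param x a log2-scale [lfq_matrix()].
#' @param downshift non-negative shift in units of the per-column standard
#'   deviation (default 1.8).
#' @param width positive width as a fraction of the per-column standard
#'   deviation (default 0.3).
#' @param seed integer seed for the imputation draws.
#' @param per_column logical; compute \eqn{\mu,\sigma} per sample column
#'   (default, the behaviour of mainstream proteomics software) or from the
#'   whole matrix.
#' @return The matrix with all missing cells filled and \code{imputed = TRUE}.
#' @export
impute_left_censored <- function(x, downshift = 1.8, width = 0.3, seed = 1L,
                                 per_column = TRUE) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "log2") stopf("imputation expects a log2-scale matrix")
  if (downshift < 0) stopf("downshift must be >= 0")
  if (width <= 0) stopf("width must be > 0")
  v <- x$values
  if (!per_column) {
    mu <- mean(v, na.rm = TRUE)
    sd_all <- stats::sd(as.vector(v), na.rm = TRUE)
  }
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      if (per_column) {
        present <- v[!miss, j]
        if (length(present) < 3L) {
          stopf("sample column '%s' has fewer than 3 present values; imputation statistics undefined",
                colnames(v)[j])
        }
        mu <- mean(present)
        sd_all <- stats::sd(present)
      }
      v[miss, j] <- stats::rnorm(sum(miss), mean = mu - downshift * sd_all,
                                 sd = width * sd_all)
    }
  })
  x$values <- v
  x$imputed <- TRUE
  x
}

#' Optional median centering across samples
#'
#' Subtracts each sample column's median of present values (log2 scale),
#' aligning sample medians at zero. Off by default in the pipeline: protein
#' amounts are assumed normalized at the bench, and no in-silico
#' between-sample normalization is applied unless requested.
#'
#' @param x a log2-scale [lfq_matrix()].
#' @return The centered matrix.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "log2") stopf("median centering expects a log2-scale matrix")
  med <- apply(x$values, 2, stats::median, na.rm = TRUE)
  x$values <- sweep(x$values, 2, med, "-")
  x
}
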