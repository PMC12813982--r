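#' S0-moderated two-sample t statistic
#'
#' The moderated statistic used for volcano selection: the ordinary pooled
#' two-sample t statistic with a constant \code{s0} (the "fudge factor")
#' added to the standard error of the difference,
#' \deqn{t_{mod} = \frac{\bar{a} - \bar{b}}{se_{pooled} + s_0},}
#' which damps the significance of proteins with very small within-group
#' variance. With \code{s0 = 0} it reduces to the classical pooled t.
#'
#' @param a,b numeric vectors of (log2) values for the two groups, each of
#'   length >= 2, finite.
#' @param s0 non-negative moderation constant (default 0.1, on the log2
#'   scale of the data).
#' @return A list with elements \code{difference} (\code{mean(a) - mean(b)}),
#'   \code{t_mod}, \code{se} (pooled standard error) and \code{p_raw}
#'   (two-sided p of the unmoderated test, for reporting).
#' @export
s0_t_statistic <- function(a, b, s0 = 0.1) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stopf("values must be finite")
  if (s0 < 0) stopf("s0 must be >= 0")
  na <- length(a); nb <- length(b)
  diff <- mean(a) - mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se + s0 == 0) {
    stopf("zero within-group variance in both groups with s0 = 0: statistic undefined")
  }
  t_mod <- diff / (se + s0)
  df <- na + nb - 2
  t0 <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
  p_raw <- 2 * stats::pt(-abs(t0), df = df)
  list(difference = diff, t_mod = t_mod, se = se, p_raw = p_raw)
}

# Row-wise moderated t for matrices A (m x na) and B (m x nb).
row_s0_t <- function(A, B, s0) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  denom <- se + s0
  if (any(denom == 0)) {
    stopf("zero within-group variance with s0 = 0 for protein(s): %s",
          paste(utils::head(rownames(A)[denom == 0], 5), collapse = ", "))
  }
  t0 <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  list(difference = diff, t_mod = diff / denom, se = se,
       p_raw = 2 * stats::pt(-abs(t0), df = na + nb - 2))
}

# Distinct group-A column assignments of 1..n taken na at a time, excluding
# the two assignments equivalent to the observed grouping (the observed
# assignment itself and, for balanced designs, its group swap, which
# reproduces |t| exactly). Including them would give the FDR estimator a
# floor of 2 / choose(n, na) — 0.10 for triplicates — so that no protein
# could ever be called at FDR 0.05 in a 3 vs 3 design. Returns one
# assignment per column; if more remain than n_perm, samples n_perm of them
# without replacement.
perm_assignments <- function(n, na, n_perm, seed) {
  key_of <- function(v) paste(v, collapse = ",")
  trivial <- key_of(seq_len(na))
  if (n - na == na) trivial <- c(trivial, key_of(seq.int(na + 1L, n)))
  total <- choose(n, na) - length(trivial)
  if (total < 1L) stopf("no non-trivial label permutations exist")
  small <- choose(n, na) <= max(1e5, n_perm + 2)
  if (small) {
    all_c <- utils::combn(n, na)
    keep <- !vapply(seq_len(ncol(all_c)), function(j) {
      key_of(all_c[, j]) %in% trivial
    }, logical(1))
    all_c <- all_c[, keep, drop = FALSE]
    if (total <= n_perm) return(all_c)
    return(with_seed(seed,
                     all_c[, sample.int(ncol(all_c), n_perm), drop = FALSE]))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, nrow = na, ncol = n_perm)
    k <- 0L
    while (k < n_perm) {
      cand <- sort(sample.int(n, na))
      key <- key_of(cand)
      if (key %in% trivial || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      out[, k] <- cand
    }
    out
  })
}

#' Permutation-FDR differential test
#'
#' Computes the S0-moderated t statistic for every protein and calls
#' significance by a single global threshold on \code{|t_mod|} estimated
#' from label permutations: for a candidate threshold \eqn{c}, the false
#' discovery rate is estimated as the mean permuted count of
#' \eqn{|t| \ge c} divided by the observed count, and the significance
#' threshold is the smallest \eqn{c} (among observed \eqn{|t|} values) with
#' estimated FDR at or below \code{fdr}. Proteins whose \eqn{|t_{mod}|}
#' equals the threshold exactly are significant. The permutation null
#' excludes the assignments equivalent to the observed grouping (the
#' observed labels and, in balanced designs, their group swap): those
#' reproduce the observed statistics verbatim and would bound the estimated
#' FDR below by 2/(number of distinct splits), making calls at FDR 0.05
#' impossible for triplicate designs. When the number of remaining distinct
#' assignments is at most \code{n_perm} the permutations are enumerated
#' exhaustively; otherwise \code{n_perm} distinct assignments are sampled
#' without replacement under \code{seed}.
#'
#' @param A,B numeric matrices (proteins x replicates) of log2 values for
#'   the two groups, same proteins in the same row order; \code{A} rownames
#'   key the output.
#' @param s0 moderation constant, see [s0_t_statistic()].
#' @param fdr target false discovery rate in (0, 1) (default 0.05).
#' @param n_perm number of label permutations (default 250).
#' @param seed integer seed for the permutation sampler.
#' @return A data frame with columns \code{protein_id}, \code{difference},
#'   \code{t_mod}, \code{p_raw}, \code{significant}, in the input row order,
#'   with attributes \code{threshold} (the |t_mod| cut-off, \code{Inf} when
#'   nothing can be called), \code{n_perm_used}, \code{exhaustive} and
#'   \code{fdr_curve} (candidate thresholds with raw and monotonized FDR
#'   estimates).
#' @export
permutation_fdr <- function(A, B, s0 = 0.1, fdr = 0.05, n_perm = 250L,
                            seed = 1L) {
  if (!is.matrix(A) || !is.matrix(B) || nrow(A) != nrow(B)) {
    stopf("A and B must be matrices with identical row counts")
  }
  if (ncol(A) < 2L || ncol(B) < 2L) stopf("each group needs >= 2 samples")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  if (!(fdr > 0 && fdr < 1)) stopf("fdr must be in (0, 1)")
  if (anyNA(A) || anyNA(B)) {
    stopf("missing values in test input; impute or filter for completeness first")
  }
  na <- ncol(A); nb <- ncol(B); n <- na + nb
  obs <- row_s0_t(A, B, s0)
  abs_obs <- abs(obs$t_mod)

  X <- cbind(A, B)
  assign_mat <- perm_assignments(n, na, n_perm, seed)
  n_used <- ncol(assign_mat)
  perm_abs <- vector("list", n_used)
  for (k in seq_len(n_used)) {
    ia <- assign_mat[, k]
    pk <- row_s0_t(X[, ia, drop = FALSE], X[, -ia, drop = FALSE], s0)
    perm_abs[[k]] <- abs(pk$t_mod)
  }
  perm_pool <- sort(unlist(perm_abs, use.names = FALSE))

  cand <- sort(unique(abs_obs))
  sorted_obs <- sort(abs_obs)
  n_obs_ge <- length(abs_obs) - findInterval(cand, sorted_obs, left.open = TRUE)
  n_perm_ge <- (length(perm_pool) -
                  findInterval(cand, perm_pool, left.open = TRUE)) / n_used
  raw_fdr <- n_perm_ge / n_obs_ge
  mono_fdr <- cummin(raw_fdr)  # non-increasing in the threshold

  pass <- which(raw_fdr <= fdr)
  threshold <- if (length(pass)) cand[min(pass)] else Inf
  significant <- abs_obs >= threshold

  out <- data.frame(
    protein_id = rownames(A) %||% as.character(seq_len(nrow(A))),
    difference = unname(obs$difference),
    t_mod = unname(obs$t_mod),
    p_raw = unname(obs$p_raw),
    significant = unname(significant),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "n_perm_used") <- n_used
  attr(out, "exhaustive") <-
    choose(n, na) - (if (na == nb) 2L else 1L) <= n_perm
  attr(out, "fdr_curve") <- data.frame(threshold = cand, fdr_raw = raw_fdr,
                                       fdr_mono = mono_fdr)
  out
}

#' Volcano differential analysis at one chase timepoint
#'
#' Wires sample selection to [permutation_fdr()] for a two-condition
#' comparison at a single chase timepoint (the paper-style contrast is the
#' degrader co-treatment versus the translation-inhibitor-only arm at the
#' end of the chase). Candidate targets are the significantly regulated
#' proteins with negative difference (lower in \code{cond_a}) together with
#' the \code{top_k} most strongly decreased proteins regardless of
#' significance — degraders often deplete their targets without reaching
#' proteome-wide significance.
#'
#' @param x a log2-scale [lfq_matrix()], normally after imputation so that
#'   every selected cell is present.
#' @param cond_a,cond_b condition labels; the difference is
#'   \code{cond_a - cond_b}.
#' @param timepoint_h chase timepoint to compare at (default 8).
#' @param s0,fdr,n_perm,seed passed to [permutation_fdr()].
#' @param top_k number of most-negative differences always included among
#'   candidates (default 10; 0 disables).
#' @param design optional design override; defaults to the design in \code{x}.
#' @return A data frame of class \code{volcano_table}, sorted by
#'   \code{|t_mod|} descending, with a \code{candidates} attribute holding
#'   the candidate protein ids; other attributes as [permutation_fdr()].
#' @export
volcano <- function(x, cond_a, cond_b, timepoint_h = 8, s0 = 0.1,
                    fdr = 0.05, n_perm = 250L, top_k = 10L, seed = 1L,
                    design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "log2") stopf("volcano expects a log2-scale matrix")
  design <- design %||% x$design
  sa <- design_samples(design, cond_a, timepoint_h)
  sb <- design_samples(design, cond_b, timepoint_h)
  if (length(sa) < 2L) {
    stopf("condition '%s' has < 2 samples at t = %s h", cond_a, timepoint_h)
  }
  if (length(sb) < 2L) {
    stopf("condition '%s' has < 2 samples at t = %s h", cond_b, timepoint_h)
  }
  A <- x$values[, sa, drop = FALSE]
  B <- x$values[, sb, drop = FALSE]
  keep <- rowSums(is.na(A)) == 0L & rowSums(is.na(B)) == 0L
  if (!all(keep)) {
    A <- A[keep, , drop = FALSE]
    B <- B[keep, , drop = FALSE]
  }
  res <- permutation_fdr(A, B, s0 = s0, fdr = fdr, n_perm = n_perm, seed = seed)
  ord <- order(-abs(res$t_mod), res$protein_id)
  out <- res[ord, , drop = FALSE]
  rownames(out) <- NULL

  cand <- out$protein_id[out$significant & out$difference < 0]
  if (top_k > 0L) {
    neg <- out[out$difference < 0, , drop = FALSE]
    neg <- neg[order(neg$difference, neg$protein_id), , drop = FALSE]
    cand <- union(cand, utils::head(neg$protein_id, top_k))
  }
  attr(out, "threshold") <- attr(res, "threshold")
  attr(out, "n_perm_used") <- attr(res, "n_perm_used")
  attr(out, "exhaustive") <- attr(res, "exhaustive")
  attr(out, "fdr_curve") <- attr(res, "fdr_curve")
  attr(out, "candidates") <- cand
  attr(out, "contrast") <- c(cond_a, cond_b)
  attr(out, "timepoint_h") <- timepoint_h
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' @export
print.volcano_table <- function(x, ...) {
  ctr <- attr(x, "contrast")
  cat(sprintf("Volcano: %s vs %s at t = %s h; %d proteins tested\n",
              ctr[1], ctr[2], attr(x, "timepoint_h"), nrow(x)))
  cat(sprintf("  |t_mod| threshold: %s (%s permutations%s)\n",
              format(attr(x, "threshold"), digits = 4),
              attr(x, "n_perm_used"),
              if (isTRUE(attr(x, "exhaustive"))) ", exhaustive" else ""))
  cat(sprintf("  significant: %d; candidate targets: %d\n",
              sum(x$significant), length(attr(x, "candidates"))))
  invisible(x)
}
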