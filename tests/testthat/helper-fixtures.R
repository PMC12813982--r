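# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no data files.

# A minimal chase design: CON baseline triplicate at t0 plus chase
# triplicates for the requested conditions over the given grid.
mini_design <- function(conditions = "CHX", timepoints = c(1, 2, 4),
                        n_rep = 3, con_chase = FALSE) {
  rows <- data.frame(sample_id = sprintf("CON_0h_r%d", seq_len(n_rep)),
                     condition = "CON", timepoint_h = 0,
                     replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  conds <- unique(c(if (con_chase) "CON", conditions))
  for (cn in conds) {
    for (tp in timepoints) {
      rows <- rbind(rows, data.frame(
        sample_id = sprintf("%s_%gh_r%d", cn, tp, seq_len(n_rep)),
        condition = cn, timepoint_h = tp, replicate = seq_len(n_rep),
        stringsAsFactors = FALSE))
    }
  }
  sample_design(rows$sample_id, rows$condition, rows$timepoint_h,
                rows$replicate)
}

# Linear-scale matrix with the given per-(condition, timepoint) generator.
mini_lfq <- function(design, gen, protein_ids = c("P1", "P2", "P3"),
                     flags = NULL) {
  vals <- matrix(NA_real_, nrow = length(protein_ids), ncol = nrow(design),
                 dimnames = list(protein_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    vals[, j] <- gen(design$condition[j], design$timepoint_h[j],
                     design$replicate[j])
  }
  lfq_matrix(vals, design, flags = flags, scale = "linear")
}

# Textbook pooled two-sample t statistic, written from the formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Brute-force permutation-FDR evaluator: explicit loops over every
# non-trivial split, protein by protein.
oracle_perm_fdr <- function(A, B, s0, fdr) {
  na <- ncol(A); nb <- ncol(B); n <- na + nb
  X <- cbind(A, B)
  s0t <- function(a, b) {
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    (mean(a) - mean(b)) / (se + s0)
  }
  obs <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) obs[i] <- s0t(A[i, ], B[i, ])

  splits <- utils::combn(n, na)
  keep <- logical(ncol(splits))
  for (j in seq_len(ncol(splits))) {
    cc <- splits[, j]
    is_obs <- identical(as.integer(cc), seq_len(na))
    is_swap <- (na == nb) && identical(as.integer(cc), seq.int(na + 1L, n))
    keep[j] <- !(is_obs || is_swap)
  }
  splits <- splits[, keep, drop = FALSE]

  perm_abs <- matrix(0, nrow = nrow(A), ncol = ncol(splits))
  for (j in seq_len(ncol(splits))) {
    ia <- splits[, j]
    for (i in seq_len(nrow(A))) {
      perm_abs[i, j] <- abs(s0t(X[i, ia], X[i, -ia]))
    }
  }

  cand <- sort(unique(abs(obs)))
  threshold <- Inf
  for (c0 in cand) {
    n_obs <- sum(abs(obs) >= c0)
    n_perm <- mean(colSums(perm_abs >= c0))
    if (n_perm / n_obs <= fdr) { threshold <- c0; break }
  }
  list(t_mod = obs, threshold = threshold, significant = abs(obs) >= threshold)
}

# Cell-by-cell profile-classification oracle, independently coded with
# explicit loops (band per replicate, strict mean decrease, full
# completeness).
oracle_classify <- function(pfr_vals, design, condition, band = c(80, 120)) {
  tps <- sort(unique(design$timepoint_h[design$condition == condition &
                                          design$timepoint_h > 0]))
  labs <- character(nrow(pfr_vals))
  for (i in seq_len(nrow(pfr_vals))) {
    per_tp <- list()
    complete <- TRUE
    for (tp in tps) {
      ids <- design$sample_id[design$condition == condition &
                                design$timepoint_h == tp]
      v <- pfr_vals[i, ids]
      if (any(is.na(v))) complete <- FALSE
      per_tp[[as.character(tp)]] <- v
    }
    if (!complete) { labs[i] <- "incomplete"; next }
    every <- unlist(per_tp)
    if (all(every >= band[1]) && all(every <= band[2])) {
      labs[i] <- "stable"; next
    }
    mm <- vapply(per_tp, mean, numeric(1))
    dec <- TRUE
    for (k in seq_along(mm)[-1]) if (!(mm[k] < mm[k - 1])) dec <- FALSE
    labs[i] <- if (dec) "decaying" else "other"
  }
  labs
}

write_pg_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
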