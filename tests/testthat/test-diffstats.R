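test_that("moderated t reduces to the textbook pooled t and damps with s0", {
  set.seed(31)
  for (k in 1:20) {
    a <- rnorm(sample(3:6, 1), mean = rnorm(1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:6, 1), mean = rnorm(1), sd = runif(1, 0.5, 2))
    r0 <- s0_t_statistic(a, b, s0 = 0)
    expect_equal(r0$t_mod, oracle_pooled_t(a, b), tolerance = 1e-12)
    # denominator monotonicity
    r1 <- s0_t_statistic(a, b, s0 = 1)
    expect_lt(abs(r1$t_mod), abs(r0$t_mod) + 1e-15)
    # sign agreement
    expect_identical(sign(r1$t_mod), sign(r1$difference))
  }

  ident <- s0_t_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.1)
  expect_equal(ident$difference, 0)
  expect_equal(ident$t_mod, 0)

  expect_error(s0_t_statistic(c(1, 1, 1), c(2, 2, 2), s0 = 0), "undefined")
  expect_error(s0_t_statistic(1, c(1, 2), s0 = 0.1), ">= 2")
})

test_that("permutation FDR matches an exhaustive brute-force oracle at 3 vs 3", {
  set.seed(97)
  m <- 50
  A <- matrix(rnorm(m * 3), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  B <- matrix(rnorm(m * 3), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  A[1:5, ] <- A[1:5, ] - 2          # planted decreases

  got <- permutation_fdr(A, B, s0 = 0.1, fdr = 0.05, n_perm = 250, seed = 5)
  exp <- oracle_perm_fdr(A, B, s0 = 0.1, fdr = 0.05)

  expect_true(attr(got, "exhaustive"))
  expect_equal(got$t_mod, exp$t_mod, tolerance = 1e-12)
  expect_equal(attr(got, "threshold"), exp$threshold, tolerance = 1e-12)
  expect_identical(got$significant, exp$significant)
  # calls exist and include planted proteins
  expect_gte(sum(got$significant), 1L)
  expect_true(any(sprintf("P%02d", 1:5) %in% got$protein_id[got$significant]))
})

test_that("identical groups yield zero significant proteins", {
  m <- 30
  V <- matrix(rnorm(m * 3), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  got <- permutation_fdr(V, V, s0 = 0.1, fdr = 0.05, n_perm = 250, seed = 1)
  expect_equal(got$t_mod, rep(0, m))
  expect_false(any(got$significant))
})

test_that("the FDR curve is monotone and the engine has no cross-protein leakage", {
  set.seed(13)
  m <- 40
  A <- matrix(rnorm(m * 3), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  B <- matrix(rnorm(m * 3, -0.5), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  got <- permutation_fdr(A, B, seed = 3)
  curve <- attr(got, "fdr_curve")
  expect_true(all(diff(curve$fdr_mono) <= 1e-15))

  # permuting the protein order permutes the rows identically
  ord <- sample(m)
  got2 <- permutation_fdr(A[ord, , drop = FALSE], B[ord, , drop = FALSE],
                          seed = 3)
  expect_identical(got2$protein_id, got$protein_id[ord])
  expect_equal(got2$t_mod, got$t_mod[ord], tolerance = 1e-12)
  expect_identical(got2$significant, got$significant[ord])
  expect_equal(attr(got2, "threshold"), attr(got, "threshold"),
               tolerance = 1e-12)
})

test_that("the permutation sampler is seeded and samples distinct assignments", {
  set.seed(55)
  m <- 25
  A <- matrix(rnorm(m * 5), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  B <- matrix(rnorm(m * 5), nrow = m,
              dimnames = list(sprintf("P%02d", 1:m), NULL))
  # choose(10, 5) - 2 = 250 distinct non-trivial splits; sample 100
  r1 <- permutation_fdr(A, B, n_perm = 100, seed = 9)
  r2 <- permutation_fdr(A, B, n_perm = 100, seed = 9)
  expect_false(attr(r1, "exhaustive"))
  expect_identical(attr(r1, "n_perm_used"), 100L)
  expect_identical(r1, r2)
})

test_that("volcano ranks planted shifts first and honors top_k", {
  design <- mini_design(c("CHX", "CHX_PROTAC"), timepoints = c(4, 8))
  set.seed(77)
  n <- 60
  base <- rnorm(n, 25, 2)
  vals <- matrix(base + rnorm(n * nrow(design), 0, 0.1), nrow = n,
                 dimnames = list(sprintf("P%02d", 1:n), design$sample_id))
  treat8 <- design_samples(design, "CHX_PROTAC", 8)
  vals[1:5, treat8] <- vals[1:5, treat8] - 2      # 2 log2 units down
  x <- lfq_matrix(vals, design, scale = "log2")

  v <- volcano(x, "CHX_PROTAC", "CHX", timepoint_h = 8, seed = 2)
  most_negative <- v$protein_id[order(v$difference)][1:5]
  expect_setequal(most_negative, sprintf("P%02d", 1:5))
  expect_true(all(sprintf("P%02d", 1:5) %in% attr(v, "candidates")))
  expect_identical(v$protein_id[order(-abs(v$t_mod), v$protein_id)],
                   v$protein_id)  # sorted by |t_mod| descending

  # same condition on both sides: all differences zero, nothing significant
  v0 <- volcano(x, "CHX", "CHX", timepoint_h = 8, top_k = 0, seed = 2)
  expect_equal(v0$difference, rep(0, n))
  expect_length(attr(v0, "candidates"), 0)

  expect_error(volcano(x, "CHX_PROTAC", "CHX", timepoint_h = 2), "< 2 samples")
})
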