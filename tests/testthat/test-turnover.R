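test_that("PFR normalizes to the CON t0 baseline and guards its inputs", {
  design <- mini_design("CHX", timepoints = c(1, 2))
  gen <- function(cond, tp, r) {
    if (cond == "CON") c(1e6, 2e6, 4e6)
    else c(1e6, 1e6, NA) * c(1, 0.5, 1)
  }
  x <- mini_lfq(design, gen)
  pfr <- compute_pfr(x)
  chx1 <- design_samples(design, "CHX", 1)[1]
  expect_equal(unname(pfr$pfr["P1", chx1]), 100)   # equal to baseline
  expect_equal(unname(pfr$pfr["P2", chx1]), 25)    # half of 2e6 over 2e6? no: 1e6*0.5/2e6
  expect_true(all(is.na(pfr$pfr["P3", design_samples(design, "CHX", 1)])))

  # all-missing baseline drops the protein
  vals <- x$values
  vals["P3", design_samples(design, "CON", 0)] <- NA
  y <- lfq_matrix(vals, design)
  expect_false("P3" %in% rownames(compute_pfr(y)$pfr))

  # wiring guards: log2-scale and imputed matrices are refused
  expect_error(compute_pfr(log2_transform(x)), "linear")
  imp <- x
  imp$imputed <- TRUE
  expect_error(compute_pfr(imp), "imputed")
  expect_error(fit_first_order(imp, "CHX"), "imputed")
})

test_that("profile classification applies the strict band/decrease rules", {
  design <- mini_design("CHX", timepoints = c(0.5, 1, 2, 4, 8))
  ids <- c("stableP", "decayP", "otherP", "incompP")
  vals <- matrix(NA_real_, 4, nrow(design),
                 dimnames = list(ids, design$sample_id))
  profiles <- list(stableP = c(92, 95, 108, 99, 103),
                   decayP = c(90, 80, 65, 40, 20),
                   otherP = c(100, 85, 90, 70, 50),
                   incompP = c(90, 80, 65, 40, 20))
  for (j in seq_len(nrow(design))) {
    tp <- design$timepoint_h[j]
    for (id in ids) {
      vals[id, j] <- if (design$condition[j] == "CON") 1e6
                     else 1e6 * profiles[[id]][match(tp, c(0.5, 1, 2, 4, 8))] / 100
    }
  }
  vals["incompP", design_samples(design, "CHX", 2)[1]] <- NA
  x <- lfq_matrix(vals, design)
  cl <- classify_profiles(compute_pfr(x), "CHX")
  got <- setNames(cl$label, cl$protein_id)
  expect_identical(unname(got[ids]),
                   c("stable", "decaying", "other", "incomplete"))
})

test_that("classification agrees with the brute-force oracle on a random fixture", {
  design <- mini_design(c("CHX"), timepoints = c(0.5, 1, 2, 4, 8),
                        con_chase = TRUE)
  set.seed(2024)
  n <- 200
  kdeg <- rlnorm(n, log(log(2) / 10), 1.2)
  steady <- rlnorm(n, log(1e7), 1)
  vals <- matrix(NA_real_, n, nrow(design),
                 dimnames = list(sprintf("P%03d", 1:n), design$sample_id))
  for (j in seq_len(nrow(design))) {
    tp <- design$timepoint_h[j]
    mu <- if (design$condition[j] == "CON") steady else steady * exp(-kdeg * tp)
    vals[, j] <- mu * rlnorm(n, 0, 0.15)
  }
  vals[sample(length(vals), 250)] <- NA
  vals[, design_samples(design, "CON", 0)[1]] <- steady   # keep baselines
  x <- lfq_matrix(vals, design)
  pfr <- compute_pfr(x)

  for (cond in c("CHX", "CON")) {
    got <- classify_profiles(pfr, cond)
    expected <- oracle_classify(pfr$pfr, design, cond)
    expect_identical(got$label, expected)
    # partition: labels exhaustive over proteins with PFR rows
    expect_identical(sort(unique(got$label %in%
      c("stable", "decaying", "incomplete", "other"))), TRUE)
    expect_identical(nrow(got), nrow(pfr$pfr))
  }
})

test_that("first-order fits recover exact exponentials and handle edge cases", {
  design <- mini_design("CHX", timepoints = c(0.5, 1, 2, 4, 8))
  gen <- function(cond, tp, r) {
    if (cond == "CON") c(1e7, 1e7, 1e7)
    else c(1e7 * exp(-0.2 * tp),          # kdeg 0.2/h
           1e7,                            # constant
           1e7 * exp(+0.05 * tp))          # increasing
  }
  x <- mini_lfq(design, gen)
  fits <- fit_first_order(x, "CHX")

  expect_s3_class(fits, "decay_fits")
  expect_equal(fits$kdeg[1], 0.2, tolerance = 1e-12)
  expect_equal(fits$t_half[1], log(2) / 0.2, tolerance = 1e-12)
  expect_equal(fits$r2[1], 1, tolerance = 1e-12)
  expect_equal(fits$n_points[1], 15L)

  expect_equal(fits$kdeg[2], 0, tolerance = 1e-12)
  expect_true(is.na(fits$t_half[2]))

  expect_equal(fits$kdeg[3], -0.05, tolerance = 1e-12)
  expect_true(is.na(fits$t_half[3]))
  expect_false(any(fits$excluded_long))

  # < 3 points: no fit reported
  vals <- x$values
  chx <- design$sample_id[design$condition == "CHX"]
  vals["P1", chx[-(1:2)]] <- NA
  f2 <- fit_first_order(lfq_matrix(vals, design), "CHX")
  expect_true(is.na(f2$kdeg[1]))
  expect_identical(f2$n_points[1], 2L)

  # imputed and log2 matrices are rejected
  expect_error(fit_first_order(log2_transform(x), "CHX"), "linear")
})

test_that("fits are scale-equivariant and obey the two-point closed form", {
  design <- mini_design("CHX", timepoints = c(1, 2, 4))
  set.seed(5)
  noisy <- rlnorm(9, 0, 0.2)
  gen <- function(cond, tp, r) {
    i <- which(c(1, 2, 4) == tp)
    if (cond == "CON") c(1e7, 1e7)
    else 1e7 * exp(-0.3 * tp) * noisy[3 * (i - 1) + r] * c(1, 1)
  }
  x <- mini_lfq(design, gen, protein_ids = c("A", "B"))
  # multiply protein B by a constant
  x$values["B", ] <- x$values["B", ] * 37.5
  fits <- fit_first_order(x, "CHX")
  expect_equal(fits$kdeg[1], fits$kdeg[2], tolerance = 1e-12)
  expect_equal(fits$r2[1], fits$r2[2], tolerance = 1e-12)
  expect_equal(fits$intercept[2] - fits$intercept[1], log(37.5),
               tolerance = 1e-12)

  # two distinct timepoints, >= 3 points: slope equals the secant of the means
  design2 <- mini_design("CHX", timepoints = c(1, 4), n_rep = 2)
  i1 <- 2e6; i2 <- 5e5
  gen2 <- function(cond, tp, r) if (cond == "CON") 1e6
                                else if (tp == 1) i1 else i2
  x2 <- mini_lfq(design2, gen2, protein_ids = "A")
  f2 <- fit_first_order(x2, "CHX")
  expect_equal(-f2$kdeg[1], (log(i2) - log(i1)) / (4 - 1), tolerance = 1e-12)
})

test_that("half-life conversion and the 60 h exclusion flag behave", {
  expect_equal(half_life_from_rate(log(2)), 1)
  expect_equal(half_life_from_rate(0.0693147), 10, tolerance = 1e-6)
  expect_true(is.na(half_life_from_rate(0)))
  expect_true(is.na(half_life_from_rate(-1)))

  design <- mini_design("CHX", timepoints = c(1, 2, 4, 8))
  gen <- function(cond, tp, r) {
    if (cond == "CON") c(1e7, 1e7)
    else c(1e7 * exp(-0.004 * tp), 1e7 * exp(-0.2 * tp))  # t1/2 173 h vs 3.5 h
  }
  x <- mini_lfq(design, gen, protein_ids = c("slow", "fast"))
  fits <- fit_first_order(x, "CHX")
  expect_identical(fits$excluded_long, c(TRUE, FALSE))
  expect_equal(fits$t_half[1], log(2) / 0.004, tolerance = 1e-9)  # retained
})

test_that("half-life differences join, sort and rank correctly", {
  mk_fits <- function(ids, th, excl = FALSE) {
    structure(data.frame(protein_id = ids, condition = "X",
                         kdeg = log(2) / th, t_half = th, intercept = 0,
                         r2 = 1, n_points = 15L,
                         excluded_long = rep_len(excl, length(ids)),
                         stringsAsFactors = FALSE),
              class = c("decay_fits", "data.frame"))
  }
  ref <- mk_fits(c("A", "B", "C", "D"), c(20, 12, 30, 80),
                 excl = c(FALSE, FALSE, FALSE, TRUE))
  treat <- mk_fits(c("A", "B", "E"), c(10, 12, 4))
  d <- delta_half_life(ref, treat)

  expect_identical(d$protein_id, c("A", "B"))       # C, E unmatched; D excluded
  expect_equal(d$delta, c(10, 0))
  expect_identical(d$rank, 1:2)
  # undefined half-life never enters
  ref$t_half[1] <- NA
  expect_identical(delta_half_life(ref, treat)$protein_id, "B")
})

test_that("decay_fits model methods are coherent", {
  design <- mini_design("CHX", timepoints = c(0.5, 1, 2, 4, 8))
  gen <- function(cond, tp, r) {
    if (cond == "CON") c(1e7, 2e6) else c(1e7, 2e6) * exp(-c(0.2, 0.5) * tp)
  }
  x <- mini_lfq(design, gen, protein_ids = c("A", "B"))
  fits <- fit_first_order(x, "CHX")

  co <- coef(fits)
  expect_identical(rownames(co), c("A", "B"))
  expect_equal(unname(co["A", "kdeg"]), 0.2, tolerance = 1e-12)

  pred <- predict(fits, times = c(0, 2))
  expect_equal(unname(pred["B", "2"]), 2e6 * exp(-1), tolerance = 1e-9)
  expect_equal(unname(pred["A", "0"]), 1e7, tolerance = 1e-6)

  expect_lt(max(abs(residuals(fits))), 1e-10)       # noiseless input
  s <- summary(fits)
  expect_s3_class(s, "summary.decay_fits")
  expect_identical(s$n_fitted, 2L)
  expect_output(print(s), "Condition CHX")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fits, protein = "A"))
})
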