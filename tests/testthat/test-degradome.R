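test_that("target discovery intersects candidates with decaying kinetics", {
  v <- data.frame(protein_id = c("A", "B", "C"),
                  difference = c(-2, -1, 0.5),
                  t_mod = c(-8, -4, 2),
                  p_raw = c(1e-4, 1e-3, 0.1),
                  significant = c(TRUE, TRUE, FALSE))
  attr(v, "candidates") <- c("A", "B")
  cl <- data.frame(protein_id = c("A", "B", "C"),
                   condition = "CHX_PROTAC",
                   label = c("decaying", "stable", "decaying"))
  got <- discover_targets(v, cl)
  expect_identical(got$candidates, c("A", "B"))
  expect_identical(got$verified, "A")          # B stable -> excluded
  expect_true(all(got$verified %in% got$candidates))

  # empty volcano -> both sets empty
  v0 <- v[0, ]
  attr(v0, "candidates") <- character(0)
  got0 <- discover_targets(v0, cl)
  expect_length(got0$candidates, 0)
  expect_length(got0$verified, 0)
})

test_that("rescue calls depend on depletion and restoration thresholds", {
  design <- sample_design(
    sample_id = c(sprintf("CON_0h_r%d", 1:2), sprintf("CON_4h_r%d", 1:2),
                  sprintf("PROTAC_4h_r%d", 1:2),
                  sprintf("BORT_PROTAC_4h_r%d", 1:2)),
    condition = rep(c("CON", "CON", "PROTAC", "BORT_PROTAC"), each = 2),
    timepoint_h = rep(c(0, 4, 4, 4), each = 2),
    replicate = rep(1:2, 4))
  # per protein: (r_protac, r_rescue) relative to CON at 4 h
  ratios <- list(A = c(0.3, 1.0),   # depleted and restored -> rescued
                 B = c(0.3, 0.4),   # depleted, not restored
                 C = c(0.95, 1.0))  # no depletion to rescue
  vals <- matrix(NA_real_, 3, nrow(design),
                 dimnames = list(names(ratios), design$sample_id))
  for (j in seq_len(nrow(design))) {
    for (p in names(ratios)) {
      base <- 1e7
      vals[p, j] <- switch(design$condition[j],
        CON = base,
        PROTAC = base * ratios[[p]][1],
        BORT_PROTAC = base * ratios[[p]][2])
    }
  }
  x <- lfq_matrix(vals, design)
  got <- rescue_check(x, c("A", "B", "C"))
  expect_identical(got$rescued, c(TRUE, FALSE, FALSE))
  expect_identical(got$depleted, c(TRUE, TRUE, FALSE))
  expect_equal(got$r_protac, c(0.3, 0.3, 0.95), tolerance = 1e-12)

  # missing arm is fatal and names the arm
  d2 <- design[design$condition != "BORT_PROTAC", ]
  x2 <- lfq_matrix(vals[, d2$sample_id], d2)
  expect_error(rescue_check(x2, "A"), "BORT_PROTAC")
})

test_that("decaying-set overlaps satisfy inclusion-exclusion exactly", {
  mk_classes <- function(dec, all_ids) {
    data.frame(protein_id = all_ids, condition = "X",
               label = ifelse(all_ids %in% dec, "decaying", "stable"))
  }
  ids <- sprintf("P%02d", 1:26)
  got <- compare_decaying_sets(list(
    X = mk_classes(c("P01", "P02", "P03"), ids),
    Y = mk_classes(c("P02", "P03", "P04"), ids)))
  expect_identical(lengths(got$unique_sets), c(X = 1L, Y = 1L))
  oc <- setNames(got$overlap_counts$n, got$overlap_counts$conditions)
  expect_identical(oc[["X&Y"]], 2L)
  expect_identical(oc[["X"]], 3L)

  # identical sets -> no uniques
  same <- compare_decaying_sets(list(X = mk_classes(c("P01", "P02"), ids),
                                     Y = mk_classes(c("P01", "P02"), ids)))
  expect_identical(lengths(same$unique_sets), c(X = 0L, Y = 0L))

  # three random sets vs brute-force membership tabulation
  set.seed(11)
  sets <- lapply(1:3, function(i) sample(ids, sample(5:15, 1)))
  names(sets) <- c("A", "B", "C")
  got3 <- compare_decaying_sets(lapply(sets, mk_classes, all_ids = ids))
  oc3 <- setNames(got3$overlap_counts$n, got3$overlap_counts$conditions)
  brute <- function(subset) {
    sum(vapply(ids, function(id) {
      all(vapply(subset, function(s) id %in% sets[[s]], logical(1)))
    }, logical(1)))
  }
  for (k in seq_along(got3$overlap_counts$conditions)) {
    subset <- strsplit(got3$overlap_counts$conditions[k], "&", fixed = TRUE)[[1]]
    expect_identical(oc3[[k]], brute(subset))
  }
  # inclusion-exclusion: |A u B u C| from pairwise/triple intersections
  union_size <- length(Reduce(union, sets))
  ie <- oc3[["A"]] + oc3[["B"]] + oc3[["C"]] - oc3[["A&B"]] - oc3[["A&C"]] -
    oc3[["B&C"]] + oc3[["A&B&C"]]
  expect_identical(as.integer(ie), union_size)
})

test_that("half-life medians drop undefined and over-cap values", {
  mk_fits <- function(ids, th) {
    data.frame(protein_id = ids, condition = "X", kdeg = log(2) / th,
               t_half = th, intercept = 0, r2 = 1, n_points = 15L,
               excluded_long = !is.na(th) & th > 60,
               stringsAsFactors = FALSE)
  }
  fits <- list(CHX = mk_fits(c("A", "B", "C"), c(5, 10, 70)),
               CHX_PROTAC = mk_fits(c("D", "E"), c(12, 65)))
  us <- list(CHX = c("A", "B", "C"), CHX_PROTAC = c("D", "E"))
  got <- summarize_half_lives(fits, us)
  expect_equal(got$median_t_half[got$condition == "CHX"], 7.5)
  expect_identical(got$n[got$condition == "CHX"], 2L)
  expect_equal(got$median_t_half[got$condition == "CHX_PROTAC"], 12)

  # everything excluded -> undefined median, count 0
  all_long <- summarize_half_lives(list(Z = mk_fits("A", 70)),
                                   list(Z = "A"))
  expect_identical(all_long$n, 0L)
  expect_true(is.na(all_long$median_t_half))
})
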