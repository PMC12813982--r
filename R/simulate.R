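#' Configuration for the steady-state turnover simulator
#'
#' Parameters of the generative model behind [simulate_chase()]. Protein
#' turnover is zero-order synthesis plus first-order degradation,
#' \eqn{dI/dt = k_{syn} - k_{deg} I}; at steady state \eqn{I = k_{syn}/k_{deg}}.
#' Blocking synthesis (the CHX arms) leaves pure exponential decay
#' \eqn{I(t) = I_0 e^{-k_{deg} t}}. Degrader targets get their degradation
#' rate multiplied by an acceleration factor.
#'
#' @param n_proteins number of proteins.
#' @param fraction_targets fraction of proteins that are degrader targets
#'   (default 0).
#' @param timepoints_h ascending chase grid starting at 0 (default
#'   \code{c(0, 0.5, 1, 2, 4, 8)}).
#' @param n_replicates replicates per condition/timepoint (default 3).
#' @param abundance_model list \code{(meanlog, sdlog)} of the log-normal
#'   steady-state intensity distribution. Defaults centre on 1e7 with
#'   sdlog 2, spanning the orders of magnitude typical of LFQ intensities.
#' @param kdeg_model list \code{(meanlog, sdlog)} of the log-normal basal
#'   degradation-rate distribution. Default median \code{log(2)/15} (a 15 h
#'   median half-life, the scale of a nonproliferative steady-state
#'   proteome) with sdlog 1.
#' @param acceleration_model list \code{(min, max)} of the uniform
#'   multiplicative factor applied to target degradation rates (default
#'   3–10; set \code{min == max} for a fixed factor).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   measurement noise (default 0.10).
#' @param missing_mnar_quantile intensity quantile below which noisy values
#'   drop out (missing not at random, detection limit; default 0.05).
#' @param missing_mar_rate per-cell probability of random dropout (missing
#'   at random; default 0.01).
#' @param include_rescue_arms add degrader-only (\code{PROTAC}) and
#'   proteasome-inhibitor (\code{BORT_PROTAC}) arms at the rescue endpoint.
#' @param rescue_endpoint_h rescue endpoint (default 4 h).
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_proteins = 1000,
                              fraction_targets = 0,
                              timepoints_h = c(0, 0.5, 1, 2, 4, 8),
                              n_replicates = 3,
                              abundance_model = list(meanlog = log(1e7), sdlog = 2),
                              kdeg_model = list(meanlog = log(log(2) / 15), sdlog = 1),
                              acceleration_model = list(min = 3, max = 10),
                              noise_cv = 0.10,
                              missing_mnar_quantile = 0.05,
                              missing_mar_rate = 0.01,
                              include_rescue_arms = FALSE,
                              rescue_endpoint_h = 4,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              fraction_targets = fraction_targets,
              timepoints_h = as.numeric(timepoints_h),
              n_replicates = as.integer(n_replicates),
              abundance_model = abundance_model,
              kdeg_model = kdeg_model,
              acceleration_model = acceleration_model,
              noise_cv = noise_cv,
              missing_mnar_quantile = missing_mnar_quantile,
              missing_mar_rate = missing_mar_rate,
              include_rescue_arms = isTRUE(include_rescue_arms),
              rescue_endpoint_h = rescue_endpoint_h,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stopf("n_proteins must be >= 1")
  if (cfg$fraction_targets < 0 || cfg$fraction_targets > 1) {
    stopf("fraction_targets must be in [0, 1]")
  }
  if (cfg$fraction_targets > 0 &&
      round(cfg$fraction_targets * cfg$n_proteins) < 1) {
    stopf("fraction_targets * n_proteins must be >= 1 when targets are requested")
  }
  tp <- cfg$timepoints_h
  if (length(tp) < 2L || tp[1] != 0 || is.unsorted(tp, strictly = TRUE)) {
    stopf("timepoints_h must be a strictly ascending grid starting at 0")
  }
  if (cfg$n_replicates < 1L) stopf("n_replicates must be >= 1")
  if (cfg$noise_cv < 0) stopf("noise_cv must be >= 0")
  if (cfg$missing_mnar_quantile < 0 || cfg$missing_mnar_quantile >= 1) {
    stopf("missing_mnar_quantile must be in [0, 1)")
  }
  if (cfg$missing_mar_rate < 0 || cfg$missing_mar_rate >= 1) {
    stopf("missing_mar_rate must be in [0, 1)")
  }
  with(cfg$acceleration_model, {
    if (min <= 0 || max < min) stopf("acceleration_model must satisfy 0 < min <= max")
  })
  if (cfg$kdeg_model$sdlog < 0 || cfg$abundance_model$sdlog < 0) {
    stopf("sdlog parameters must be >= 0")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a cycloheximide chase LFQ dataset with ground truth
#'
#' Generates the arms of a chase experiment from the steady-state turnover
#' model:
#' \itemize{
#'   \item \code{CON} — vehicle control at steady state: intensity constant
#'     at \eqn{I = k_{syn}/k_{deg}} over the whole grid (including t = 0,
#'     the PFR baseline);
#'   \item \code{CHX} — synthesis blocked: \eqn{I_0 e^{-k_{deg} t}} over the
#'     chase timepoints;
#'   \item \code{CHX_PROTAC} — synthesis blocked, target degradation
#'     accelerated: \eqn{I_0 e^{-k^{treat}_{deg} t}};
#'   \item \code{PROTAC} (rescue arm, optional) — synthesis ongoing,
#'     degradation accelerated: the turnover ODE relaxes toward the new
#'     steady state, \eqn{I(t) = I_0 [\,k_{deg}/k^{treat}_{deg} +
#'     (1 - k_{deg}/k^{treat}_{deg})\, e^{-k^{treat}_{deg} t}\,]};
#'   \item \code{BORT_PROTAC} (rescue arm, optional) — proteasome inhibition
#'     blocks the degrader-induced acceleration, so the basal steady state
#'     persists: intensity stays at \eqn{I_0}.
#' }
#' Every measurement is the model value times an independent log-normal
#' noise factor with coefficient of variation \code{noise_cv}
#' (\eqn{\sigma = \sqrt{\ln(1 + CV^2)}}, unit mean). Missingness is applied
#' MNAR first (noisy values below the \code{missing_mnar_quantile} of the
#' full value distribution drop out — a detection limit), then MAR
#' (independent Bernoulli dropout); a cell is missing at most once.
#'
#' @param config a [simulation_config()].
#' @return List with \code{lfq} (linear-scale [lfq_matrix()]),
#'   \code{design} ([sample_design()]) and \code{truth} (data frame with
#'   per-protein \code{steady_intensity}, \code{kdeg_basal},
#'   \code{is_target}, \code{kdeg_treated}, \code{t_half_basal},
#'   \code{t_half_treated}, \code{ksyn}).
#' @examples
#' sim <- simulate_chase(simulation_config(n_proteins = 50, seed = 7))
#' sim$lfq
#' @export
simulate_chase <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proteins
  ids <- sprintf("P%05d", seq_len(n))

  tp <- config$timepoints_h
  chase_tp <- tp[tp > 0]
  reps <- seq_len(config$n_replicates)
  grid <- rbind(
    expand.grid(condition = "CON", timepoint_h = tp, replicate = reps,
                stringsAsFactors = FALSE),
    expand.grid(condition = "CHX", timepoint_h = chase_tp, replicate = reps,
                stringsAsFactors = FALSE),
    expand.grid(condition = "CHX_PROTAC", timepoint_h = chase_tp,
                replicate = reps, stringsAsFactors = FALSE)
  )
  if (config$include_rescue_arms) {
    grid <- rbind(grid,
      expand.grid(condition = c("PROTAC", "BORT_PROTAC"),
                  timepoint_h = config$rescue_endpoint_h, replicate = reps,
                  stringsAsFactors = FALSE))
  }
  grid$sample_id <- sprintf("%s_%gh_r%d", grid$condition, grid$timepoint_h,
                            grid$replicate)
  design <- sample_design(grid$sample_id, grid$condition, grid$timepoint_h,
                          grid$replicate)

  with_seed(config$seed, {
    steady <- stats::rlnorm(n, config$abundance_model$meanlog,
                            config$abundance_model$sdlog)
    kdeg_basal <- stats::rlnorm(n, config$kdeg_model$meanlog,
                                config$kdeg_model$sdlog)
    n_targets <- round(config$fraction_targets * n)
    is_target <- logical(n)
    if (n_targets > 0) is_target[sample.int(n, n_targets)] <- TRUE
    factor <- rep(1, n)
    am <- config$acceleration_model
    factor[is_target] <- stats::runif(sum(is_target), am$min, am$max)
    kdeg_treated <- kdeg_basal * factor

    model_value <- function(cond, t) {
      switch(cond,
        CON = steady,
        CHX = steady * exp(-kdeg_basal * t),
        CHX_PROTAC = steady * exp(-kdeg_treated * t),
        PROTAC = {
          ratio <- kdeg_basal / kdeg_treated
          steady * (ratio + (1 - ratio) * exp(-kdeg_treated * t))
        },
        BORT_PROTAC = steady,
        stopf("unknown condition '%s'", cond))
    }

    vals <- matrix(NA_real_, nrow = n, ncol = nrow(design),
                   dimnames = list(ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      vals[, j] <- model_value(design$condition[j], design$timepoint_h[j])
    }
    if (config$noise_cv > 0) {
      sigma <- sqrt(log(1 + config$noise_cv^2))
      noise <- matrix(stats::rlnorm(length(vals), -sigma^2 / 2, sigma),
                      nrow = n)
      vals <- vals * noise
    }
    if (config$missing_mnar_quantile > 0) {
      cut <- stats::quantile(vals, config$missing_mnar_quantile, names = FALSE)
      vals[vals < cut] <- NA_real_
    }
    if (config$missing_mar_rate > 0) {
      mar <- matrix(stats::runif(length(vals)) < config$missing_mar_rate,
                    nrow = n)
      vals[mar & !is.na(vals)] <- NA_real_
    }

    truth <- data.frame(
      protein_id = ids,
      steady_intensity = steady,
      kdeg_basal = kdeg_basal,
      is_target = is_target,
      kdeg_treated = kdeg_treated,
      t_half_basal = half_life_from_rate(kdeg_basal),
      t_half_treated = half_life_from_rate(kdeg_treated),
      ksyn = steady * kdeg_basal,
      stringsAsFactors = FALSE
    )

    lfq <- lfq_matrix(vals, design,
                      gene_symbol = sprintf("GENE%05d", seq_len(n)),
                      scale = "linear")
    list(lfq = lfq, design = design, truth = truth)
  })
}

#' Bundled deterministic demonstration datasets
#'
#' Small simulated datasets regenerated from fixed seeds, used in unit tests
#' and documentation:
#' \describe{
#'   \item{tiny_clean}{20 proteins, noiseless, no missingness, no targets.}
#'   \item{tiny_missing}{30 proteins, 10\% CV noise with default MNAR/MAR
#'     dropout.}
#'   \item{targets_demo}{200 proteins, 10 degrader targets with a fixed
#'     5-fold degradation acceleration, 10\% CV noise, no dropout.}
#'   \item{rescue_demo}{100 proteins including degrader-only and
#'     proteasome-inhibitor arms at 4 h, 10 targets (5-fold), noiseless, a
#'     narrow half-life distribution.}
#' }
#'
#' @param name one of \code{"tiny_clean"}, \code{"tiny_missing"},
#'   \code{"targets_demo"}, \code{"rescue_demo"}.
#' @return A [simulate_chase()] result list.
#' @export
make_fixture <- function(name = c("tiny_clean", "tiny_missing",
                                  "targets_demo", "rescue_demo")) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny_clean = simulation_config(
      n_proteins = 20, noise_cv = 0, missing_mnar_quantile = 0,
      missing_mar_rate = 0, seed = 101L),
    tiny_missing = simulation_config(
      n_proteins = 30, noise_cv = 0.10, seed = 102L),
    targets_demo = simulation_config(
      n_proteins = 200, fraction_targets = 0.05,
      acceleration_model = list(min = 5, max = 5), noise_cv = 0.10,
      missing_mnar_quantile = 0, missing_mar_rate = 0, seed = 103L),
    rescue_demo = simulation_config(
      n_proteins = 100, fraction_targets = 0.10,
      acceleration_model = list(min = 5, max = 5), noise_cv = 0,
      missing_mnar_quantile = 0, missing_mar_rate = 0,
      kdeg_model = list(meanlog = log(log(2) / 15), sdlog = 0.2),
      include_rescue_arms = TRUE, seed = 104L)
  )
  simulate_chase(cfg)
}

#' Write a simulated dataset as pipeline input files
#'
#' Emits the same protein-groups dialect that [read_protein_groups()]
#' consumes, plus the design table and the ground truth, so the pipeline
#' runs unmodified on simulated data.
#'
#' @param sim a [simulate_chase()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (\code{protein_groups.tsv},
#'   \code{design.tsv}, \code{ground_truth.tsv}).
#' @export
write_chase_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- sim$lfq$values
  tab <- data.frame(`Majority protein IDs` = rownames(v),
                    `Gene names` = unname(sim$lfq$gene_symbol %||%
                                            rep("", nrow(v))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(v)) tab[[paste("LFQ intensity", s)]] <- v[, s]
  tab[["Reverse"]] <- ifelse(sim$lfq$flags$reverse, "+", "")
  tab[["Potential contaminant"]] <- ifelse(sim$lfq$flags$contaminant, "+", "")
  tab[["Only identified by site"]] <- ifelse(sim$lfq$flags$only_by_site, "+", "")

  paths <- c(protein_groups = file.path(dir, "protein_groups.tsv"),
             design = file.path(dir, "design.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_table(tab, paths["protein_groups"])
  write_table(as.data.frame(sim$design), paths["design"])
  write_table(sim$truth, paths["ground_truth"])
  invisible(paths)
}
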