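#' Read a run-configuration file
#'
#' Loads a YAML run configuration and fills defaults. The configuration has
#' nested sections: exactly one of \code{input} (paths
#' \code{protein_groups}, \code{design}) or \code{simulate} (fields of
#' [simulation_config()]); optional \code{imputation} (\code{downshift}
#' 1.8, \code{width} 0.3), \code{volcano} (\code{cond_a CHX_PROTAC},
#' \code{cond_b CHX}, \code{timepoint_h} 8, \code{s0} 0.1, \code{fdr} 0.05,
#' \code{n_perm} 250, \code{top_k} 10), \code{turnover}
#' (\code{stability_low} 80, \code{stability_high} 120,
#' \code{decrease_tolerance} 0, \code{max_half_life_h} 60, \code{band_mode}
#' replicate), \code{rescue} (\code{endpoint_h} 4,
#' \code{depletion_threshold} 0.7, \code{rescue_threshold} 0.8); and
#' top-level \code{seed} and \code{output_dir}.
#'
#' @param path path to a YAML file.
#' @return A validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  build_run_config(yaml::read_yaml(path))
}

#' Assemble a run configuration from a list
#'
#' Programmatic counterpart of [read_run_config()].
#'
#' @param config nested list, see [read_run_config()].
#' @return A validated configuration list of class \code{run_config}.
#' @export
build_run_config <- function(config) {
  defaults <- list(
    seed = 1L,
    output_dir = "protchase_out",
    imputation = list(downshift = 1.8, width = 0.3),
    volcano = list(cond_a = "CHX_PROTAC", cond_b = "CHX", timepoint_h = 8,
                   s0 = 0.1, fdr = 0.05, n_perm = 250L, top_k = 10L),
    turnover = list(stability_low = 80, stability_high = 120,
                    decrease_tolerance = 0, max_half_life_h = 60,
                    band_mode = "replicate"),
    rescue = list(endpoint_h = 4, depletion_threshold = 0.7,
                  rescue_threshold = 0.8)
  )
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      user <- config[[sec]] %||% list()
      merged <- defaults[[sec]]
      merged[names(user)] <- user
      config[[sec]] <- merged
    } else if (is.null(config[[sec]])) {
      config[[sec]] <- defaults[[sec]]
    }
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stopf("config must contain exactly one of 'input' or 'simulate'")
  }
  if (has_input) {
    for (p in c("protein_groups", "design")) {
      if (is.null(config$input[[p]])) stopf("config$input lacks '%s'", p)
      if (!file.exists(config$input[[p]])) {
        stopf("input file not found: %s", config$input[[p]])
      }
    }
  }
  class(config) <- "run_config"
  config
}

sim_config_from_list <- function(lst, seed) {
  lst$seed <- lst$seed %||% derive_seed(seed, 3L)
  do.call(simulation_config, lst)
}

#' Simulate a dataset and write it to disk
#'
#' Orchestration command: builds the simulator configuration from the
#' \code{simulate} section of a run configuration, generates the dataset
#' and writes \code{protein_groups.tsv}, \code{design.tsv} and
#' \code{ground_truth.tsv} to the output directory.
#'
#' @param config a \code{run_config} (list or path to YAML) with a
#'   \code{simulate} section.
#' @param out_dir output directory (default: the configured
#'   \code{output_dir}).
#' @return Invisibly, the written file paths.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  config <- as_run_config(config)
  if (is.null(config$simulate)) stopf("config has no 'simulate' section")
  sim <- simulate_chase(sim_config_from_list(config$simulate, config$seed))
  out_dir <- out_dir %||% config$output_dir
  paths <- write_chase_dataset(sim, out_dir)
  message(sprintf("simulate: wrote %d proteins x %d samples to %s",
                  nrow(sim$lfq$values), ncol(sim$lfq$values), out_dir))
  invisible(paths)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    return(read_run_config(config))
  }
  if (is.list(config)) return(build_run_config(config))
  stopf("'config' must be a run_config, a list, or a path to a YAML file")
}

#' Run the full chase degradome pipeline
#'
#' Executes the whole analysis on measured or simulated data:
#' decoy/contaminant filtering; a differential branch (log2 transform,
#' left-censored imputation, volcano contrast of the degrader co-treatment
#' versus the translation-inhibitor arm at the configured chase endpoint);
#' a kinetics branch on the non-imputed linear intensities (protein
#' fraction remaining, profile classification, first-order half-life fits
#' per condition); target discovery and — when rescue arms are present —
#' proteasome-inhibition rescue checks; decaying-set overlaps, per-condition
#' median half-lives and the half-life-reduction ranking. The imputed
#' matrix never reaches the kinetics branch; this is asserted at run time
#' by the PFR and fitting functions.
#'
#' All randomness (imputation draws, permutation sampling, simulation) is
#' derived from the single configured seed by fixed offsets, so identical
#' configurations produce byte-identical output tables.
#'
#' @param config a \code{run_config} list or a path to a YAML file.
#' @param out_dir output directory for the result TSVs (default: the
#'   configured \code{output_dir}; created if needed).
#' @return Invisibly, a list with all intermediate objects (\code{lfq},
#'   \code{volcano}, \code{classes}, \code{fits}, \code{targets},
#'   \code{rescue}, \code{overlaps}, \code{medians}, \code{delta},
#'   \code{report}) and the written file paths.
#' @export
run_chase_pipeline <- function(config, out_dir = NULL) {
  config <- as_run_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # --- load or simulate -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_chase(sim_config_from_list(config$simulate, config$seed))
    lfq <- sim$lfq
    design <- sim$design
    truth <- sim$truth
  } else {
    design <- read_design(config$input$design)
    lfq <- read_protein_groups(config$input$protein_groups, design)
    truth <- NULL
  }
  if (nrow(lfq$values) == 0L) stopf("preprocess: empty protein table")

  # --- preprocess -----------------------------------------------------------
  lfq <- filter_decoys(lfq)
  if (nrow(lfq$values) == 0L) stopf("preprocess: no proteins left after decoy/contaminant filtering")

  # --- differential branch (imputed) ---------------------------------------
  vcfg <- config$volcano
  log2_m <- log2_transform(lfq)
  imputed <- impute_left_censored(log2_m,
                                  downshift = config$imputation$downshift,
                                  width = config$imputation$width,
                                  seed = derive_seed(config$seed, 1L))
  volc <- volcano(imputed, vcfg$cond_a, vcfg$cond_b,
                  timepoint_h = vcfg$timepoint_h, s0 = vcfg$s0,
                  fdr = vcfg$fdr, n_perm = vcfg$n_perm, top_k = vcfg$top_k,
                  seed = derive_seed(config$seed, 2L))

  # --- kinetics branch (never imputed) --------------------------------------
  tcfg <- config$turnover
  pfr <- compute_pfr(lfq)
  kin_conds <- intersect(unique(design$condition),
                         c("CON", "CHX", "CHX_PROTAC", vcfg$cond_a, vcfg$cond_b))
  kin_conds <- kin_conds[vapply(kin_conds, function(cn) {
    length(chase_timepoints(design, cn)) >= 2
  }, logical(1))]
  classes <- lapply(kin_conds, function(cn) {
    classify_profiles(pfr, cn,
                      stability_band = c(tcfg$stability_low, tcfg$stability_high),
                      decrease_tolerance = tcfg$decrease_tolerance,
                      band_mode = tcfg$band_mode)
  })
  names(classes) <- kin_conds
  fits <- lapply(kin_conds, function(cn) {
    fit_first_order(lfq, cn, max_half_life_h = tcfg$max_half_life_h)
  })
  names(fits) <- kin_conds

  # --- discovery, rescue, summaries ----------------------------------------
  targets <- discover_targets(volc, classes[[vcfg$cond_a]])
  rcfg <- config$rescue
  rescue <- NULL
  has_rescue_arms <- all(c("PROTAC", "BORT_PROTAC") %in% design$condition)
  if (has_rescue_arms && length(targets$verified)) {
    rescue <- rescue_check(lfq, targets$verified,
                           endpoint_h = rcfg$endpoint_h,
                           depletion_threshold = rcfg$depletion_threshold,
                           rescue_threshold = rcfg$rescue_threshold)
  }
  overlaps <- if (length(classes) >= 2) compare_decaying_sets(classes) else NULL
  medians <- if (!is.null(overlaps)) {
    summarize_half_lives(fits, overlaps$unique_sets)
  } else NULL
  # Delta t1/2 is ranked over the proteins that decay in BOTH arms (the
  # overlap of the per-arm decaying sets): those are the only proteins with
  # a meaningful half-life in each condition.
  delta <- if (all(c(vcfg$cond_b, vcfg$cond_a) %in% names(fits))) {
    dec <- function(cn) {
      cl <- classes[[cn]]
      cl$protein_id[cl$label == "decaying"]
    }
    both <- intersect(dec(vcfg$cond_b), dec(vcfg$cond_a))
    fr <- fits[[vcfg$cond_b]]
    ft <- fits[[vcfg$cond_a]]
    delta_half_life(fr[fr$protein_id %in% both, , drop = FALSE],
                    ft[ft$protein_id %in% both, , drop = FALSE])
  } else NULL
  report <- degradome_report(volc, classes, fits, targets, rescue, delta)

  # --- write outputs --------------------------------------------------------
  paths <- list()
  write_out <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    paths[[name]] <<- p
  }
  write_out(as.data.frame(volc), "volcano.tsv")
  write_out(data.frame(protein_id = rownames(pfr$pfr),
                       as.data.frame(pfr$pfr), check.names = FALSE),
            "pfr.tsv")
  write_out(do.call(rbind, classes), "profile_classes.tsv")
  write_out(do.call(rbind, lapply(fits, as.data.frame)), "half_lives.tsv")
  if (!is.null(delta)) write_out(delta, "delta_half_life.tsv")
  if (!is.null(rescue)) write_out(rescue, "rescue.tsv")
  if (!is.null(overlaps)) write_out(overlaps$overlap_counts, "overlap_counts.tsv")
  if (!is.null(medians)) write_out(medians, "median_half_lives.tsv")
  write_out(report, "degradome_report.tsv")

  log_lines <- c(
    sprintf("protchase %s", as.character(utils::packageVersion("protchase"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d", config$seed),
    sprintf("config_hash %s", config_hash(config)),
    sprintf("proteins %d samples %d", nrow(lfq$values), ncol(lfq$values)),
    sprintf("candidates %d verified %d rescued %s",
            length(targets$candidates), length(targets$verified),
            if (is.null(rescue)) "NA" else sum(rescue$rescued))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  message(paste(log_lines, collapse = "\n"))
  invisible(list(lfq = lfq, design = design, truth = truth, volcano = volc,
                 pfr = pfr, classes = classes, fits = fits,
                 targets = targets, rescue = rescue, overlaps = overlaps,
                 medians = medians, delta = delta, report = report,
                 paths = paths, out_dir = out_dir))
}

# Stable content hash of the analysis-relevant configuration (the output
# location is excluded: it does not affect results), recorded in the run log.
config_hash <- function(config) {
  config$output_dir <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x) %||% seq_along(x))]
      lapply(x, canon)
    } else x
  }
  txt <- paste(deparse(canon(unclass(config))), collapse = "")
  # small rolling hash; enough to detect config drift between runs
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Half-life table for a single condition
#'
#' Runs only the kinetics branch (decoy filtering, then first-order fits)
#' for one condition and writes \code{half_lives.tsv}.
#'
#' @param config a \code{run_config} list or YAML path.
#' @param condition condition label to fit.
#' @param out_dir output directory (default: configured \code{output_dir}).
#' @param include_excluded keep rows whose half-life exceeds the reporting
#'   cap (default TRUE; they stay flagged in the \code{excluded_long}
#'   column either way).
#' @return Invisibly, the \code{decay_fits} table.
#' @export
run_half_lives <- function(config, condition, out_dir = NULL,
                           include_excluded = TRUE) {
  config <- as_run_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$simulate)) {
    sim <- simulate_chase(sim_config_from_list(config$simulate, config$seed))
    lfq <- sim$lfq
  } else {
    design <- read_design(config$input$design)
    lfq <- read_protein_groups(config$input$protein_groups, design)
  }
  if (!condition %in% lfq$design$condition) {
    stopf("unknown condition '%s'", condition)
  }
  lfq <- filter_decoys(lfq)
  fits <- fit_first_order(lfq, condition,
                          max_half_life_h = config$turnover$max_half_life_h)
  out <- as.data.frame(fits)
  if (!include_excluded) out <- out[!out$excluded_long, , drop = FALSE]
  write_table(out, file.path(out_dir, "half_lives.tsv"))
  invisible(fits)
}
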