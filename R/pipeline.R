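#' Default end-to-end demo configuration
#'
#' Six synthetic surfaces (A-F) with instability boundaries shifted per
#' surface, the standard 4 x 4 condition grid with 9 retained pulls, six
#' surface pairs spanning a range of differential-instability scores, and
#' a behavioural generator whose accuracy follows the differential
#' steady-sliding percentage and whose response time follows the
#' differential stiction-spike percentage.
#'
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory for the report bundle.
#' @return A named configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("frinstab_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    grid = list(masses = c(0, 25, 75, 100), velocities = c(5, 10, 25, 45),
                n_reps = 9L),
    surfaces = list(
      A = list(sfw_offset = -1.5, sp_offset = 0.6, mu_k0 = 2.2),
      B = list(sfw_offset = -0.5, sp_offset = -0.6, mu_k0 = 2.4),
      C = list(sfw_offset = 0.5, sp_offset = 0.0, mu_k0 = 2.5),
      D = list(sfw_offset = 1.5, sp_offset = 1.0, mu_k0 = 3.0),
      E = list(sfw_offset = 0.0, sp_offset = -1.2, mu_k0 = 2.1),
      F = list(sfw_offset = -1.0, sp_offset = 0.3, mu_k0 = 2.0)
    ),
    pairs = list(P1 = c("A", "E"), P2 = c("C", "E"), P3 = c("A", "B"),
                 P4 = c("D", "E"), P5 = c("A", "F"), P6 = c("B", "E")),
    noise_sd = 0.013,
    thresholds = list(),
    behavior = list(beta0 = -0.7, beta1 = 0.1, sigma_subject = 0.5,
                    n_subjects = 10L, n_trials_per_pair = 10L,
                    rt_beta0 = log(10), rt_beta1 = -0.03, rt_sigma = 0.4,
                    rt_subject_sd = 0.2),
    accuracy_predictor = "dSS",
    rt_predictor = "dSp"
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) six surfaces' force traces, classify every pull,
#' build phase-count grids, score the configured surface pairs, generate
#' (or ingest) 3-AFC behavioural trials, and fit the chance tests and
#' mixed models. Writes `classified.csv`, `counts_<surface>.json`,
#' `pair_<label>.json`, `fits.json` and `summary.txt` into the output
#' directory. Identical seeds give identical outputs; any stage failure
#' aborts with the stage name and a manifest of outputs written so far.
#'
#' @param config Configuration list as produced by
#'   [default_pipeline_config()], or a path to a YAML file with the same
#'   structure.
#' @return Invisibly, a list with the classified table, phase-count
#'   grids, pair differences, predictors, behavioural table, test and
#'   model results, and the output file manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$seed) || is.null(cfg$surfaces) || is.null(cfg$pairs))
    abort("config must provide seed, surfaces and pairs",
          "frinstab_validation_error")
  for (p in names(cfg$pairs)) {
    miss <- setdiff(unlist(cfg$pairs[[p]]), names(cfg$surfaces))
    if (length(miss))
      abort(sprintf("pair %s refers to unknown surface(s): %s", p,
                    paste(miss, collapse = ", ")),
            "frinstab_validation_error")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage '%s' failed: %s\noutputs written so far: %s",
                    name, conditionMessage(e),
                    if (length(manifest)) paste(manifest, collapse = ", ")
                    else "(none)"),
            "frinstab_stage_error")
    })
  }

  grid <- stage("grid", do.call(condition_grid, cfg$grid))
  thresholds <- do.call(classifier_thresholds,
                        if (is.null(cfg$thresholds)) list() else cfg$thresholds)

  classified <- stage("classify", {
    out <- list()
    snames <- names(cfg$surfaces)
    for (i in seq_along(snames)) {
      s <- snames[i]
      sc <- cfg$surfaces[[s]]
      spec <- demo_regime(grid, sfw_offset = sc$sfw_offset,
                          sp_offset = sc$sp_offset, surface_id = s,
                          mu_k0 = sc$mu_k0)
      traces <- simulate_surface(spec, seed = child_seed(cfg$seed, i),
                                 noise_sd = cfg$noise_sd)
      out[[s]] <- classify_traces(traces, thresholds)
    }
    do.call(rbind, out)
  })
  p_class <- file.path(cfg$out_dir, "classified.csv")
  utils::write.csv(classified, p_class, row.names = FALSE)
  manifest <- c(manifest, p_class)

  pcgs <- stage("phasemap", {
    lapply(split(classified, classified$surface_id), count_phases, grid = grid)
  })
  for (s in names(pcgs)) {
    p <- file.path(cfg$out_dir, sprintf("counts_%s.json", s))
    write_json_file(list(surface_id = s, masses = grid$masses,
                         velocities = grid$velocities, n_reps = grid$n_reps,
                         totals = as.list(pcgs[[s]]$totals),
                         counts = lapply(c(SS = "SS", SFW = "SFW", Sp = "Sp"),
                                         function(l) pcgs[[s]]$counts[, , l])),
                    p)
    manifest <- c(manifest, p)
  }

  mus <- stage("friction", lapply(split(classified, classified$surface_id),
                                  aggregate_mu, grid = grid))

  pairdiffs <- stage("pairdiff", {
    lapply(names(cfg$pairs), function(lab) {
      ab <- unlist(cfg$pairs[[lab]])
      pair_difference(pcgs[[ab[1]]], pcgs[[ab[2]]], label = lab)
    })
  })
  names(pairdiffs) <- names(cfg$pairs)
  predictors <- data.frame(
    pair_label = names(pairdiffs),
    dSS = vapply(pairdiffs, function(x) x$delta_percent[["SS"]], 0),
    dSFW = vapply(pairdiffs, function(x) x$delta_percent[["SFW"]], 0),
    dSp = vapply(pairdiffs, function(x) x$delta_percent[["Sp"]], 0),
    dMu = vapply(names(pairdiffs), function(lab) {
      ab <- unlist(cfg$pairs[[lab]])
      abs(mus[[ab[1]]]$mu_bar - mus[[ab[2]]]$mu_bar)
    }, 0),
    stringsAsFactors = FALSE)
  for (lab in names(pairdiffs)) {
    p <- file.path(cfg$out_dir, sprintf("pair_%s.json", lab))
    pd <- pairdiffs[[lab]]
    write_json_file(list(label = lab, surfaces = pd$surfaces,
                         delta_count = as.list(pd$delta_count),
                         delta_percent = as.list(pd$delta_percent),
                         max_pulls = pd$max_pulls,
                         dMu = predictors$dMu[predictors$pair_label == lab]),
                    p)
    manifest <- c(manifest, p)
  }

  behavior <- stage("behavior", {
    b <- cfg$behavior
    if (!is.null(b$path)) read_behavior(b$path)
    else {
      acc_pred <- stats::setNames(predictors[[cfg$accuracy_predictor]],
                                  predictors$pair_label)
      rt_pred <- stats::setNames(predictors[[cfg$rt_predictor]],
                                 predictors$pair_label)
      synth_behavior(acc_pred, beta0 = b$beta0, beta1 = b$beta1,
                     sigma_subject = b$sigma_subject,
                     n_subjects = b$n_subjects,
                     n_trials_per_pair = b$n_trials_per_pair,
                     seed = child_seed(cfg$seed, 991L),
                     rt_predictors = rt_pred, rt_beta0 = b$rt_beta0,
                     rt_beta1 = b$rt_beta1, rt_sigma = b$rt_sigma,
                     rt_subject_sd = b$rt_subject_sd)
    }
  })
  p_beh <- file.path(cfg$out_dir, "behavior.csv")
  write_behavior(behavior, p_beh)
  manifest <- c(manifest, p_beh)

  stats_out <- stage("stats", {
    summ <- tabulate_behavior(behavior, predictors)
    chance_by_pair <- lapply(split(summ$accuracy, summ$pair_label),
                             chance_test)
    acc_fit <- fit_accuracy_glmm(behavior, predictors,
                                 cfg$accuracy_predictor)
    rt_fit <- fit_rt_model(behavior, predictors, cfg$rt_predictor)
    mu_fit <- fit_accuracy_glmm(behavior, predictors, "dMu")
    list(summary = summ, chance = chance_by_pair, acc_fit = acc_fit,
         rt_fit = rt_fit, mu_fit = mu_fit)
  })
  fit_json <- function(f) list(family = f$family,
                               intercept = f$fixed$intercept,
                               slope = f$fixed$slope,
                               slope_se = f$fixed$slope_se,
                               slope_p = f$fixed$slope_p,
                               subject_sd = f$random$subject_sd,
                               descriptive_r = f$descriptive_r,
                               n_obs = f$n_obs)
  p_fits <- file.path(cfg$out_dir, "fits.json")
  write_json_file(list(
    chance = lapply(stats_out$chance,
                    function(z) list(t = z$t, p = z$p, mean = z$mean)),
    accuracy_vs_dSS = fit_json(stats_out$acc_fit),
    rt_vs_dSp = fit_json(stats_out$rt_fit),
    accuracy_vs_dMu = fit_json(stats_out$mu_fit)), p_fits)
  manifest <- c(manifest, p_fits)

  p_sum <- file.path(cfg$out_dir, "summary.txt")
  lines <- c(
    sprintf("frinstab pipeline run (seed %d)", cfg$seed),
    "",
    "Instability totals per surface (SS / SFW / Sp):",
    vapply(names(pcgs), function(s)
      sprintf("  %s: %d / %d / %d", s, pcgs[[s]]$totals["SS"],
              pcgs[[s]]$totals["SFW"], pcgs[[s]]$totals["Sp"]), ""),
    "",
    "Pair differences (|dSS| / |dSFW| / |dSp| %, dMu):",
    vapply(names(pairdiffs), function(lab)
      sprintf("  %s (%s vs %s): %g / %g / %g, dMu %.3f", lab,
              pairdiffs[[lab]]$surfaces[1], pairdiffs[[lab]]$surfaces[2],
              pairdiffs[[lab]]$delta_percent[["SS"]],
              pairdiffs[[lab]]$delta_percent[["SFW"]],
              pairdiffs[[lab]]$delta_percent[["Sp"]],
              predictors$dMu[predictors$pair_label == lab]), ""),
    "",
    sprintf("Accuracy GLMM vs %s: slope %.4f (p = %.3g), r = %.2f",
            cfg$accuracy_predictor, stats_out$acc_fit$fixed$slope,
            stats_out$acc_fit$fixed$slope_p, stats_out$acc_fit$descriptive_r),
    sprintf("log-RT model vs %s: slope %.4f (p = %.3g), r = %.2f",
            cfg$rt_predictor, stats_out$rt_fit$fixed$slope,
            stats_out$rt_fit$fixed$slope_p, stats_out$rt_fit$descriptive_r),
    sprintf("Accuracy GLMM vs dMu: slope %.4f (p = %.3g), r = %.2f",
            stats_out$mu_fit$fixed$slope, stats_out$mu_fit$fixed$slope_p,
            stats_out$mu_fit$descriptive_r))
  writeLines(lines, p_sum)
  manifest <- c(manifest, p_sum)

  invisible(list(classified = classified, phase_counts = pcgs,
                 pair_differences = pairdiffs, predictors = predictors,
                 mu = mus, behavior = behavior, stats = stats_out,
                 manifest = manifest))
}
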