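#' Run the cortical-flow / spindle-skew pipeline end to end
#'
#' Orchestrates the stages `simulate -> piv -> chirality -> myosin ->
#' model -> skew -> report` with one reproducible configuration. Each
#' stage writes its outputs (CSV/JSON) into `out_dir`; a failing stage
#' halts the run with the stage named, keeping the outputs of earlier
#' stages. Every output bundle records the seed, the configuration hash
#' and the package version.
#'
#' @param config a named list, or the path of a JSON file holding one.
#'   Recognised entries (all optional, with AB-like defaults):
#'   `seed`, `out_dir`, `stages` (character subset of the stage names),
#'   `flow` (arguments for [flow_truth()] plus `image_shape`,
#'   `pixel_size`, `frame_interval`, `n_frames`), `cell_id`,
#'   `piv` (`windows`, `final_step`), `time_window`, `onset_frame`,
#'   `profile` (arguments for [profile_truth()]),
#'   `model` (`ell`, `chi`, `d`, `n_grid`),
#'   `spindle` (`n_frames`, `skew_rate`, `elongation_rate`, `seed`),
#'   `torque` (`gamma_L`, `gamma_R`, `A_L`, `A_R`, `R`),
#'   `write_images` (store the synthetic stacks as text; default FALSE).
#' @return A `pipeline_result` list with the per-stage results and the
#'   paths of everything written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- pipeline_defaults(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_hash <- rlang::hash(cfg)
  provenance <- list(
    package = "chiralflow",
    version = as.character(utils::packageVersion("chiralflow")),
    seed = cfg$seed,
    config_hash = config_hash,
    stages = cfg$stages
  )
  res <- list(config = cfg, provenance = provenance, files = character(0))
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  run_stage("simulate", function() {
    truth <- do.call(flow_truth, c(cfg$flow_truth, list(seed = cfg$seed)))
    res$movie <<- do.call(sim_flow_movie, c(list(truth = truth), cfg$flow_movie))
    path <- file.path(out_dir, "flow_truth.json")
    jsonlite::write_json(
      c(unclass(truth), provenance["config_hash"]),
      path, auto_unbox = TRUE, digits = NA
    )
    if (isTRUE(cfg$write_images)) {
      write_image_stack(res$movie$stack, file.path(out_dir, "flow_movie"),
                        truth = unclass(truth))
    }
    sp_truth <- do.call(spindle_truth, cfg$spindle_truth)
    res$spindle_movie <<- do.call(
      sim_spindle_movie, c(list(truth = sp_truth), cfg$spindle_movie)
    )
    res$files <<- c(res$files, path)
  })

  run_stage("piv", function() {
    if (is.null(res$movie)) abort("No movie: enable the simulate stage.")
    res$field <<- do.call(compute_piv, c(list(stack = res$movie$stack), cfg$piv))
    path <- file.path(out_dir, "velocity_field.csv")
    utils::write.csv(res$field, path, row.names = FALSE)
    res$files <<- c(res$files, path)
  })

  run_stage("chirality", function() {
    if (is.null(res$field)) abort("No velocity field: enable the piv stage.")
    frame <- res$movie$frame
    rois <- place_rois(frame, cell_id = cfg$cell_id,
                       pixel_size = res$movie$stack$pixel_size,
                       image_shape = dim(res$movie$stack$frames[[1]]))
    res$chiral <<- chiral_stats(res$field, rois, frame,
                                onset_frame = cfg$onset_frame,
                                time_window = cfg$time_window)
    utils::write.csv(res$chiral$per_frame,
                     file.path(out_dir, "chiral_per_frame.csv"),
                     row.names = FALSE)
    path <- file.path(out_dir, "chiral_summary.json")
    jsonlite::write_json(
      c(as.list(res$chiral$summary), provenance["config_hash"],
        list(seed = cfg$seed)),
      path, auto_unbox = TRUE, digits = NA
    )
    res$files <<- c(res$files,
                    file.path(out_dir, "chiral_per_frame.csv"), path)
  })

  run_stage("myosin", function() {
    truth <- do.call(profile_truth, cfg$profile_truth)
    sim <- sim_myosin_profile(truth)
    fit <- fit_myosin_profile(sim$profile)
    res$myosin <<- list(profile = sim$profile, truth = truth, fit = fit,
                        ratio = myosin_ratio(sim$profile))
    utils::write.csv(sim$profile, file.path(out_dir, "myosin_profile.csv"),
                     row.names = FALSE)
    path <- file.path(out_dir, "myosin_fit.json")
    jsonlite::write_json(
      list(params = fit$params, converged = fit$converged, rss = fit$rss,
           myosin_ratio = res$myosin$ratio, seed = truth$seed,
           config_hash = config_hash),
      path, auto_unbox = TRUE, digits = NA
    )
    res$files <<- c(res$files,
                    file.path(out_dir, "myosin_profile.csv"), path)
  })

  run_stage("model", function() {
    p <- if (!is.null(res$myosin) && res$myosin$fit$converged) {
      res$myosin$fit$params
    } else {
      list(IA = 1, IP = 1, IR = 0.3, w = 0.05, xr = 0.5)
    }
    m <- film_model(
      length = cfg$flow_truth$cell_length %||% 24,
      ell = cfg$model$ell, chi = cfg$model$chi,
      myosin = function(x) myosin_model(x, p$IA, p$IP, p$IR, p$w, p$xr)
    )
    sol <- solve_chiral_flow(m, n_grid = cfg$model$n_grid)
    vc_pred <- predict_vc(sol, xr = p$xr * m$L, d = cfg$model$d)
    res$model <<- list(model = m, solution = sol, vc_pred = vc_pred)
    path <- file.path(out_dir, "film_solution.csv")
    utils::write.csv(sol$grid, path, row.names = FALSE)
    res$files <<- c(res$files, path)
  })

  run_stage("skew", function() {
    if (is.null(res$spindle_movie)) abort("No spindle movie: enable simulate.")
    track <- track_poles(res$spindle_movie)
    summary <- rate_analysis(track)
    tq <- cfg$torque
    v <- counter_rotation_speed(vc = if (!is.null(res$chiral)) {
      res$chiral$summary$vc
    } else {
      cfg$flow_truth$vc %||% -6
    })
    pred <- omega_torque_balance(tq$gamma_L, tq$gamma_R, tq$A_L, tq$A_R,
                                 v = v$v, R = tq$R)
    res$skew <<- list(track = track, summary = summary, prediction = pred,
                      v_mapping = v$method)
    utils::write.csv(track, file.path(out_dir, "spindle_track.csv"),
                     row.names = FALSE)
    path <- file.path(out_dir, "skew_summary.json")
    jsonlite::write_json(
      list(skew_angle = summary$skew_angle,
           peak_skew_rate = summary$peak_skew_rate,
           peak_elongation_rate = summary$peak_elongation_rate,
           omega_pred_rad = pred$omega_rad,
           omega_pred_deg = pred$omega_deg,
           v_mapping = v$method,
           seed = cfg$seed, config_hash = config_hash),
      path, auto_unbox = TRUE, digits = NA
    )
    res$files <<- c(res$files,
                    file.path(out_dir, "spindle_track.csv"), path)
  })

  run_stage("report", function() {
    path <- file.path(out_dir, "report.md")
    lines <- c(
      "# chiralflow pipeline report",
      "",
      sprintf("- package version: %s", provenance$version),
      sprintf("- seed: %d", cfg$seed),
      sprintf("- config hash: %s", config_hash),
      ""
    )
    if (!is.null(res$chiral)) {
      s <- res$chiral$summary
      lines <- c(lines, "## Chiral flow statistics", "",
                 sprintf("- vc = %.3f +/- %.3f um/min (%s)",
                         s$vc, s$vc_ci95, s$handedness),
                 sprintf("- vr = %.3f um/min; vcontr = %.3f um/min; flow speed = %.3f um/min",
                         s$vr, s$vcontr, s$flow_speed), "")
      if (!is.null(res$movie)) {
        lines <- c(lines,
                   sprintf("- ground truth vc = %.3f um/min", res$movie$truth$vc), "")
      }
    }
    if (!is.null(res$myosin)) {
      p <- res$myosin$fit$params
      lines <- c(lines, "## Myosin profile", "",
                 sprintf("- myosin ratio (anterior/posterior) = %.3f",
                         res$myosin$ratio),
                 sprintf("- fit: IA=%.3f IP=%.3f IR=%.3f w=%.3f xr=%.3f (converged: %s)",
                         p$IA, p$IP, p$IR, p$w, p$xr, res$myosin$fit$converged), "")
    }
    if (!is.null(res$model)) {
      lines <- c(lines, "## Film model", "",
                 sprintf("- predicted vc = %.3f um/min", res$model$vc_pred), "")
    }
    if (!is.null(res$skew)) {
      lines <- c(lines, "## Spindle skew", "",
                 sprintf("- skew angle = %.2f deg; peak skew rate = %.3f deg/min",
                         res$skew$summary$skew_angle,
                         res$skew$summary$peak_skew_rate),
                 sprintf("- torque-balance omega = %.3f deg/min (%s)",
                         res$skew$prediction$omega_deg,
                         res$skew$prediction$interpretation), "")
    }
    writeLines(lines, path)
    res$files <<- c(res$files, path)
  })

  structure(res, class = "pipeline_result")
}

pipeline_defaults <- function(config) {
  dflt <- list(
    seed = 1L,
    out_dir = file.path(tempdir(), "chiralflow-run"),
    stages = c("simulate", "piv", "chirality", "myosin", "model", "skew",
               "report"),
    flow_truth = list(),
    flow_movie = list(),
    cell_id = "AB",
    piv = list(),
    time_window = 21,
    onset_frame = 1,
    profile_truth = list(),
    spindle_truth = list(),
    spindle_movie = list(),
    model = list(ell = 4, chi = -1, d = 4.5, n_grid = 401),
    torque = list(gamma_L = 1, gamma_R = 1.7, A_L = 1, A_R = 1.3, R = 4.5),
    write_images = FALSE
  )
  cfg <- utils::modifyList(dflt, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> stages: %s\n",
              paste(x$config$stages, collapse = ", ")))
  cat(sprintf("  %d file(s) written under %s\n",
              length(x$files), x$config$out_dir))
  invisible(x)
}

#' Rank-based comparison of two measurement groups
#'
#' Two-sided Wilcoxon rank sum test between two sets of per-embryo
#' measurements (e.g. counter-rotating flow velocities under two RNAi
#' conditions), with the significance flag evaluated at 95% confidence.
#' Ties are handled by midranks (via the normal approximation when exact
#' enumeration is impossible).
#'
#' @param x,y numeric vectors of per-embryo values (>= 3 each).
#' @param conf_level confidence level for the significance flag.
#' @return A one-row tibble: `statistic` (rank-sum `W` of `x`),
#'   `p_value`, `significant`, `n_x`, `n_y`, `method`.
#' @export
compare_conditions <- function(x, y, conf_level = 0.95) {
  if (length(x) < 3 || length(y) < 3) {
    abort("Need at least 3 samples per group.")
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    significant = wt$p.value < (1 - conf_level),
    n_x = length(x), n_y = length(y),
    method = wt$method
  )
}
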