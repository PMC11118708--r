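# End-to-end synthetic pipeline: simulate -> maps -> grid -> stats -> model
# -> textures, with per-stage provenance and deterministic child seeds.

#' Pipeline configuration
#'
#' Validated parameter set for [run_pipeline()]. Defaults mirror the
#' experimental analysis: 8 orientations, carrier spatial frequency 1
#' cycle/degree, envelope sigma 0.6 degrees, like-to-like FWHM 22.5 degrees,
#' grid resolution 0.02 degrees, 1000 pixel resamples, 1500 pattern shifts,
#' 320-pixel texture images at 100 px/degree. Unknown keys are rejected.
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `seed`; map: `map_height`, `map_width`, `map_smoothness`,
#'   `pixels_per_mm`, `map_noise_sd`; cells: `n_cells`, `bias_strength`,
#'   `like_to_like_fwhm`, `cluster_scale`, `injection_radius`; grid:
#'   `extent_par_deg`, `extent_orth_deg`, `grid_resolution`, `grid_coarse`;
#'   stats: `n_resample`, `n_shifts`; model: `sf`, `sigma_x`, `n_v2_pixels`,
#'   `v2_noise_frac`, `tuning_res`; textures: `n_families`,
#'   `texture_samples`, `texture_size`, `px_per_deg`, `n_texture_cells`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    map_height = 64L, map_width = 64L, map_smoothness = 0.75,
    pixels_per_mm = 55.6, map_noise_sd = 2,
    n_cells = 500L, bias_strength = 0.31, like_to_like_fwhm = 22.5,
    cluster_scale = 8, injection_radius = 4,
    extent_par_deg = 2.5, extent_orth_deg = 1.5,
    grid_resolution = 0.02, grid_coarse = c(41L, 25L),
    n_resample = 1000L, n_shifts = 1500L,
    sf = 1, sigma_x = 0.6, n_v2_pixels = 20L, v2_noise_frac = 0.05,
    tuning_res = 0.05,
    n_families = 4L, texture_samples = 30L, texture_size = 320L,
    px_per_deg = 100, n_texture_cells = 20L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file of config overrides.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_files_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> maps -> grid -> stats -> model -> textures in order
#' on synthetic data with known ground truth, writing all artifacts under
#' `out_dir` and returning (and writing) a run report with per-stage
#' parameters, derived seeds, warnings, and output checksums. A single
#' config seed fans out deterministically to per-stage child seeds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list of class `run_report`, invisibly; the report is also written
#'   to `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), stages = list(), warnings = list())
  t_all <- Sys.time()
  note <- function(stage, w) {
    report$warnings[[stage]] <<- c(report$warnings[[stage]], w)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    report$stages[[stage]] <<- list(
      seed = child_seed(config$seed, match(stage, c(
        "simulate", "maps", "grid", "stats", "model", "textures"))),
      runtime_s = as.numeric(Sys.time() - t0)
    )
    res
  }
  seeds <- vapply(1:6, function(k) child_seed(config$seed, k), integer(1))

  ## stage 1: simulate ---------------------------------------------------
  sim <- run_stage("simulate", {
    mcfg <- map_sim_config(config$map_height, config$map_width,
                           config$pixels_per_mm, config$map_smoothness,
                           config$map_noise_sd, seed = seeds[1])
    sim_map <- simulate_orientation_map(mcfg)
    ctr <- c(round(config$map_width / 2), round(config$map_height / 2))
    ccfg <- connectivity_sim_config(
      config$n_cells, config$like_to_like_fwhm, config$bias_strength,
      config$cluster_scale, injection_center = ctr,
      injection_radius = config$injection_radius,
      seed = child_seed(seeds[1], 1))
    cells <- simulate_labeled_cells(ccfg, sim_map)
    write_map_set(sim_map$maps, file.path(out_dir, "maps"))
    write_cell_table(cells, file.path(out_dir, "cells.csv"))
    list(map = sim_map, cells = cells, injection_center = ctr)
  })

  ## stage 2: maps --------------------------------------------------------
  pomap <- run_stage("maps", {
    pm <- vector_sum_po(sim$map$maps)
    write_matrix_csv(pm$po, file.path(out_dir, "po_map.csv"))
    pm
  })

  ## stage 3: grid --------------------------------------------------------
  asg <- run_stage("grid", {
    o <- outline_rect(1, 1, config$map_width - 2, config$map_height - 2,
                      config$extent_par_deg, config$extent_orth_deg)
    grid <- generate_elliptic_grid(o, resolution = config$grid_resolution,
                                   coarse = config$grid_coarse)
    a <- assign_cells(sim$cells, grid)
    utils::write.csv(a, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
    a
  })

  ## stage 4: stats -------------------------------------------------------
  stats_out <- run_stage("stats", {
    keep <- match(asg$cell_id, sim$cells$cell_id)
    cells <- sim$cells[keep, ]
    cpo <- po_at_points(pomap, cells$x_px, cells$y_px)
    inj_po <- attr(sim$cells, "injection_po")
    obs <- circ_stats(cpo)
    hist_cells <- po_histogram(cpo)
    # injection-site histogram from the disc pixels
    h <- nrow(pomap$po); w <- ncol(pomap$po)
    gx <- matrix(seq_len(w), h, w, byrow = TRUE)
    gy <- matrix(seq_len(h), h, w)
    disc <- (gx - sim$injection_center[1])^2 +
      (gy - sim$injection_center[2])^2 <= config$injection_radius^2
    hist_inj <- po_histogram(pomap$po[disc])
    hist_field <- po_histogram(pomap$po[!pomap$undefined])
    resamp <- pixel_resample_null(pomap, NULL, m = length(cpo),
                                  n_rep = config$n_resample,
                                  seed = seeds[4])
    shifts <- pattern_shift_null(pomap, cells$x_px, cells$y_px,
                                 n_shifts = config$n_shifts,
                                 seed = child_seed(seeds[4], 1))
    l2l <- like_to_like_sim(hist_inj, hist_cells,
                            fwhm = config$like_to_like_fwhm)
    res <- list(
      n_cells_assigned = length(cpo),
      injection_po = inj_po,
      fraction_within_22.5 = fraction_within(cpo, inj_po),
      observed = unclass(obs),
      exceedance_resample = exceedance(resamp, obs),
      exceedance_shift = exceedance(shifts, obs),
      chisq_vs_field = chisq_gof(hist_cells,
                                 hist_field / sum(hist_field) *
                                   sum(hist_cells))[c("statistic", "df",
                                                      "p.value")],
      like_to_like_chisq = l2l$chisq[c("statistic", "df", "p.value")]
    )
    write_results(res, file.path(out_dir, "stats.json"))
    utils::write.csv(
      data.frame(mrl = resamp$mrl, csd = resamp$csd),
      file.path(out_dir, "null_resample.csv"), row.names = FALSE)
    res
  })

  ## stage 5: model -------------------------------------------------------
  model_out <- run_stage("model", {
    keep <- match(asg$cell_id, sim$cells$cell_id)
    cells <- sim$cells[keep, ]
    # measured V1 tunings from the synthetic single-condition maps
    v1_meas <- t(vapply(seq_len(nrow(cells)), function(i) {
      sim$map$maps$responses[cells$y_px[i], cells$x_px[i], ]
    }, numeric(8)))
    bank <- aspect_ratio_bank(sigma_x = config$sigma_x, sf = config$sf,
                              res = config$tuning_res)
    gam <- vapply(seq_len(nrow(cells)), function(i) {
      estimate_aspect_ratio(v1_meas[i, ], bank = bank)$gamma_c
    }, numeric(1))
    po <- vapply(seq_len(nrow(cells)), function(i) {
      tuning_po(v1_meas[i, ])
    }, numeric(1))
    gidx <- match(gam, bank$gammas)
    v1_model <- t(vapply(seq_len(nrow(cells)), function(i) {
      bank_tuning(bank, gidx[i], po[i])
    }, numeric(8)))
    # synthetic V2 pixels: like-to-like weighted sums of the model tunings
    inj_po <- attr(sim$cells, "injection_po")
    th <- standard_orientations()
    v2 <- with_seed(seeds[5], {
      targets <- wrap_po(inj_po + stats::rnorm(config$n_v2_pixels, sd = 10))
      lapply(seq_len(config$n_v2_pixels), function(j) {
        ref <- 1 + cos(2 * (th - targets[j]) * pi / 180)
        wgen <- as.numeric(compute_weights(v1_model, rbind(ref)))
        noise_sd <- config$v2_noise_frac *
          mean(apply(v1_model, 1, function(r) diff(range(r))))
        simulate_v2_pixel(v1_model, wgen, noise_sd = noise_sd,
                          seed = child_seed(seeds[5], j))
      })
    })
    v2_meas <- t(vapply(v2, `[[`, numeric(8), "tuning"))
    cv <- loo_cross_validate(v1_meas, v2_meas, v1_model)
    w <- compute_weights(v1_meas, v2_meas)
    v1cells <- lapply(seq_len(nrow(cells)), function(i) {
      v1_cell(gabor_params(asg$x_deg[i], asg$y_deg[i], po[i], gam[i],
                           config$sigma_x, config$sf), "complex")
    })
    rf_even <- render_v2_rf(v1cells, w[, 1], "even", res = 0.05)
    res <- list(
      mean_relative_error = mean(cv$mean_relative_error),
      median_po_abs_error = stats::median(cv$po_abs_error, na.rm = TRUE),
      median_hwhh_abs_error = stats::median(cv$hwhh_abs_error, na.rm = TRUE)
    )
    utils::write.csv(
      data.frame(pixel = seq_len(nrow(v2_meas)),
                 mean_relative_error = cv$mean_relative_error,
                 po_abs_error = cv$po_abs_error,
                 hwhh_abs_error = cv$hwhh_abs_error),
      file.path(out_dir, "cv_metrics.csv"), row.names = FALSE)
    write_matrix_csv(w, file.path(out_dir, "weights.csv"))
    write_matrix_csv(unclass(rf_even), file.path(out_dir, "rf_even.csv"))
    write_results(res, file.path(out_dir, "model.json"))
    list(summary = res, weights = w, cells = v1cells, v1_meas = v1_meas,
         v2_meas = v2_meas)
  })

  ## stage 6: textures ----------------------------------------------------
  tex_out <- run_stage("textures", {
    nsub <- min(config$n_texture_cells, length(model_out$cells))
    sub <- with_seed(seeds[6],
                     sample(seq_along(model_out$cells), nsub))
    cells <- lapply(model_out$cells[sub], function(cl) {
      # centre the subsampled receptive fields on the image
      cl$params$xc <- cl$params$xc - config$extent_par_deg / 2
      cl$params$yc <- cl$params$yc - config$extent_orth_deg / 2
      cl
    })
    w <- model_out$weights[sub, , drop = FALSE]
    kinds <- c("oriented-composite", "thresholded-noise", "plaid")
    mi_v1 <- NULL; mi_v2 <- NULL
    for (fam in seq_len(config$n_families)) {
      family <- simulate_texture_family(
        config$texture_samples, kinds[1 + (fam - 1) %% length(kinds)],
        seed = child_seed(seeds[6], fam), size = config$texture_size)
      rot <- rotate_family(family)
      resp <- family_responses(cells, w, rot,
                               deg_per_px = 1 / config$px_per_deg)
      mi_v1 <- cbind(mi_v1, population_mi(resp, "v1")$mi)
      mi_v2 <- cbind(mi_v2, population_mi(resp, "v2")$mi)
    }
    cmp <- compare_populations(mi_v1, mi_v2)
    res <- list(
      mean_mi_v1 = mean(mi_v1), mean_mi_v2 = mean(mi_v2),
      t_mean = cmp$mean_test$t, p_mean = cmp$mean_test$p.value,
      t_max = cmp$max_test$t, p_max = cmp$max_test$p.value
    )
    utils::write.csv(as.data.frame(mi_v1),
                     file.path(out_dir, "mi_v1.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(mi_v2),
                     file.path(out_dir, "mi_v2.csv"), row.names = FALSE)
    write_results(res, file.path(out_dir, "textures.json"))
    res
  })

  report$runtime_s <- as.numeric(Sys.time() - t_all)
  report$outputs <- stage_files_checksums(
    list.files(out_dir, recursive = TRUE, full.names = TRUE))
  report$summary <- list(stats = stats_out, model = model_out$summary,
                         textures = tex_out)
  write_results(report[c("config", "stages", "warnings", "outputs",
                         "runtime_s")],
                file.path(out_dir, "run_report.json"))
  class(report) <- "run_report"
  invisible(report)
}
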