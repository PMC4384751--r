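# End-to-end synthetic study: generate data, correct FRET bleed-through,
# compute per-endosome statistics, count molecules from bleaching series,
# fit the trafficking model and compare dephosphorylation variants. Stages
# exchange plain CSV/JSON files; a manifest records an MD5 per output so a
# rerun with the same configuration is verifiably identical.

#' Pipeline configuration
#'
#' @param seed Global seed; propagates to every stage.
#' @param out_dir Output directory (created if needed).
#' @param synth A [synth_config()]; its seed is overridden by `seed`.
#' @param model_parameters A [model_params()] set used to generate and fit
#'   the time courses.
#' @param doses,times Time-course design.
#' @param free Free parameters of the fitting stage.
#' @param n_starts Multi-start count of the fitting stage.
#' @param run_fit Include the (comparatively slow) fitting and
#'   model-comparison stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("endoquanta-"),
                            synth = synth_config(seed = seed),
                            model_parameters = reference_params(),
                            doses = c(0.5, 1, 5, 10),
                            times = seq(0, 60, by = 5),
                            free = c("beta2", "Q", "rho"),
                            n_starts = 4L,
                            run_fit = TRUE) {
  synth$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, synth = synth,
                 model_parameters = model_parameters, doses = doses,
                 times = times, free = free, n_starts = as.integer(n_starts),
                 run_fit = isTRUE(run_fit)),
            class = "pipeline_config")
}

write_stage <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic study
#'
#' Deterministic stage graph: synth -> fret-correct -> stats -> count ->
#' fit -> compare. Each stage writes its outputs under `config$out_dir` and
#' the manifest records an MD5 checksum per file; rerunning with the same
#' configuration reproduces the checksums.
#'
#' @param config A [pipeline_config()].
#' @return List with `report` (named summary quantities), `manifest`
#'   (data.frame of files and checksums), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  report <- new.env()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # synth: object table with FRET channel
  tab <- stage("synth", {
    t <- generate_endosome_table(config$synth)
    generate_fret_channels(t, config$synth)
  })
  files["objects"] <- write_stage(tab, file.path(config$out_dir, "objects.csv"))

  # fret-correct: fit the ratio mixture on the bleed-through-only view and
  # correct the table (control view: the configured mixture defines truth;
  # the fit uses ratios from objects with negligible true FRET)
  corrected <- stage("fret-correct", {
    ratios <- (tab$I_fret - tab$F_true) / tab$I_ptyr
    fit <- fit_ratio_mixture(ratios, K = 2)
    report$mixture_means <- fit$mixture$means
    correct_object_table(tab, fit$mixture)
  })
  files["corrected"] <- write_stage(corrected,
                                    file.path(config$out_dir, "corrected.csv"))
  report$mean_F_corrected <- mean(corrected$F_corrected)
  report$mean_F_true <- mean(corrected$F_true)

  # stats
  stage("stats", {
    area_total <- config$synth$n_images * config$synth$cell_area_per_image
    report$total_intensity_per_1000um2 <-
      total_integral_intensity(corrected$F_corrected, area_total)
    report$mean_intensity_per_endosome <-
      mean_integral_per_endosome(corrected$F_corrected)
    report$endosome_density_per_1000um2 <-
      endosome_number_density(nrow(corrected), area_total)
    h <- log_binned_histogram(corrected$area_um2)
    lf <- fit_lognormal(h)
    report$area_lognormal_meanlog <- lf$meanlog
    report$area_lognormal_sdlog <- lf$sdlog
  })

  # count: single-fluorophore unit from photobleaching
  counts <- stage("count", {
    tracks <- generate_bleach_series(config$synth)
    h <- delta_intensity_histogram(tracks,
                                   config$synth$bleach$unit_intensity / 10)
    u <- detect_unit_intensity(neg_double_difference(h))
    report$unit_intensity <- u$unit_intensity
    first <- tracks[tracks$frame == 1, ]
    data.frame(object_id = first$object_id,
               count = count_molecules(first$intensity, u$unit_intensity),
               count_true = first$n_true)
  })
  files["counts"] <- write_stage(counts, file.path(config$out_dir, "counts.csv"))

  if (config$run_fit) {
    tc <- stage("timecourses", {
      generate_timecourse_data(config$model_parameters, config$doses,
                               config$times, config$synth$ode_noise_cv,
                               seed = config$seed)
    })
    files["timecourses"] <- write_stage(tc,
                                        file.path(config$out_dir, "timecourses.csv"))
    fit <- stage("fit", {
      pb <- fit_problem(tc[, c("dose", "observable", "time", "value", "sem")],
                        free = config$free, fixed = config$model_parameters,
                        n_starts = config$n_starts, seed = config$seed)
      fit_model(pb)
    })
    report$fit_ssr <- fit$ssr
    report$fit_values <- fit$free_values
    cmp <- stage("compare", {
      list(sig = plateau_metric(config$model_parameters, config$doses),
           fo = plateau_metric(config$model_parameters, config$doses,
                               variant = "first-order"))
    })
    report$plateau_fold_sigmoidal <- cmp$sig$fold
    report$plateau_fold_first_order <- cmp$fo$fold
  }

  manifest <- data.frame(
    file = basename(unname(files)),
    md5 = vapply(unname(files), function(f) unname(tools::md5sum(f)), character(1)),
    row.names = NULL)
  files["manifest"] <- write_stage(manifest,
                                   file.path(config$out_dir, "manifest.csv"))
  list(report = as.list(report), manifest = manifest, out_dir = config$out_dir)
}
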