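# Pipeline driver: YAML configuration, stage orchestration, artifact
# sidecars carrying the config hash + seed, and structured logging.

#' Load (and complete) a pipeline configuration
#'
#' Reads a YAML configuration and merges it over the packaged defaults
#' (`inst/extdata/default_config.yaml`).  Every random stage has an
#' explicit seed; `seed` overrides the base seed from which the per-stage
#' seeds are derived.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param seed optional base-seed override.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "fencorr"))
  cfg <- if (is.null(path)) defaults else {
    if (!file.exists(path)) stop(sprintf("config file %s not found", path))
    modifyList(defaults, yaml::read_yaml(path))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop("config must provide an explicit base seed")
  # derived per-stage seeds (kept below 2^31)
  cfg$seeds <- list(model = cfg$seed,
                    dehydration = (cfg$seed * 7 + 1) %% .Machine$integer.max,
                    sem_noise = (cfg$seed * 11 + 2) %% .Machine$integer.max,
                    optics = (cfg$seed * 13 + 3) %% .Machine$integer.max,
                    qi = (cfg$seed * 17 + 4) %% .Machine$integer.max)
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

plog <- function(logfile, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

need_file <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing input %s: run the '%s' stage first", path, producer))
  }
  path
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (generate wet/dry cell models and render them),
#' `segment` (threshold segmentation of both renders), `qi` (QI synthesis,
#' topography and force tomography), `match` (registration + one-to-one
#' matching), `stats` (distribution fits, paired regression, percent
#' change, correction coefficient), `report` (summary JSON), or `all`.
#' Every artifact's sidecar carries the config hash and the base seed, so
#' outputs are reproducible from config + seed alone.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file).
#' @param subcommand one of simulate, segment, qi, match, stats, report, all.
#' @param out output directory (created if absent).
#' @param seed optional base-seed override.
#' @return invisibly, a named list of artifact paths produced.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         subcommand = c("all", "simulate", "segment", "qi",
                                        "match", "stats", "report"),
                         out = "fencorr_out", seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- pipeline_config(config, seed = seed)
  else if (!is.null(seed)) config <- pipeline_config(NULL, seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "pipeline.log")
  hash <- config_hash(config)
  prov <- list(config_hash = hash, seed = config$seed)

  p <- function(...) file.path(out, ...)
  art <- list(wet_tif = p("wet.tif"), dry_tif = p("dry.tif"),
              wet_gt = p("wet_truth.csv"), dry_gt = p("dry_truth.csv"),
              wet_tab = p("wet_pores.csv"), dry_tab = p("dry_pores.csv"),
              qi_h5 = p("qi.h5"), tomo = p("force_tomography.csv"),
              matches = p("matches.csv"), transform = p("transform.json"),
              stats = p("stats.json"), report = p("report.json"))
  stages <- if (subcommand == "all") {
    c("simulate", "segment", "qi", "match", "stats", "report")
  } else subcommand

  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      simulate = {
        g <- config$generator
        wet <- generate_cell_model(
          field_size = unlist(g$field_size), n_plates = g$n_plates,
          pores_per_plate = g$pores_per_plate,
          diameter_mean = g$diameter_mean, diameter_sd = g$diameter_sd,
          roundness_mean = g$roundness_mean, roundness_sd = g$roundness_sd,
          n_gaps = g$n_gaps, closed_fraction = g$closed_fraction,
          seed = config$seeds$model)
        dp <- config$dehydration
        dry <- apply_dehydration(wet, dehydration_params(
          lambda_dilation = dp$lambda_dilation,
          edge_fraction = dp$edge_fraction,
          edge_elongation = dp$edge_elongation,
          p_open_on_drying = dp$p_open_on_drying,
          seed = config$seeds$dehydration))
        oc <- config$optics
        wet_img <- render_optical(wet, optical_params(
          psf_fwhm = oc$psf_fwhm, pixel_size = oc$pixel_size,
          photon_budget = oc$photon_budget, background = oc$background,
          seed = config$seeds$optics), modality = oc$modality)
        dry_img <- render_sem(dry, pixel_size = config$sem$pixel_size,
                              noise_sd = config$sem$noise_sd,
                              seed = config$seeds$sem_noise)
        write_raster(wet_img, art$wet_tif, extra = prov)
        write_raster(dry_img, art$dry_tif, extra = prov)
        write_pore_table(pore_table(wet, modality = oc$modality), art$wet_gt)
        write_pore_table(pore_table(dry, modality = "SEM"), art$dry_gt)
        if (isTRUE(config$qi$enabled)) {
          qp <- qi_preset(config$qi$preset, pixel_size = config$qi$pixel_size,
                          seed = config$seeds$qi)
          write_qi(render_qi(wet, qp), art$qi_h5)
        }
        plog(logfile, stage, "models + renders written (%d wet pores), %.1fs",
             nrow(wet$pores), as.numeric(Sys.time() - t0, units = "secs"))
      },
      segment = {
        sp <- do.call(segmentation_params, config$segmentation %||% list())
        for (side in c("wet", "dry")) {
          img <- read_raster(need_file(art[[paste0(side, "_tif")]], "simulate"))
          tab <- segment_image(img, sp)
          write_pore_table(tab, art[[paste0(side, "_tab")]])
        }
        plog(logfile, stage, "segmented wet + dry, %.1fs",
             as.numeric(Sys.time() - t0, units = "secs"))
      },
      qi = {
        if (!isTRUE(config$qi$enabled)) {
          plog(logfile, stage, "qi disabled in config, skipped")
        } else {
          qm <- read_qi(need_file(art$qi_h5, "simulate"))
          tomo <- force_tomography(qm, unlist(config$qi$tomography_forces))
          write.csv(tomo, art$tomo, row.names = FALSE)
          plog(logfile, stage, "tomography at %s pN, %.1fs",
               paste(config$qi$tomography_forces, collapse = "/"),
               as.numeric(Sys.time() - t0, units = "secs"))
        }
      },
      match = {
        wet <- read_pore_table(need_file(art$wet_tab, "segment"))
        dry <- read_pore_table(need_file(art$dry_tab, "segment"))
        tr <- if (!is.null(config$landmarks_file)) {
          fit_transform(read_landmarks(config$landmarks_file),
                        kind = config$matching$transform_kind %||% "similarity")
        } else identity_transform()
        mt <- match_pores(wet, dry, tr, gate = config$matching$gate)
        write_match_table(mt, art$matches)
        write_transform(tr, art$transform)
        plog(logfile, stage, "%d pairs matched (gate %g nm), %.1fs",
             nrow(mt$pairs), config$matching$gate,
             as.numeric(Sys.time() - t0, units = "secs"))
      },
      stats = {
        wet <- read_pore_table(need_file(art$wet_tab, "segment"))
        dry <- read_pore_table(need_file(art$dry_tab, "segment"))
        mt <- read_match_table(need_file(art$matches, "match"))
        fw <- fit_diameter_distribution(wet, config$stats$diameter_bin)
        fd <- fit_diameter_distribution(dry, config$stats$diameter_bin)
        res <- list(
          wet_fit = fw[c("mu", "sigma", "n", "fallback")],
          dry_fit = fd[c("mu", "sigma", "n", "fallback")],
          wet_roundness = roundness_stats(wet)[c("mean", "sd", "n")],
          dry_roundness = roundness_stats(dry)[c("mean", "sd", "n")],
          paired_diameter = paired_regression(mt, wet, dry, "d_eq"),
          paired_area = paired_regression(mt, wet, dry, "area"),
          percent_change = percent_change(fw$mu, fd$mu),
          correction = correction_coefficient(list(c(fw$mu, fd$mu))),
          wet_porosity = porosity_frequency(wet),
          dry_porosity = porosity_frequency(dry),
          provenance = prov)
        jsonlite::write_json(res, art$stats, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        plog(logfile, stage, "percent change %g%%, %.1fs",
             res$percent_change, as.numeric(Sys.time() - t0, units = "secs"))
      },
      report = {
        wet <- read_pore_table(need_file(art$wet_tab, "segment"))
        dry <- read_pore_table(need_file(art$dry_tab, "segment"))
        mt <- read_match_table(need_file(art$matches, "match"))
        fw <- fit_diameter_distribution(wet, config$stats$diameter_bin)
        fd <- fit_diameter_distribution(dry, config$stats$diameter_bin)
        build_report(
          tables = list(wet = wet, dry = dry), matches = mt,
          diameter_fits = list(wet = fw, dry = fd),
          roundness = list(wet = roundness_stats(wet),
                           dry = roundness_stats(dry)),
          paired = list(d_eq = paired_regression(mt, wet, dry, "d_eq"),
                        area = paired_regression(mt, wet, dry, "area")),
          percent_changes = list(wet_to_dry = percent_change(fw$mu, fd$mu)),
          correction = correction_coefficient(list(c(fw$mu, fd$mu))),
          params = prov, path = art$report)
        plog(logfile, stage, "report written, %.1fs",
             as.numeric(Sys.time() - t0, units = "secs"))
      })
  }
  invisible(art)
}
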