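#' Read a pipeline run configuration
#'
#' A single YAML file drives all pipeline stages. Missing keys fall back
#' to the assay defaults: the standard 333 -> 466 -> 333 protocol, 0.5 Hz
#' sampling, 0.2 um/px, 5% radius noise, the published group presets, and
#' seed 1.
#'
#' @param path YAML file path, or NULL for an all-defaults config.
#' @return A named list (the config).
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    groups = c("untreated", "TNFa", "CN03+TNFa"),
    cells_per_group = 12,
    modulus_cells_per_group = 45,
    protocol = list(osmolarity = c(466, 333), duration = c(300, 300),
                    equilibration = 333),
    temperature_k = 295.15,
    sampling_interval_s = 2,
    pixel_size_um = 0.2,
    radius_noise_cv = 0.05,
    force_noise_frac = 0.02,
    tip_radius_m = 3e-6,
    field_size_px = 512,
    cells_per_field = 8,
    seed = 1)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

.cfgProtocol <- function(cfg)
  OsmoticProtocol(cfg$protocol$osmolarity, cfg$protocol$duration,
                  cfg$protocol$equilibration)

.cfgConstants <- function(cfg) modelConstants(cfg$temperature_k)

# Manifest ties outputs to config hash, seed and package version.
.writeManifest <- function(cfg, dir, files) {
  cfgPath <- file.path(dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfgPath)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfgPath)),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("cellosmo")),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate all synthetic datasets for a run
#'
#' For every configured treatment group: draws the cell population,
#' simulates noisy volume traces, generates Hertz force curves at the
#' sampled moduli, and renders image fields of disks at the sampled
#' radii. Writes traces, curves, truth tables (CSV), image stacks (TIFF)
#' and a run manifest into \code{outDir}.
#'
#' @param cfg Config list from \code{\link{readRunConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the manifest.
#' @export
runSimulate <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  protocol <- .cfgProtocol(cfg)
  constants <- .cfgConstants(cfg)
  files <- character()
  truthAll <- list()
  for (g in seq_along(cfg$groups)) {
    grp <- cfg$groups[[g]]
    seed <- cfg$seed + g
    pop <- samplePopulation(grp, cfg$cells_per_group, seed = seed)
    tv <- makeVolumeTraces(pop, protocol,
                           radiusNoiseCV = cfg$radius_noise_cv,
                           seed = seed, constants = constants,
                           samplingInterval = cfg$sampling_interval_s)
    safe <- gsub("[^A-Za-z0-9]", "_", grp)
    f1 <- file.path(outDir, paste0("traces_", safe, ".csv"))
    writeVolumeTraces(tv$traces, f1)

    popE <- samplePopulation(grp, cfg$modulus_cells_per_group,
                             seed = seed + 1000)
    curves <- makeForceCurves(popE$modulus_pa,
                              tipRadius = cfg$tip_radius_m,
                              contactOffset = 1e-7,
                              noiseSD = cfg$force_noise_frac,
                              seed = seed)
    f2 <- file.path(outDir, paste0("forcecurves_", safe, ".csv"))
    writeForceCurves(curves, f2)

    nField <- min(cfg$cells_per_field, nrow(pop))
    rf <- renderFrameSequence(pop$radius_um[seq_len(nField)],
                              nFrames = 1,
                              pixelSize = cfg$pixel_size_um,
                              fieldSize = cfg$field_size_px, seed = seed)
    f3 <- file.path(outDir, paste0("field_", safe, ".tif"))
    EBImage::writeImage(EBImage::Image(rf$frames[[1]]), f3, type = "tiff")
    truthAll[[grp]] <- pop
    files <- c(files, f1, f2, f3)
  }
  truth <- do.call(rbind, truthAll)
  f4 <- file.path(outDir, "truth.csv")
  utils::write.csv(truth, f4, row.names = FALSE)
  invisible(.writeManifest(cfg, outDir, c(files, f4)))
}

#' Fit all datasets of a simulated run
#'
#' Reads the datasets written by \code{\link{runSimulate}} and produces
#' per-cell results: mixture-model fits per osmotic step, Hertz fits, and
#' morphometry of the rendered fields (segmentation, gating, radius).
#' Corrupt or missing rows are skipped with a message; missing datasets
#' raise a named error.
#'
#' @param cfg Config list.
#' @param inDir Directory produced by \code{runSimulate}.
#' @param outDir Output directory for result CSVs.
#' @return Invisibly, a list of the three result data.frames.
#' @export
runFit <- function(cfg, inDir, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  protocol <- .cfgProtocol(cfg)
  constants <- .cfgConstants(cfg)
  osmo <- list(); hertz <- list(); morpho <- list()
  for (grp in cfg$groups) {
    safe <- gsub("[^A-Za-z0-9]", "_", grp)
    f1 <- file.path(inDir, paste0("traces_", safe, ".csv"))
    if (!file.exists(f1)) stop("missing dataset: ", f1)
    traces <- readVolumeTraces(f1)
    for (tr in traces) {
      res <- tryCatch(
        fitTwoStepSequence(tr, protocol, constants),
        error = function(e) {
          message("skipping trace ", cellId(tr), ": ",
                  conditionMessage(e)); NULL
        })
      if (!is.null(res)) {
        tab <- mixtureFitTable(res)
        tab$group <- grp
        osmo[[length(osmo) + 1]] <- tab
      }
    }
    f2 <- file.path(inDir, paste0("forcecurves_", safe, ".csv"))
    if (!file.exists(f2)) stop("missing dataset: ", f2)
    curves <- readForceCurves(f2)
    fits <- lapply(curves, fitHertz)
    ht <- hertzFitTable(fits)
    ht$group <- grp
    hertz[[length(hertz) + 1]] <- ht

    f3 <- file.path(inDir, paste0("field_", safe, ".tif"))
    if (!file.exists(f3)) stop("missing dataset: ", f3)
    img <- EBImage::imageData(EBImage::readImage(f3))
    mask <- segmentCells(img, pixelSize = cfg$pixel_size_um)
    sm <- gateSingleCells(shapeMetrics(mask))
    if (nrow(sm)) sm$group <- grp
    morpho[[length(morpho) + 1]] <- sm
  }
  res <- list(osmotic = do.call(rbind, osmo),
              hertz = do.call(rbind, hertz),
              morphometry = do.call(rbind, morpho))
  utils::write.csv(res$osmotic, file.path(outDir, "osmotic_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$hertz, file.path(outDir, "hertz_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$morphometry,
                   file.path(outDir, "morphometry.csv"),
                   row.names = FALSE)
  .writeManifest(cfg, outDir,
                 c("osmotic_fits.csv", "hertz_fits.csv",
                   "morphometry.csv"))
  invisible(res)
}

#' Summarize a fitted run into group-level report tables
#'
#' Produces per-group mean/SD/n tables for each measured metric
#' (hyper/hypo Lp, phir, modulus, radius, circularity), group
#' comparisons (t test for two groups, ANOVA + Fisher LSD beyond), and
#' the group-mean scaling regression of hyperosmotic Lp against
#' circularity when at least three groups carry both. Metrics whose
#' preset is unavailable are reported as "null (figure-only in source)".
#'
#' @param cfg Config list.
#' @param inDir Directory produced by \code{runFit}.
#' @param outFile Output CSV path for the summary table.
#' @return Invisibly, a list with \code{summary}, \code{tests},
#'   \code{scaling}.
#' @export
runReport <- function(cfg, inDir, outFile) {
  osmo <- utils::read.csv(file.path(inDir, "osmotic_fits.csv"))
  hertz <- utils::read.csv(file.path(inDir, "hertz_fits.csv"))
  morpho <- utils::read.csv(file.path(inDir, "morphometry.csv"))

  tidy <- rbind(
    data.frame(metric = paste0("Lp_", osmo$step_label),
               group = osmo$group, value = osmo$Lp),
    data.frame(metric = paste0("phir_", osmo$step_label),
               group = osmo$group, value = osmo$phir),
    data.frame(metric = "modulus_pa", group = hertz$group,
               value = hertz$E_Pa),
    data.frame(metric = "radius_um", group = morpho$group,
               value = morpho$radius_um),
    data.frame(metric = "circularity", group = morpho$group,
               value = morpho$circularity))
  tidy <- tidy[is.finite(tidy$value), ]
  summ <- groupSummary(tidy)

  pre <- groupPresets()
  missing <- pre[pre$group %in% cfg$groups & is.na(pre$circularity_rel),
                 "group"]
  if (length(missing))
    summ <- rbind(summ, data.frame(
      metric = "circularity_rel_preset", group = missing, n = NA,
      mean = NA, sd = NA, norm_mean = NA))
  summ$note <- ifelse(is.na(summ$mean), "null (figure-only in source)", "")

  tests <- lapply(split(tidy, tidy$metric), function(d) {
    d <- d[!is.na(d$value), ]
    if (length(unique(d$group)) < 2 || any(table(d$group) < 2))
      return(NULL)
    compareGroups(d$value, d$group)
  })

  gm <- summ[summ$metric == "Lp_hyper" & is.finite(summ$mean), ]
  cm <- summ[summ$metric == "circularity" & is.finite(summ$mean), ]
  shared <- intersect(gm$group, cm$group)
  scaling <- if (length(shared) >= 3)
    scalingRelationship(cm$mean[match(shared, cm$group)],
                        gm$mean[match(shared, gm$group)] * 1e14)
  else NULL

  utils::write.csv(summ, outFile, row.names = FALSE)
  invisible(list(summary = summ, tests = tests, scaling = scaling))
}
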