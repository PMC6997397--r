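#' Read and validate a run configuration
#'
#' One YAML file drives all pipeline stages. Global keys: \code{seed},
#' \code{outdir}; stage sections: \code{simulate} (cell line block, treatments,
#' scan days, render settings), \code{quantify} (input files / channel order),
#' \code{curves} (grouping, peak-PI window), \code{fit} (clonogenic CSV path),
#' \code{isoeffect} (target effect or reference dose, radiation grid). Units
#' are microns, Gy and CEM43 throughout.
#'
#' @param path YAML file path.
#' @param overrides named list overriding top-level keys (CLI flags).
#' @return Validated config list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed)) stop("config field 'seed' must be an integer")
  if (is.null(cfg$outdir)) stop("config field 'outdir' is required")
  class(cfg) <- "RunConfig"
  cfg
}

.logmsg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}

# manifest: config hash, seed, package version, artifact list
.writeManifest <- function(cfg, outdir, artifacts) {
  tmp <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("spheroTx")),
    artifacts = artifacts
  )
  unlink(tmp)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.simConfigFromBlock <- function(block, seed) {
  args <- block[intersect(names(block),
                          names(formals(simConfig)))]
  if (!is.null(block$survivalParams))
    args$survivalParams <- do.call(survivalParams, block$survivalParams)
  args$seed <- seed
  do.call(simConfig, args)
}

#' Run the simulation stage
#'
#' Generates one synthetic time-lapse per configured treatment: a multi-page
#' TIFF (pages alternate phase, PI), a ground-truth CSV per treatment, and a
#' manifest. Ground-truth dynamics are deterministic; the seed only drives
#' image noise, so reruns with the same config give byte-identical
#' ground-truth CSVs.
#'
#' @param cfg a \code{RunConfig} with a \code{simulate} section containing
#'   \code{treatments} (list of \code{{label, doseGy, cem43}}), optional
#'   simulator fields (see [simConfig()]), optional \code{scanDays} and an
#'   optional \code{render} block (see [renderConfig()]).
#' @return Invisibly, the list of written artifact paths.
#' @export
runSimulate <- function(cfg) {
  if (is.null(cfg$simulate)) stop("config has no 'simulate' section")
  blk <- cfg$simulate
  if (is.null(blk$treatments) || !length(blk$treatments))
    stop("simulate section must list at least one treatment")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  scanDays <- if (is.null(blk$scanDays)) 0:21 else unlist(blk$scanDays)
  rcfg <- if (is.null(blk$render)) renderConfig()
          else do.call(renderConfig, blk$render)
  sc <- .simConfigFromBlock(blk, seed = cfg$seed)

  artifacts <- character(0)
  for (k in seq_along(blk$treatments)) {
    tb <- blk$treatments[[k]]
    for (f in c("label", "doseGy", "cem43"))
      if (is.null(tb[[f]])) stop("treatment ", k, ": missing required field '", f, "'")
    tr <- treatmentSpec(tb$doseGy, cem43 = tb$cem43, label = tb$label)
    .logmsg("simulating ", tb$label)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", tb$label)
    tifPath <- file.path(cfg$outdir, paste0(safe, ".tif"))
    truthPath <- file.path(cfg$outdir, paste0(safe, "_truth.csv"))
    frames <- list()
    tl <- generateTimeLapse(sc, tr, rcfg, scanDays = scanDays,
                            seed = cfg$seed + k,
                            frameCallback = function(frame, truthRow) {
                              frames[[length(frames) + 1L]] <<- frame
                            })
    writeTimeLapseTIFF(frames, tifPath)
    write.csv(tl$truth, truthPath, row.names = FALSE)
    artifacts <- c(artifacts, tifPath, truthPath)
  }
  mp <- .writeManifest(cfg, cfg$outdir, artifacts)
  invisible(c(artifacts, mp))
}

#' Run the quantification stage
#'
#' Reads each input time-lapse TIFF, segments and measures every frame, and
#' writes one metrics CSV per input. Unreadable files are logged and skipped;
#' the run continues.
#'
#' @param cfg a \code{RunConfig} with a \code{quantify} section:
#'   \code{inputs} (TIFF paths; defaults to all .tif in \code{outdir}),
#'   optional \code{pixelSizeUm}, \code{scanDays}, \code{piRegion}.
#' @return Invisibly, the metrics CSV paths.
#' @export
runQuantify <- function(cfg) {
  blk <- cfg$quantify
  inputs <- blk$inputs
  if (is.null(inputs))
    inputs <- list.files(cfg$outdir, pattern = "\\.tif$", full.names = TRUE)
  if (!length(inputs)) stop("no input TIFFs to quantify")
  px <- if (is.null(blk$pixelSizeUm)) 1 else blk$pixelSizeUm
  scanDays <- if (is.null(blk$scanDays)) NULL else unlist(blk$scanDays)
  piRegion <- if (is.null(blk$piRegion)) "image" else blk$piRegion
  outPaths <- character(0)
  for (p in inputs) {
    res <- tryCatch({
      times <- if (is.null(scanDays)) NULL else scanDays * 24
      frames <- readTimeLapseTIFF(p, pixelSize = px, timesHours = times)
      rows <- lapply(seq_along(frames), function(i)
        quantifyFrame(frames[[i]], frameId = sprintf("f%03d", i - 1L),
                      piRegion = piRegion))
      metrics <- do.call(rbind, rows)
      out <- sub("\\.tif$", "_metrics.csv", p)
      writeMetricsCSV(metrics, out)
      out
    }, error = function(e) {
      .logmsg("skipping ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) outPaths <- c(outPaths, res)
  }
  if (!length(outPaths)) stop("no input could be quantified")
  invisible(outPaths)
}

#' Run the reporting stage
#'
#' Assembles growth and PI curves per treatment from metrics CSVs (grouping
#' repeats by file), classifies growth regimes, regresses peak PI on
#' biological effect when survival parameters are available, optionally fits
#' survival parameters from a clonogenic CSV and solves isoeffective dose
#' combinations. Writes growth-curve CSVs and a report JSON with explicit
#' units.
#'
#' @param cfg a \code{RunConfig}; uses sections \code{report} (metrics file
#'   patterns grouped per treatment: named lists of paths), optional
#'   \code{fit} (\code{clonogenicCsv}) and \code{isoeffect}
#'   (\code{targetEffect} or \code{referenceDoseGy}, \code{radiationGrid}).
#' @return Invisibly, the report JSON path.
#' @export
runReport <- function(cfg) {
  blk <- cfg$report
  if (is.null(blk) || is.null(blk$groups))
    stop("config has no 'report$groups' section")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(units = list(diameter = "um", dose = "Gy",
                              thermal_dose = "CEM43", time = "days"))

  curves <- list()
  for (label in names(blk$groups)) {
    paths <- unlist(blk$groups[[label]])
    series_d <- list(); series_pi <- list()
    for (p in paths) {
      m <- readMetricsCSV(p)
      series_d[[length(series_d) + 1L]] <-
        data.frame(day = m$time_h / 24, value = m$mean_diameter_um)
      series_pi[[length(series_pi) + 1L]] <-
        data.frame(day = m$time_h / 24, value = m$mean_pi)
    }
    gc <- assembleGrowthCurve(series_d, units = "um")
    pc <- assembleGrowthCurve(series_pi, units = "PI intensity")
    writeGrowthCurveCSV(gc, file.path(cfg$outdir, paste0(label, "_growth.csv")))
    writeGrowthCurveCSV(pc, file.path(cfg$outdir, paste0(label, "_pi.csv")))
    regime <- classifyRegime(gc, pc)
    if (!gc@publicationGrade)
      .logmsg("group ", label, ": fewer than 3 repeats; publication-grade flag is FALSE")
    curves[[label]] <- list(regime = as.character(regime),
                            regrowth = attr(regime, "regrowth"),
                            publication_grade = gc@publicationGrade,
                            peak_pi = tryCatch(peakPI(pc), error = function(e) NULL))
  }
  report$groups <- curves

  if (!is.null(cfg$fit) && !is.null(cfg$fit$clonogenicCsv)) {
    rec <- readClonogenicCSV(cfg$fit$clonogenicCsv)
    fixed <- if (is.null(cfg$fit$fixed)) list() else cfg$fit$fixed
    fit <- fitSurvivalParams(rec, fixed = fixed)
    p <- fit$params
    report$survival_fit <- list(
      cell_line = p@cellLine,
      alpha0_per_gy = p@alpha0, beta_per_gy2 = p@beta,
      a_thermal_per_cem43 = p@aThermal, b_thermal_per_cem43_2 = p@bThermal,
      c_sens_per_cem43 = p@cSens,
      rss = fit$rss, converged = fit$converged)

    if (!is.null(cfg$isoeffect)) {
      iso <- cfg$isoeffect
      target <- if (!is.null(iso$targetEffect)) iso$targetEffect
                else if (!is.null(iso$referenceDoseGy))
                  biologicalEffect(survivalFraction(
                    treatmentSpec(iso$referenceDoseGy), p))
                else stop("isoeffect section needs targetEffect or referenceDoseGy")
      grid <- if (is.null(iso$radiationGrid)) c(0, 2, 5, 10)
              else unlist(iso$radiationGrid)
      tab <- isoeffectCombinations(target, p, grid)
      report$isoeffect <- list(target_effect = target,
                               units = list(dose = "Gy", thermal = "CEM43"),
                               combinations = tab)
    }
  }

  path <- file.path(cfg$outdir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  .writeManifest(cfg, cfg$outdir, path)
  invisible(path)
}
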