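## Pipeline orchestration: simulate -> segment -> score -> localize ->
## dynamics -> chip, with YAML config, manifest validation, provenance and
## deterministic re-runs.

## 16-bit TIFF I/O. Intensities are float photons internally; on export they
## are multiplied by `gain` and quantized to 16-bit counts.

#' Write one field as a pair of 16-bit grayscale TIFFs
#'
#' @param field a [FieldImage-class].
#' @param redPath,greenPath output file paths.
#' @param gain counts per photon used for quantization (default 1).
#' @return invisibly, the two paths.
#' @export
writeFieldImage <- function(field, redPath, greenPath, gain = 1) {
  q <- function(m) round(pmin(pmax(m * gain, 0), 65535)) / 65535
  tiff::writeTIFF(q(redChannel(field)), redPath, bits.per.sample = 16L)
  tiff::writeTIFF(q(greenChannel(field)), greenPath, bits.per.sample = 16L)
  invisible(c(redPath, greenPath))
}

#' Read a field from a pair of 16-bit grayscale TIFFs
#'
#' @param redPath,greenPath input file paths.
#' @param pixelSize micrometres per pixel.
#' @param gain counts per photon used at export (default 1).
#' @param meta metadata list.
#' @return a [FieldImage-class].
#' @export
readFieldImage <- function(redPath, greenPath, pixelSize = 0.1, gain = 1,
                           meta = list()) {
  r <- tiff::readTIFF(redPath) * 65535 / gain
  g <- tiff::readTIFF(greenPath) * 65535 / gain
  new("FieldImage", red = r, green = g, pixelSize = pixelSize, meta = meta)
}

## CSV with a '#'-prefixed provenance header; no timestamps, so identical
## runs produce byte-identical files.
.writeCsv <- function(df, path, prov = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(prov)) writeLines(paste0("# ", prov), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Validate a field manifest
#'
#' Checks the manifest CSV (columns `field`, `condition`, `replicate`,
#' `timepoint`, `red`, `green`): unique field ids, both channel files
#' present on disk, and matching image dimensions. All violations are
#' collected, not just the first.
#'
#' @param path manifest CSV path.
#' @return list with `manifest` (data.frame) and `violations` (character;
#'   empty when valid).
#' @export
validateManifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  mf <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  v <- character()
  need <- c("field", "condition", "replicate", "timepoint", "red", "green")
  miss <- setdiff(need, names(mf))
  if (length(miss)) {
    v <- c(v, paste("missing column(s):", paste(miss, collapse = ", ")))
    return(list(manifest = mf, violations = v))
  }
  dup <- mf$field[duplicated(mf$field)]
  if (length(dup))
    v <- c(v, paste("duplicate field id(s):", paste(unique(dup),
                                                    collapse = ", ")))
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  for (i in seq_len(nrow(mf))) {
    rp <- resolve(mf$red[i]); gp <- resolve(mf$green[i])
    if (!file.exists(rp)) {
      v <- c(v, paste0("field '", mf$field[i], "': red file missing (",
                       mf$red[i], ")"))
      next
    }
    if (!file.exists(gp)) {
      v <- c(v, paste0("field '", mf$field[i], "': green file missing (",
                       mf$green[i], ")"))
      next
    }
    dr <- dim(tiff::readTIFF(rp)); dg <- dim(tiff::readTIFF(gp))
    if (!identical(dr, dg))
      v <- c(v, paste0("field '", mf$field[i], "': channel shapes differ (",
                       paste(dr, collapse = "x"), " vs ",
                       paste(dg, collapse = "x"), ")"))
  }
  list(manifest = mf, violations = v)
}

## Default pipeline configuration; every entry is overridable from the YAML.
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    gain = 1,
    scene = list(imageShape = c(128L, 128L), nCells = 4L, cellRadius = 14,
                 backgroundSmoothness = 20),
    conditions = list(list(name = "wt_starved", recruitedFraction = 1),
                      list(name = "wt_rich", recruitedFraction = 0)),
    nReplicates = 3L, nFields = 2L,
    reference = "wt_starved", compare = "wt_rich",
    segmentation = list(anchor = list(), prey = list(gaussSigma = 1.5)),
    scoring = list(areaMode = "overlap"),
    localization = list(dMin = 1, dMax = 4, margin = 0.15,
                        prominenceNmad = 3),
    dynamics = list(slowThreshold = 0.2, kinetics = list()),
    chip = list(target = "35S", control = "chrVII", referenceLocus = "5S",
                referenceCondition = "rich", efficiency = 1,
                occupancy = list(
                  list(condition = "rich", locus = "35S", occ = 1),
                  list(condition = "rich", locus = "5S", occ = 1),
                  list(condition = "rich", locus = "chrVII", occ = 1),
                  list(condition = "starved", locus = "35S", occ = 0.05),
                  list(condition = "starved", locus = "5S", occ = 1),
                  list(condition = "starved", locus = "chrVII", occ = 1)))
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.sceneFromConfig <- function(cfg) {
  sp <- cfg$scene
  allowed <- names(formals(sceneParams))
  do.call(sceneParams, sp[intersect(names(sp), allowed)])
}

.segFromConfig <- function(lst, base) {
  allowed <- names(formals(segmentationParams))
  args <- lst[intersect(names(lst), allowed)]
  do.call(segmentationParams, utils::modifyList(base, args))
}

#' Run the full PICT analysis pipeline
#'
#' Executes all stages in dependency order on a synthetic data set generated
#' from the configuration: field simulation (TIFFs + manifest + ground
#' truth), manifest validation, per-channel segmentation, recruitment
#' scoring with replicate pooling and condition summaries, inter-anchor
#' localization, kinetic time-course analysis, and the ChIP-qPCR occupancy
#' chain. Every CSV carries a provenance header (config hash, seed, package
#' version); re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config a configuration list, or the path of a YAML file with the
#'   same structure; missing entries take the defaults of
#'   `defaultPipelineConfig()`.
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, a list with the stage results and output paths.
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  failMarker <- file.path(outDir, "FAILED")
  if (file.exists(failMarker)) unlink(failMarker)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "w")
  on.exit(close(logCon), add = TRUE)
  logmsg <- function(...) writeLines(paste0(...), logCon)

  cfgYaml <- yaml::as.yaml(cfg)
  cfgPath <- file.path(outDir, "config_used.yaml")
  writeLines(cfgYaml, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  prov <- c(paste0("config_md5: ", cfgHash),
            paste0("seed: ", cfg$seed),
            paste0("PICTquant_version: ",
                   as.character(utils::packageVersion("PICTquant"))))

  runStage <- function(name, expr) {
    logmsg("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, " failed: ",
                        conditionMessage(e)), failMarker)
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- simulate ------------------------------------------------------------
  scene <- .sceneFromConfig(cfg)
  fields <- list()
  manifest <- data.frame()
  gt <- data.frame()
  runStage("simulate", {
    for (cd in cfg$conditions) {
      p <- scene
      for (nm in setdiff(names(cd), "name"))
        slot(p, nm) <- if (nm %in% c("nCells", "anchorsPerCell"))
          as.integer(cd[[nm]]) else cd[[nm]]
      sim <- simulateCondition(p, cfg$nReplicates, cfg$nFields,
                               baseSeed = fieldSeed(cfg$seed,
                                                    match(cd$name,
                                                          vapply(cfg$conditions,
                                                                 `[[`,
                                                                 character(1),
                                                                 "name")), 0L),
                               condition = cd$name)
      for (r in seq_along(sim)) for (f in seq_along(sim[[r]])) {
        id <- paste(cd$name, r, f, sep = "_")
        rp <- file.path(outDir, paste0(id, "_RFP.tif"))
        gp <- file.path(outDir, paste0(id, "_GFP.tif"))
        writeFieldImage(sim[[r]][[f]]$field, rp, gp, gain = cfg$gain)
        fields[[id]] <- sim[[r]][[f]]
        manifest <- rbind(manifest, data.frame(
          field = id, condition = cd$name, replicate = r, timepoint = 0,
          red = basename(rp), green = basename(gp)))
        tr <- sim[[r]][[f]]$truth
        cells <- groundTruthCells(tr)
        if (nrow(cells))
          gt <- rbind(gt, cbind(field = id, cells))
      }
    }
    .writeCsv(manifest, file.path(outDir, "manifest.csv"), prov)
    .writeCsv(gt, file.path(outDir, "ground_truth.csv"), prov)
  })

  ## -- validate + segment --------------------------------------------------
  segAll <- list()
  spotRows <- list()
  runStage("segment", {
    chk <- validateManifest(file.path(outDir, "manifest.csv"))
    if (length(chk$violations))
      stop("manifest invalid: ", paste(chk$violations, collapse = "; "))
    ap <- .segFromConfig(cfg$segmentation$anchor, list())
    pp <- .segFromConfig(cfg$segmentation$prey, list(gaussSigma = 1.5))
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$field[i]
      fld <- readFieldImage(file.path(outDir, manifest$red[i]),
                            file.path(outDir, manifest$green[i]),
                            pixelSize = scene@pixelSize, gain = cfg$gain)
      seg <- list(anchors = segmentSpots(redChannel(fld), p = ap),
                  prey = segmentSpots(greenChannel(fld), p = pp))
      segAll[[id]] <- seg
      for (ch in names(seg)) {
        tb <- spotTable(seg[[ch]])
        if (nrow(tb))
          spotRows[[length(spotRows) + 1L]] <- cbind(field = id,
                                                      channel = ch, tb)
      }
    }
    spots <- if (length(spotRows)) do.call(rbind, spotRows) else
      data.frame(field = character(), channel = character())
    .writeCsv(spots, file.path(outDir, "spots.csv"), prov)
  })

  ## -- score ---------------------------------------------------------------
  summaries <- list()
  runStage("score", {
    fieldRows <- list(); repRows <- list()
    byCond <- split(seq_len(nrow(manifest)), manifest$condition)
    repPooled <- list()
    for (cond in names(byCond)) {
      byRep <- split(byCond[[cond]], manifest$replicate[byCond[[cond]]])
      repScores <- numeric(0)
      for (r in names(byRep)) {
        frs <- list()
        for (i in byRep[[r]]) {
          id <- manifest$field[i]
          res <- withCallingHandlers(
            recruitmentScore(greenChannel(fields[[id]]$field),
                             segAll[[id]]$prey, segAll[[id]]$anchors,
                             areaMode = cfg$scoring$areaMode),
            warning = function(w) {
              logmsg("field ", id, ": ", conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          if (!is.null(res)) {
            frs[[length(frs) + 1L]] <- res
            fieldRows[[length(fieldRows) + 1L]] <- data.frame(
              field = id, condition = cond, replicate = as.integer(r),
              yellowArea = yellowArea(res), redArea = redArea(res),
              score = recruitScore(res))
          }
        }
        pooled <- poolReplicate(frs)
        repScores <- c(repScores, recruitScore(pooled))
        repRows[[length(repRows) + 1L]] <- data.frame(
          condition = cond, replicate = as.integer(r),
          yellowArea = yellowArea(pooled), redArea = redArea(pooled),
          score = recruitScore(pooled))
      }
      repPooled[[cond]] <- repScores
    }
    ref0 <- if (!is.null(cfg$reference) && cfg$reference %in% names(repPooled))
      summarizeCondition(cfg$reference, repPooled[[cfg$reference]]) else NULL
    cmp0 <- if (!is.null(cfg$compare) && cfg$compare %in% names(repPooled))
      summarizeCondition(cfg$compare, repPooled[[cfg$compare]]) else NULL
    sumRows <- list()
    for (cond in names(repPooled)) {
      cs <- summarizeCondition(cond, repPooled[[cond]], reference = ref0,
                               comparison = if (!is.null(cmp0) &&
                                                cond != cfg$compare)
                                 cmp0 else NULL)
      summaries[[cond]] <- cs
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        condition = cond, mean = cs@mean, sd = cs@sd, n = cs@n,
        normalized_mean = cs@normalizedMean, normalized_sd = cs@normalizedSd,
        comparison = cs@comparison, p_value = cs@pValue)
    }
    .writeCsv(do.call(rbind, fieldRows),
              file.path(outDir, "scores_fields.csv"), prov)
    .writeCsv(do.call(rbind, repRows),
              file.path(outDir, "scores_replicates.csv"), prov)
    .writeCsv(do.call(rbind, sumRows),
              file.path(outDir, "condition_summary.csv"), prov)
  })

  ## -- localize ------------------------------------------------------------
  runStage("localize", {
    locRows <- list()
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$field[i]
      prs <- pairAnchors(segAll[[id]]$anchors, scene@pixelSize,
                         dMin = cfg$localization$dMin,
                         dMax = cfg$localization$dMax)
      for (k in seq_along(prs)) {
        prof <- profileAnchorPair(fields[[id]]$field, prs[[k]])
        cl <- classifyLocalization(prof$red, prof$green,
                                   margin = cfg$localization$margin,
                                   prominenceNmad =
                                     cfg$localization$prominenceNmad)
        locRows[[length(locRows) + 1L]] <- data.frame(
          field = id, pair = k,
          row1 = prs[[k]]@points[1, 1], col1 = prs[[k]]@points[1, 2],
          row2 = prs[[k]]@points[2, 1], col2 = prs[[k]]@points[2, 2],
          separation_um = prs[[k]]@separation,
          green_peak_fraction = cl@greenPeakFraction, class = cl@locClass)
      }
    }
    loc <- if (length(locRows)) do.call(rbind, locRows) else
      data.frame(field = character(), pair = integer())
    .writeCsv(loc, file.path(outDir, "localization.csv"), prov)
  })

  ## -- dynamics ------------------------------------------------------------
  runStage("dynamics", {
    kin <- do.call(kineticParams, cfg$dynamics$kinetics)
    tcs <- if (!is.null(cfg$dynamics$timecourse_csv)) {
      d <- utils::read.csv(cfg$dynamics$timecourse_csv, comment.char = "#")
      lapply(split(d, d$complex), function(x)
        timeCourse(x$complex[1], x$timepoint_min, x$level))
    } else {
      simulateTimecourse(kin, seed = fieldSeed(cfg$seed, 99L, 1L))
    }
    tcs <- lapply(tcs, normalizeLevels)
    rates <- lapply(tcs, intervalRates)
    lvl <- do.call(rbind, lapply(tcs, function(x) data.frame(
      complex = x@complexId, timepoint_min = timePoints(x),
      level = levelValues(x))))
    rt <- do.call(rbind, lapply(names(rates), function(nm) data.frame(
      complex = tcs[[nm]]@complexId, midpoint_min = rates[[nm]]@midpoints,
      rate_per_min = rates[[nm]]@rates)))
    fits <- list(fitExponentialDecay(tcs[[1]]), fitLogistic(tcs[[2]]))
    ft <- do.call(rbind, lapply(fits, function(f) data.frame(
      model = f@model,
      parameter = names(fitParameters(f)), value = fitParameters(f),
      rss = f@rss, converged = f@converged, degenerate = f@degenerate)))
    st <- classifyStages(rates[[1]], rates[[2]],
                         slowThreshold = cfg$dynamics$slowThreshold,
                         idA = tcs[[1]]@complexId, idB = tcs[[2]]@complexId)
    .writeCsv(lvl, file.path(outDir, "dynamics_levels.csv"), prov)
    .writeCsv(rt, file.path(outDir, "dynamics_rates.csv"), prov)
    .writeCsv(ft, file.path(outDir, "dynamics_fits.csv"), prov)
    .writeCsv(st@intervals, file.path(outDir, "dynamics_stages.csv"), prov)
  })

  ## -- chip ----------------------------------------------------------------
  chipRes <- NULL
  runStage("chip", {
    ch <- cfg$chip
    loci <- unique(vapply(ch$occupancy, `[[`, character(1), "locus"))
    curves <- list()
    curveRows <- list()
    for (i in seq_along(loci)) {
      dil <- simulateDilutionSeries(amplicon = loci[i],
                                    efficiency = ch$efficiency,
                                    ctNoiseSd = 0,
                                    seed = fieldSeed(cfg$seed, 98L, i))
      curves[[loci[i]]] <- fitStandardCurve(dil)
      sc <- curves[[loci[i]]]
      curveRows[[i]] <- data.frame(amplicon = loci[i], slope = sc@slope,
                                   intercept = sc@intercept,
                                   efficiency = sc@efficiency, r2 = sc@r2)
    }
    occDf <- do.call(rbind, lapply(ch$occupancy, as.data.frame))
    cts <- simulateCtTable(occDf, efficiency = ch$efficiency,
                           seed = fieldSeed(cfg$seed, 97L, 1L))
    chipRes <- relativeOccupancy(cts, curves, target = ch$target,
                                  control = ch$control,
                                  referenceLocus = ch$referenceLocus,
                                  referenceCondition = ch$referenceCondition)
    .writeCsv(do.call(rbind, curveRows),
              file.path(outDir, "chip_curves.csv"), prov)
    .writeCsv(chipRes@summary, file.path(outDir, "occupancy.csv"), prov)
  })

  provenance <- list(config_md5 = cfgHash, seed = cfg$seed,
                     version = as.character(utils::packageVersion("PICTquant")),
                     outputs = sort(list.files(outDir, pattern = "\\.csv$")))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("pipeline complete")
  invisible(list(manifest = manifest, summaries = summaries,
                 chip = chipRes, outDir = outDir))
}
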