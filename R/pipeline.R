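#' Default module hypothesis set
#'
#' Builds a nested scan of module hypotheses from a scheme's module labels,
#' from a two-module split (first module versus the rest) through the full
#' partition up to eight modules (splitting the largest modules into
#' anterior/posterior halves), mirroring the structure of published
#' high-density modularity scans. The exact hypothesis set is user
#' configuration; see [readHypotheses()] for supplying your own.
#'
#' @param scheme a [landmarkScheme()].
#' @param maxModules largest hypothesis size to generate (default 8).
#' @return named list of assignments (landmark id -> module label).
#' @export
defaultHypotheses <- function(scheme, maxModules = 8) {
  mods <- schemeModules(scheme)
  M <- length(mods)
  ids <- scheme$id
  base <- setNames(scheme$module, ids)
  hyps <- list()
  ## nested merges: 2 .. M modules
  if (M >= 2) {
    for (j in 1:(M - 1)) {
      a <- base
      rest <- mods[(j + 1):M]
      a[a %in% rest] <- paste(rest, collapse = "+")
      hyps[[sprintf("mod%02d.nested", j + 1)]] <- a
    }
  }
  ## finer hypotheses: split the largest modules in two along landmark order
  sizes <- sort(table(scheme$module), decreasing = TRUE)
  extra <- min(maxModules - M, sum(sizes >= 6))
  if (extra > 0) {
    a <- base
    for (e in seq_len(extra)) {
      m <- names(sizes)[e]
      idx <- which(scheme$module == m)
      half <- idx[seq_len(floor(length(idx) / 2))]
      a[scheme$id[half]] <- paste0(m, ".a")
      a[setdiff(scheme$id[idx], scheme$id[half])] <- paste0(m, ".b")
      hyps[[sprintf("mod%02d.split", M + e)]] <- a
    }
  }
  hyps
}

#' Restrict an aligned dataset to one module's landmarks
#'
#' Keeps the global alignment and the whole-configuration centroid sizes;
#' this is the "globally aligned module" view used by the per-module CAC
#' and dimorphism analyses.
#'
#' @param aligned an `aligned_dataset`.
#' @param module module label.
#' @return an `aligned_dataset` over the module's landmarks.
#' @export
alignedModuleSubset <- function(aligned, module) {
  idx <- which(aligned$scheme$module == module)
  if (!length(idx)) stop("unknown module: ", module)
  scheme <- aligned$scheme[idx, , drop = FALSE]
  scheme$pair[!(scheme$pair %in% scheme$id)] <- NA_character_
  class(scheme) <- c("landmark_scheme", "data.frame")
  out <- aligned
  out$coords <- aligned$coords[idx, , , drop = FALSE]
  out$consensus <- aligned$consensus[idx, , drop = FALSE]
  out$scheme <- scheme
  out$moduleSize <- aligned$moduleSize[module, , drop = FALSE]
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full four-prediction analysis
#'
#' Orchestrates the complete workflow: input (or simulation), mirroring of
#' left-side-only specimens, optional landmark-level retrodeformation,
#' reflection-augmented GPA on the analysis-side (midline + right)
#' landmarks, optional semilandmark sliding, allometry (module size slopes
#' and CAC slopes with pairwise ANCOVAs), modularity (maximum-likelihood
#' hypothesis comparison with the merge rule, covariance ratio on raw and
#' allometry-corrected data), disparity with covariate tests, and the
#' dimorphism dip scan (all specimens and juveniles removed). All
#' randomisation flows from `config$seed` through fixed stage offsets, so
#' the same configuration always yields the same report.
#'
#' @param config a list (or path to a YAML file) with entries: `seed`
#'   (mandatory); either `simulate` (list of [syntheticTruth()] /
#'   [simulateDataset()] arguments) or `input` (list with `path`,
#'   `dialect`, `schemePath`); optional `hypothesesPath`, `retrodeform`
#'   (default TRUE), `slide` (default TRUE), `slideIterations` (3),
#'   `nPerm` (999), `nMc` (2000), `outDir` (`NULL` = nothing written).
#' @return a report list (invisibly written to `outDir` when set) with
#'   elements `modularity`, `allometry`, `disparity`, `dimorphism`,
#'   `predictions` and `log`.
#' @export
runFullAnalysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  nPerm <- config$nPerm %||% 999
  nMc <- config$nMc %||% 2000
  logLines <- character(0)
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }

  ## ---- input -----------------------------------------------------------
  sim <- NULL
  dataset <- .stage("input", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      truthArgs <- args[setdiff(names(args),
                                c("nSpecimens", "nPartial", "kPerModule"))]
      scheme <- makeScheme(kPerModule = args$kPerModule %||% 20)
      truth <- do.call(syntheticTruth, c(list(scheme = scheme), truthArgs))
      sim <- do.call(simulateDataset, list(
        truth = truth, nSpecimens = args$nSpecimens %||% 30,
        nPartial = args$nPartial %||% 14, seed = seed))
      note("simulated ", length(sim$dataset$specimens), " specimens")
      sim$dataset
    } else if (!is.null(config$input)) {
      scheme <- if (!is.null(config$input$schemePath)) {
        readScheme(config$input$schemePath)
      } else NULL
      readLandmarks(config$input$path,
                    dialect = config$input$dialect %||% "long_table",
                    scheme = scheme)
    } else {
      stop("config needs either 'simulate' or 'input'")
    }
  })
  scheme <- dataset$scheme

  ## ---- mirroring of left-only specimens --------------------------------
  dataset <- .stage("mirroring", {
    right <- which(scheme$side == "right")
    left <- which(scheme$side == "left")
    if (length(right)) {
      for (s in seq_along(dataset$specimens)) {
        if (!any(dataset$present[right, s]) && any(dataset$present[left, s])) {
          dataset$coords[, , s] <-
            mirrorIncompleteSide(dataset$coords[, , s], scheme)
          note("mirrored left-side specimen ", dataset$specimens[s])
        }
      }
      dataset <- specimenDataset(dataset$coords, scheme, dataset$specimens,
                                 dataset$retrodeformed)
    }
    dataset
  })

  ## ---- retrodeformation -------------------------------------------------
  if (config$retrodeform %||% TRUE) {
    dataset <- .stage("retrodeformation", {
      for (s in seq_along(dataset$specimens)) {
        if (!all(dataset$present[, s])) next
        res <- tryCatch(
          symmetrizeRetrodeform(dataset$coords[, , s], scheme,
                                maxObliquityDeg = config$maxObliquityDeg %||% 10),
          error = function(e) NULL)
        if (!is.null(res)) {
          dataset$coords[, , s] <- res
          dataset$retrodeformed[s] <- TRUE
        } else {
          note("specimen ", dataset$specimens[s],
               " too oblique to retrodeform; left unchanged")
        }
      }
      dataset
    })
  }

  ## ---- alignment (analysis side: midline + right) ----------------------
  sideIdx <- analysisSideIndex(scheme)
  complete <- which(apply(dataset$present[sideIdx, , drop = FALSE], 2, all))
  if (length(complete) < 4) {
    stop("pipeline stage 'alignment' failed: fewer than 4 complete specimens")
  }
  whole <- .stage("alignment", {
    ds <- subsetDataset(dataset, landmarks = sideIdx, specimens = complete)
    al <- if (any(ds$scheme$midline)) symmetricGPA(ds) else gpa(ds)
    note("aligned ", length(al$specimens), " complete specimens (",
         al$variant, " GPA, ", al$iterations, " iterations)")
    al
  })
  if (config$slide %||% TRUE) {
    whole <- .stage("sliding", {
      sl <- slideSemilandmarks(whole,
                               iterations = config$slideIterations %||% 3)
      en <- attr(sl, "energyLog")
      if (!is.null(en)) {
        note("slid semilandmarks: energy ",
             sprintf("%.4g -> %.4g", en$before[1], en$after[nrow(en)]))
      }
      sl
    })
  }

  ## ---- allometry --------------------------------------------------------
  allo <- .stage("allometry", {
    model <- fitShapeSizeRegression(whole, nPerm = nPerm, seed = seed + 1)
    sizeTab <- moduleSizeAllometry(whole)
    cacTab <- cacSlopePerModule(whole)
    ## pairwise ANCOVAs over per-specimen points
    lw <- log(whole$size)
    ms <- whole$moduleSize
    pts <- do.call(rbind, lapply(rownames(ms), function(m) {
      ok <- !is.na(ms[m, ])
      data.frame(x = lw[ok], y = log(ms[m, ok]), g = m)
    }))
    sizeAncova <- compareSlopesAncova(pts$x, pts$y, pts$g)
    sc <- attr(cacTab, "scores")
    cacAncova <- NULL
    if (!is.null(sc)) {
      modsOnly <- setdiff(colnames(sc), "whole")
      pts2 <- do.call(rbind, lapply(modsOnly, function(m) {
        data.frame(x = lw, y = sc[, m], g = m)
      }))
      cacAncova <- compareSlopesAncova(pts2$x, pts2$y, pts2$g)
    }
    list(model = model, sizeSlopes = sizeTab, cacSlopes = cacTab,
         sizeAncova = sizeAncova, cacAncova = cacAncova)
  })
  corrected <- .stage("allometry-correction",
                      allometryCorrect(whole, allo$model))

  ## ---- modularity -------------------------------------------------------
  modres <- .stage("modularity", {
    hyps <- if (!is.null(config$hypothesesPath)) {
      readHypotheses(config$hypothesesPath, whole$scheme)
    } else {
      defaultHypotheses(whole$scheme)
    }
    n <- length(whole$specimens)
    fitRaw <- emmliFit(congruenceMatrix(whole), hyps, n)
    fitCorr <- emmliFit(congruenceMatrix(corrected), hyps, n)
    merged <- mergeModules(fitCorr)
    crRaw <- covarianceRatio(whole, nPerm = nPerm, seed = seed + 2)
    crCorr <- covarianceRatio(corrected, nPerm = nPerm, seed = seed + 3)
    list(emmliRaw = fitRaw, emmliCorrected = fitCorr, merged = merged,
         crRaw = crRaw, crCorrected = crCorr)
  })

  ## ---- disparity --------------------------------------------------------
  disp <- .stage("disparity", {
    raw <- procrustesVariance(whole)
    corr <- procrustesVariance(corrected)
    dv <- setNames(corr$module$normalized, corr$module$module)
    slopes <- setNames(allo$sizeSlopes$slope, allo$sizeSlopes$module)
    ## within-module congruence per scheme module (the disparity partition)
    cg <- abs(modres$emmliCorrected$corr)
    rhoW <- vapply(names(dv), function(m) {
      sel <- whole$scheme$module == m
      rr <- cg[sel, sel]
      mean(rr[upper.tri(rr)])
    }, numeric(1))
    list(raw = raw, corrected = corr,
         vsGrowth = disparityCovariateTest(dv, slopes),
         vsIntegration = disparityCovariateTest(dv, rhoW))
  })

  ## ---- dimorphism -------------------------------------------------------
  dimo <- .stage("dimorphism", {
    variants <- list(whole = whole)
    for (m in schemeModules(whole$scheme)) {
      variants[[paste0(m, ".global")]] <- alignedModuleSubset(whole, m)
      sep <- tryCatch({
        md <- moduleDataset(subsetDataset(dataset, landmarks = sideIdx), m)
        if (length(md$specimens) >= 4) {
          if (sum(md$scheme$midline) >= 3) symmetricGPA(md) else gpa(md)
        } else NULL
      }, error = function(e) NULL)
      if (!is.null(sep)) variants[[paste0(m, ".separate")]] <- sep
    }
    set.seed(seed + 4)
    dimorphismScan(variants, nComponents = 8, nMc = nMc, seed = NULL)
  })

  ## ---- report -----------------------------------------------------------
  frillLike <- allo$sizeSlopes$module[which.max(allo$sizeSlopes$slope)]
  topCac <- {
    tb <- allo$cacSlopes[allo$cacSlopes$module != "whole", ]
    tb$module[which.max(tb$slope)]
  }
  topDisp <- disp$corrected$module$module[
    which.max(disp$corrected$module$normalized)]
  report <- list(
    modularity = list(
      bestModel = modres$emmliCorrected$best,
      nModulesMerged = modres$merged$nModules,
      mergedModules = unname(unique(modres$merged$mapping)),
      crRaw = modres$crRaw$cr, crRawP = modres$crRaw$p,
      crCorrected = modres$crCorrected$cr,
      crCorrectedP = modres$crCorrected$p),
    allometry = list(
      r2 = allo$model$r2, p = allo$model$p,
      wholeCacSlope = allo$cacSlopes$slope[allo$cacSlopes$module == "whole"],
      topSizeSlopeModule = frillLike,
      topCacSlopeModule = topCac,
      sizeSlopes = allo$sizeSlopes,
      cacSlopes = allo$cacSlopes,
      sizeAncova = allo$sizeAncova,
      cacAncova = allo$cacAncova),
    disparity = list(
      topModule = topDisp,
      module = disp$corrected$module,
      vsGrowth = disp$vsGrowth, vsIntegration = disp$vsIntegration),
    dimorphism = list(
      nTests = nrow(dimo), nFlags = sum(dimo$flag),
      expectedFalseFlags = attr(dimo, "expectedFalseFlags"),
      minP = min(dimo$p), scan = dimo),
    predictions = list(
      modularity_supported = modres$crCorrected$p <= 0.05 &&
        modres$merged$nModules >= 2,
      allometry_top_module = frillLike,
      disparity_top_module = topDisp,
      dimorphism_detected = any(dimo$flag)),
    log = logLines,
    seed = seed
  )
  if (!is.null(sim)) report$truth <- sim$truth
  if (!is.null(config$outDir)) .writeReport(report, whole, config$outDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeReport <- function(report, whole, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeLandmarks(
    specimenDataset(whole$coords, whole$scheme, whole$specimens),
    file.path(outDir, "aligned_coordinates.csv"))
  utils::write.csv(report$allometry$sizeSlopes,
                   file.path(outDir, "module_size_slopes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$allometry$cacSlopes,
                   file.path(outDir, "module_cac_slopes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$disparity$module,
                   file.path(outDir, "disparity.csv"), row.names = FALSE)
  utils::write.csv(report$dimorphism$scan,
                   file.path(outDir, "dip_scan.csv"), row.names = FALSE)
  slim <- report
  slim$allometry$sizeSlopes <- NULL
  slim$allometry$cacSlopes <- NULL
  slim$allometry$sizeAncova <- NULL
  slim$allometry$cacAncova <- NULL
  slim$dimorphism$scan <- NULL
  slim$disparity$module <- NULL
  slim$truth <- NULL
  yaml::write_yaml(slim, file.path(outDir, "report.yaml"))
  invisible(NULL)
}
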