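#' Correlation coefficient between actual and predicted traits
#'
#' Pearson correlation (CC), the accuracy measure of the comparison grid.
#' A constant
#' prediction vector has no defined correlation; by convention it scores 0
#' with a warning, so degenerate models rank last rather than aborting the
#' comparison grid.
#'
#' @param yTrue actual trait values (length >= 3, non-constant).
#' @param yPred predicted trait values, same length.
#' @return a single correlation in [-1, 1].
#' @export
computeCC <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred)) stop("lengths differ")
    if (length(yTrue) < 3L) stop("need at least 3 pairs")
    if (stats::sd(yTrue) == 0)
        stop("degenerate target: actual values are constant")
    if (stats::sd(yPred) == 0) {
        warning("constant predictions: CC reported as 0")
        return(0)
    }
    stats::cor(yTrue, yPred)
}

#' Root-mean-square error between actual and predicted traits
#'
#' @param yTrue actual trait values.
#' @param yPred predicted trait values, same length.
#' @return RMSE in trait units.
#' @export
computeRMSE <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred)) stop("lengths differ")
    if (!length(yTrue)) stop("need at least 1 pair")
    sqrt(mean((yTrue - yPred)^2))
}

#' Pipeline configuration for the comparison experiment
#'
#' Collects every knob of the selection-by-model comparison grid.  Either a
#' simulation configuration (the default synthetic study) or an existing
#' \linkS4class{SeedSpectra} with traits may supply the data.  The master
#' seed drives both the simulation and the GA, making the whole experiment
#' deterministic.
#'
#' @param simulation a \code{\link{simulationConfig}} used when no dataset is
#'   supplied; its \code{rngSeed} is re-derived from \code{masterSeed}.
#' @param dataset optional \linkS4class{SeedSpectra} carrying the traits.
#' @param traits trait column names to model.
#' @param windowLow,windowHigh analysis window in nm (default 430.1-971.5).
#' @param nTrain Kennard-Stone training-set size (default 73).
#' @param hccK number of correlation-ranked bands kept (default 100).
#' @param spaSizes candidate SPA chain lengths (default 5, 10, 15, 20, 25).
#' @param gaKMax,gaGenerations,gaPopSize GA size cap, generations and
#'   population (defaults 20, 100, 50).
#' @param qMax largest component count scanned per model (default 20).
#' @param sigma Gaussian kernel bandwidth for KPCR (default 50).
#' @param masterSeed integer master seed.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(simulation = NULL, dataset = NULL,
                           traits = c("root_length", "seedling_length"),
                           windowLow = 430.1, windowHigh = 971.5,
                           nTrain = 73L, hccK = 100L,
                           spaSizes = c(5L, 10L, 15L, 20L, 25L),
                           gaKMax = 20L, gaGenerations = 100L,
                           gaPopSize = 50L, qMax = 20L, sigma = 50,
                           masterSeed = 1L) {
    if (is.null(dataset) && is.null(simulation))
        simulation <- defaultStudyConfig()
    if (!is.null(simulation)) {
        stopifnot(inherits(simulation, "vigorspec_config"))
        simulation$rngSeed <- .subSeed(masterSeed, 11L)
    }
    structure(list(simulation = simulation, dataset = dataset,
                   traits = traits, windowLow = windowLow,
                   windowHigh = windowHigh, nTrain = as.integer(nTrain),
                   hccK = as.integer(hccK), spaSizes = as.integer(spaSizes),
                   gaKMax = as.integer(gaKMax),
                   gaGenerations = as.integer(gaGenerations),
                   gaPopSize = as.integer(gaPopSize),
                   qMax = as.integer(qMax), sigma = sigma,
                   masterSeed = as.integer(masterSeed)),
              class = "vigorspec_pipeline")
}

.emptyGridRow <- function(trait, selection, model)
    data.frame(trait = trait, selection = selection, model = model,
               cc = NA_real_, rmse = NA_real_, q = NA_integer_,
               n_bands = NA_integer_, status = "failed", message = "",
               stringsAsFactors = FALSE)

#' Run the full selection-by-model comparison experiment
#'
#' Executes the pipeline once: simulate (or take) the dataset, window the
#' spectrum, split by Kennard-Stone, and for every trait, feature setting
#' (none, correlation ranking, SPA, GA) and regressor (PCR, KPCR, PLS):
#' select bands on the training partition only, choose the component count
#' by leave-one-out CV on the training partition, fit, predict the held-out
#' test seeds, and record CC and RMSE.  Band selection and model tuning
#' never see test-set trait values.  A failing cell is recorded as failed
#' and the grid continues.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a data.frame grid (one row per trait x selection x model) with
#'   columns \code{trait, selection, model, cc, rmse, q, n_bands, status,
#'   message}; attribute \code{"details"} carries the split, the per-trait
#'   correlation profiles, selected bands and test-set predictions, and
#'   attribute \code{"provenance"} the seeds and configuration echo.
#' @export
runExperiment <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "vigorspec_pipeline"))
    ds <- if (!is.null(config$dataset)) config$dataset
          else spectra(simulateStudy(config$simulation))
    dsw <- windowBands(ds, config$windowLow, config$windowHigh)
    n <- ncol(dsw)
    nTrain <- min(config$nTrain, n - 2L)
    split <- kennardStoneSplit(dsw, nTrain)
    train <- dsw[, split@trainIds]
    test <- dsw[, split@testIds]
    p <- nrow(train)
    grid <- list()
    details <- list(split = split, scores = list(), selections = list(),
                    predictions = list())
    for (ti in seq_along(config$traits)) {
        trait <- config$traits[ti]
        ytr <- traitVector(train, trait)
        yte <- traitVector(test, trait)
        scores <- tryCatch(bandTraitCorrelation(train, ytr, trait = trait),
                           error = function(e) NULL)
        if (!is.null(scores)) details$scores[[trait]] <- scores
        selections <- list(
            none = function() new("SelectionResult", method = "none",
                selected = seq_len(p), k = p, trait = trait,
                wavelengths = wavelengths(train), scores = numeric(0),
                diagnostics = list()),
            hcc = function() hccSelect(scores, k = min(config$hccK, p)),
            spa = function() spaSelect(train,
                m = config$spaSizes[config$spaSizes <= min(nTrain - 1L, p)],
                start = "auto", y = ytr, trait = trait),
            ga = function() gaSelect(train, ytr, kMax = config$gaKMax,
                generations = config$gaGenerations,
                popSize = config$gaPopSize,
                rngSeed = .subSeed(config$masterSeed, 20L + ti),
                trait = trait))
        for (selName in names(selections)) {
            sel <- tryCatch(selections[[selName]](), error = function(e) e)
            for (model in c("pcr", "kpcr", "pls")) {
                row <- .emptyGridRow(trait, selName, model)
                if (inherits(sel, "error")) {
                    row$message <- conditionMessage(sel)
                    grid[[length(grid) + 1L]] <- row
                    next
                }
                cell <- tryCatch({
                    bands <- selectedBands(sel)
                    Xtr <- spectraMatrix(train)[, bands, drop = FALSE]
                    Xte <- spectraMatrix(test)[, bands, drop = FALSE]
                    ch <- chooseComponents(model, Xtr, ytr, qMax = config$qMax,
                                           sigma = config$sigma)
                    fit <- switch(model,
                        pcr = fitPCR(Xtr, ytr, ch$q, trait = trait),
                        pls = fitPLS(Xtr, ytr, ch$q, trait = trait),
                        kpcr = fitKPCR(Xtr, ytr, ch$q, sigma = config$sigma,
                                       trait = trait))
                    yhat <- predict(fit, Xte)
                    list(cc = computeCC(yte, yhat), rmse = computeRMSE(yte, yhat),
                         q = fit@q, nb = length(bands), yhat = yhat)
                }, error = function(e) e)
                if (inherits(cell, "error")) {
                    row$message <- conditionMessage(cell)
                } else {
                    row$cc <- cell$cc
                    row$rmse <- cell$rmse
                    row$q <- cell$q
                    row$n_bands <- cell$nb
                    row$status <- "ok"
                    details$predictions[[trait]][[selName]][[model]] <-
                        list(actual = yte, predicted = cell$yhat)
                }
                grid[[length(grid) + 1L]] <- row
            }
            if (!inherits(sel, "error"))
                details$selections[[trait]][[selName]] <- selectedBands(sel)
        }
    }
    grid <- do.call(rbind, grid)
    rownames(grid) <- NULL
    attr(grid, "details") <- details
    attr(grid, "provenance") <- list(
        masterSeed = config$masterSeed,
        simulationSeed = if (!is.null(config$simulation)) config$simulation$rngSeed,
        nSeeds = n, nTrain = nTrain, nBands = p,
        window = c(config$windowLow, config$windowHigh),
        hccK = config$hccK, spaSizes = config$spaSizes,
        gaKMax = config$gaKMax, gaGenerations = config$gaGenerations,
        gaPopSize = config$gaPopSize, qMax = config$qMax,
        sigma = config$sigma,
        packageVersion = as.character(utils::packageVersion("vigorspec")))
    grid
}

#' Format a comparison grid the way the tables print it
#'
#' One row per model, CC and RMSE columns per feature setting, numbers to 4
#' decimals.
#'
#' @param grid output of \code{\link{runExperiment}}.
#' @param trait which trait's sub-grid to format.
#' @return a character-matrix-backed data.frame ready for printing.
#' @export
formatEvaluationGrid <- function(grid, trait) {
    g <- grid[grid$trait == trait, ]
    sels <- unique(g$selection)
    out <- data.frame(model = unique(g$model), stringsAsFactors = FALSE)
    for (s in sels) {
        gi <- g[g$selection == s, ]
        out[[paste0(s, "_CC")]] <- sprintf("%.4f", gi$cc[match(out$model, gi$model)])
        out[[paste0(s, "_RMSE")]] <- sprintf("%.4f", gi$rmse[match(out$model, gi$model)])
    }
    out
}

#' Write / read a comparison grid as CSV
#'
#' Full precision is kept so a re-read grid equals the original; use
#' \code{\link{formatEvaluationGrid}} for 4-decimal display.
#'
#' @param grid output of \code{\link{runExperiment}}.
#' @param path CSV file path.
#' @return \code{path} (write) or the grid data.frame (read).
#' @export
writeEvaluationGrid <- function(grid, path) {
    utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEvaluationGrid
#' @export
readEvaluationGrid <- function(path) {
    g <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trait = "character",
                                        selection = "character",
                                        model = "character",
                                        cc = "numeric", rmse = "numeric",
                                        q = "integer", n_bands = "integer",
                                        status = "character",
                                        message = "character"))
    g
}

#' Correlation-vs-wavelength profile plot
#'
#' The per-band correlation of the spectra with each germination trait,
#' drawn across the analysis window: trait-specific profiles show which
#' spectral regions carry each trait's signal.
#'
#' @param scores a \linkS4class{BandScores} or a list of them (one per
#'   trait).
#' @return a ggplot object.
#' @export
plotCorrelationProfile <- function(scores) {
    if (is(scores, "BandScores")) scores <- list(scores)
    df <- do.call(rbind, lapply(scores, function(s)
        data.frame(wavelength = s@wavelengths, score = s@scores,
                   trait = if (nzchar(s@trait)) s@trait else "trait",
                   stringsAsFactors = FALSE)))
    ggplot2::ggplot(df, ggplot2::aes(x = wavelength, y = score,
                                     colour = trait)) +
        ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
        ggplot2::geom_line() +
        ggplot2::labs(x = "wavelength (nm)", y = "correlation with trait",
                      colour = NULL) +
        ggplot2::theme_minimal()
}

#' Actual-versus-predicted trajectory plot
#'
#' Test-set trait values and each model's predictions against the sample
#' index, the standard way prediction quality is eyeballed in seed-vigor
#' grids.
#'
#' @param grid output of \code{\link{runExperiment}} (with details).
#' @param trait trait name.
#' @param selection feature setting whose predictions to draw.
#' @return a ggplot object.
#' @export
plotPredictions <- function(grid, trait, selection = "hcc") {
    det <- attr(grid, "details")
    preds <- det$predictions[[trait]][[selection]]
    if (is.null(preds)) stop("no predictions recorded for that trait/selection")
    actual <- preds[[1L]]$actual
    df <- data.frame(index = seq_along(actual), value = actual,
                     series = "actual", stringsAsFactors = FALSE)
    for (model in names(preds))
        df <- rbind(df, data.frame(index = seq_along(actual),
                                   value = preds[[model]]$predicted,
                                   series = toupper(model),
                                   stringsAsFactors = FALSE))
    ggplot2::ggplot(df, ggplot2::aes(x = index, y = value,
                                     colour = series)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "test sample", y = trait, colour = NULL,
                      title = sprintf("%s (%s selection)", trait, selection)) +
        ggplot2::theme_minimal()
}

#' Write the experiment report files
#'
#' Emits one full-precision CSV grid per trait, a provenance JSON (seeds,
#' sizes, configuration echo) and, where a graphics device is available, the
#' correlation-profile and prediction-trajectory figures as PNG.
#'
#' @param grid output of \code{\link{runExperiment}}.
#' @param dir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
writeExperimentReport <- function(grid, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    det <- attr(grid, "details")
    files <- character(0)
    for (trait in unique(grid$trait)) {
        f <- file.path(dir, sprintf("grid_%s.csv", trait))
        writeEvaluationGrid(grid[grid$trait == trait, ], f)
        files <- c(files, f)
    }
    pf <- file.path(dir, "provenance.json")
    jsonlite::write_json(c(attr(grid, "provenance"),
                           list(selections = det$selections)),
                         pf, auto_unbox = TRUE, digits = NA)
    files <- c(files, pf)
    try({
        if (length(det$scores)) {
            f <- file.path(dir, "correlation_profile.png")
            ggplot2::ggsave(f, plotCorrelationProfile(det$scores),
                            width = 7, height = 4, dpi = 120)
            files <- c(files, f)
        }
        for (trait in names(det$predictions)) {
            sel <- names(det$predictions[[trait]])[1L]
            f <- file.path(dir, sprintf("predictions_%s.png", trait))
            ggplot2::ggsave(f, plotPredictions(grid, trait, sel),
                            width = 7, height = 4, dpi = 120)
            files <- c(files, f)
        }
    }, silent = TRUE)
    invisible(files)
}
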