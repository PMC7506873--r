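# Leave-one-out predictions of an OLS fit with intercept, via the hat-matrix
# shortcut (PRESS): loo residual = e_i / (1 - h_i).
.looPredictions <- function(Xb, y) {
    Z <- cbind(1, as.matrix(Xb))
    qrz <- qr(Z)
    fit <- qr.fitted(qrz, y)
    h <- rowSums(qr.Q(qrz)[, seq_len(qrz$rank), drop = FALSE]^2)
    h <- pmin(h, 1 - 1e-8)
    y - (y - fit) / (1 - h)
}

.looRmse <- function(Xb, y) {
    pred <- .looPredictions(Xb, y)
    sqrt(mean((y - pred)^2))
}

#' Pearson correlation of every band with a trait
#'
#' The correlation-ranking selector scores band b by the Pearson correlation
#' between the per-seed reflectance at that band and the germination trait.
#' Bands with zero variance are given score 0 with a warning.
#'
#' @param ds a \linkS4class{SeedSpectra} (n >= 3 seeds).
#' @param y numeric trait vector, one value per seed, non-constant.
#' @param trait optional trait name recorded in the result.
#' @return a \linkS4class{BandScores}.
#' @examples
#' ss <- SeedSpectra(cbind(1:4, c(1, 3, 2, 4)), wavelengths = c(500, 600))
#' bandTraitCorrelation(ss, c(1, 3, 2, 4))@scores
#' @export
bandTraitCorrelation <- function(ds, y, trait = "") {
    X <- spectraMatrix(ds)
    if (nrow(X) < 3L) stop("need at least 3 seeds to estimate correlations")
    if (length(y) != nrow(X)) stop("'y' must have one value per seed")
    if (stats::sd(y) == 0)
        stop("degenerate target: trait is constant, correlations undefined")
    v <- apply(X, 2L, stats::sd)
    scores <- rep(0, ncol(X))
    if (any(v == 0))
        warning(sprintf("%d zero-variance band(s) given score 0", sum(v == 0)))
    ok <- v > 0
    scores[ok] <- drop(stats::cor(X[, ok, drop = FALSE], y))
    new("BandScores", bandIndices = seq_len(ncol(X)),
        wavelengths = wavelengths(ds), scores = scores, trait = trait)
}

#' Correlation-ranking (HCC) band selection
#'
#' Keeps the k bands with the largest absolute correlation against the
#' trait, ordered by decreasing |score|; both strongly positive and strongly
#' negative bands are informative.  Ties are broken toward the lower band
#' index; requesting more bands than exist returns all of them.
#'
#' @param scores a \linkS4class{BandScores} from
#'   \code{\link{bandTraitCorrelation}}.
#' @param k number of bands to keep (default 100).
#' @return a \linkS4class{SelectionResult}; \code{diagnostics$scores} holds
#'   the full score vector.
#' @export
hccSelect <- function(scores, k = 100L) {
    k <- .assertCount(k, "k")
    p <- length(scores@scores)
    ord <- order(-abs(scores@scores), seq_len(p))
    sel <- ord[seq_len(min(k, p))]
    new("SelectionResult", method = "hcc", selected = as.integer(sel),
        k = k, trait = scores@trait,
        wavelengths = scores@wavelengths[sel],
        scores = scores@scores[sel],
        diagnostics = list(scores = scores@scores))
}

# Greedy SPA chain: starting from one column, repeatedly add the column with
# the largest residual norm after projection onto the orthogonal complement
# of the span of the selected columns.  Columns are used as-is (no
# centering).  Ties break toward the lower band index.
.spaChain <- function(X, start, m) {
    n <- nrow(X); p <- ncol(X)
    sel <- integer(0)
    R <- X
    nextCol <- start
    nv2 <- sum(R[, start]^2)
    for (j in seq_len(m)) {
        sel <- c(sel, nextCol)
        if (j == m) break
        if (nv2 < 1e-12) break  # degenerate start; cannot extend
        q <- R[, nextCol] / sqrt(nv2)
        R <- R - q %*% crossprod(q, R)
        norms <- colSums(R^2)
        norms[sel] <- -Inf
        if (max(norms) < 1e-12) break  # selected set spans the data
        nextCol <- which.max(norms)
        nv2 <- norms[nextCol]
    }
    sel
}

#' Successive projections algorithm (SPA) band selection
#'
#' Greedy forward selection of minimally collinear bands: starting from one
#' column of the spectra matrix, each step adds the band whose column has
#' the largest norm after orthogonal projection onto the complement of the
#' already-selected columns.  With \code{start = "auto"}, every band is
#' tried as the chain start and the chain (and chain length, when \code{m}
#' is a vector of candidate sizes) minimizing the leave-one-out RMSE of an
#' ordinary least-squares model on the selected bands is returned; this
#' requires \code{y}.
#'
#' @param ds a \linkS4class{SeedSpectra}.
#' @param m chain length, between 1 and min(n - 1, p); may be a vector of
#'   candidate lengths when \code{start = "auto"}.
#' @param start integer band index, or "auto".
#' @param y trait vector (required for \code{start = "auto"}).
#' @param trait optional trait name recorded in the result.
#' @return a \linkS4class{SelectionResult}; \code{diagnostics} records the
#'   start column and, for auto starts, the winning LOO RMSE.
#' @export
spaSelect <- function(ds, m, start = "auto", y = NULL, trait = "") {
    X <- spectraMatrix(ds)
    n <- nrow(X); p <- ncol(X)
    m <- sort(unique(as.integer(m)))
    if (any(m < 1L) || any(m > min(n, p)))
        stop(sprintf("invalid config: 'm' must lie in 1..min(n, p) = 1..%d",
                     min(n, p)))
    mMax <- max(m)
    if (identical(start, "auto")) {
        if (is.null(y))
            stop("'y' is required to choose the SPA start column automatically")
        best <- NULL
        for (s in seq_len(p)) {
            if (sum(X[, s]^2) < 1e-12) next
            chain <- .spaChain(X, s, mMax)
            for (mm in m[m <= length(chain)]) {
                r <- .looRmse(X[, chain[seq_len(mm)], drop = FALSE], y)
                if (is.null(best) || r < best$rmse - 1e-12) {
                    best <- list(rmse = r, chain = chain[seq_len(mm)], start = s)
                }
            }
        }
        if (is.null(best)) stop("SPA found no usable start column")
        sel <- best$chain
        diag <- list(start = best$start, looRmse = best$rmse)
    } else {
        if (length(m) != 1L)
            stop("a vector of candidate sizes requires start = 'auto'")
        start <- .assertCount(start, "start")
        if (start > p) stop("invalid config: start column out of range")
        sel <- .spaChain(X, start, mMax)
        if (length(sel) < mMax)
            warning("SPA chain stopped early: selected bands span the data")
        diag <- list(start = start)
    }
    new("SelectionResult", method = "spa", selected = as.integer(sel),
        k = as.integer(mMax), trait = trait,
        wavelengths = wavelengths(ds)[sel], scores = numeric(0),
        diagnostics = diag)
}

# GA fitness: leave-one-out cross-validated correlation between the trait
# and OLS predictions on the masked bands, penalized 0.01 per band above
# kMax.  Masks too large for LOO OLS get a harsh penalty.
.gaFitness <- function(X, y, mask, kMax) {
    k <- sum(mask)
    if (k == 0L) return(-Inf)
    if (k > length(y) - 3L) return(-10 - k)
    pred <- .looPredictions(X[, mask, drop = FALSE], y)
    f <- suppressWarnings(stats::cor(y, pred))
    if (!is.finite(f)) f <- -1
    f - 0.01 * max(0L, k - kMax)
}

#' Genetic-algorithm band selection
#'
#' Searches binary band masks with a generational GA: tournament selection,
#' uniform crossover, bit-flip mutation and single-individual elitism.  The
#' fitness of a mask is the leave-one-out cross-validated Pearson
#' correlation between the trait and an ordinary least-squares model
#' restricted to the masked bands, penalized for masks larger than
#' \code{kMax}.  The best mask ever seen is returned.  Deterministic under
#' \code{rngSeed}.
#'
#' @param ds a \linkS4class{SeedSpectra}.
#' @param y trait vector, one value per seed.
#' @param kMax soft cap on the number of selected bands (default 20).
#' @param generations number of generations (default 100).
#' @param popSize population size (default 50).
#' @param pCrossover per-pair uniform-crossover probability (default 0.8).
#' @param pMutation per-bit mutation probability (default 2/p).
#' @param tournamentSize tournament size for parent selection (default 3).
#' @param rngSeed integer seed.
#' @param trait optional trait name recorded in the result.
#' @param initProb per-bit inclusion probability of the initial population
#'   (default kMax / p, clamped to [2/p, 0.5]).
#' @param initPop optional logical matrix (rows = individuals, columns =
#'   bands) seeded into the initial population, e.g. a known-good mask.
#' @return a \linkS4class{SelectionResult}; \code{diagnostics$trajectory}
#'   holds the best fitness per generation and \code{diagnostics$fitness}
#'   the final best fitness.
#' @export
gaSelect <- function(ds, y, kMax = 20L, generations = 100L, popSize = 50L,
                     pCrossover = 0.8, pMutation = NULL, tournamentSize = 3L,
                     rngSeed = 1L, trait = "", initProb = NULL,
                     initPop = NULL) {
    X <- spectraMatrix(ds)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) stop("'y' must have one value per seed")
    popSize <- .assertCount(popSize, "popSize", min = 2L)
    generations <- .assertCount(generations, "generations")
    kMax <- .assertCount(kMax, "kMax")
    if (is.null(pMutation)) pMutation <- 2 / p
    if (is.null(initProb)) initProb <- min(0.5, max(2 / p, kMax / p))
    .withSeed(rngSeed, {
        pop <- matrix(stats::runif(popSize * p) < initProb, popSize, p)
        if (!is.null(initPop)) {
            initPop <- matrix(as.logical(initPop), ncol = p)
            rows <- seq_len(min(nrow(initPop), popSize))
            pop[rows, ] <- initPop[rows, , drop = FALSE]
        }
        for (i in which(rowSums(pop) == 0L))
            pop[i, sample.int(p, 1L)] <- TRUE
        fit <- apply(pop, 1L, function(mk) .gaFitness(X, y, mk, kMax))
        bestMask <- pop[which.max(fit), ]
        bestFit <- max(fit)
        trajectory <- numeric(generations)
        for (g in seq_len(generations)) {
            newPop <- matrix(FALSE, popSize, p)
            newPop[1L, ] <- bestMask  # elitism of 1
            i <- 2L
            while (i <= popSize) {
                pick <- function() {
                    cand <- sample.int(popSize, tournamentSize)
                    cand[which.max(fit[cand])]
                }
                pa <- pop[pick(), ]; pb <- pop[pick(), ]
                if (stats::runif(1L) < pCrossover) {
                    swap <- stats::runif(p) < 0.5
                    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
                }
                for (child in list(pa, pb)) {
                    if (i > popSize) break
                    flip <- stats::runif(p) < pMutation
                    child[flip] <- !child[flip]
                    newPop[i, ] <- child
                    i <- i + 1L
                }
            }
            pop <- newPop
            fit <- apply(pop, 1L, function(mk) .gaFitness(X, y, mk, kMax))
            if (max(fit) > bestFit) {
                bestFit <- max(fit)
                bestMask <- pop[which.max(fit), ]
            }
            trajectory[g] <- bestFit
        }
        if (!any(bestMask)) {
            warning("GA best mask is empty; falling back to the best single band")
            sc <- bandTraitCorrelation(ds, y)@scores
            bestMask[which.max(abs(sc))] <- TRUE
        }
        sel <- which(bestMask)
        new("SelectionResult", method = "ga", selected = as.integer(sel),
            k = as.integer(length(sel)), trait = trait,
            wavelengths = wavelengths(ds)[sel], scores = numeric(0),
            diagnostics = list(trajectory = trajectory, fitness = bestFit,
                               rngSeed = rngSeed))
    })
}

#' @describeIn hccSelect selected band indices of any selection result.
#' @param x a \linkS4class{SelectionResult}.
#' @export
setMethod("selectedBands", "SelectionResult", function(x) x@selected)

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult[%s]%s: %d band(s)\n", object@method,
                if (nzchar(object@trait)) paste0(" (", object@trait, ")") else "",
                length(object@selected)))
    n <- min(10L, length(object@selected))
    cat("  first indices:", paste(utils::head(object@selected, n), collapse = ", "),
        if (length(object@selected) > n) "..." else "", "\n")
})

#' Serialize a selection result to JSON
#'
#' @param x a \linkS4class{SelectionResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSelectionJSON <- function(x, path) {
    jsonlite::write_json(
        list(method = x@method, trait = x@trait, k = x@k,
             selected = x@selected, wavelengths = x@wavelengths,
             scores = x@scores, diagnostics = x@diagnostics),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
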