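#' Kennard-Stone train/test split
#'
#' Deterministic max-min-distance sample selection on the Euclidean distance
#' between spectra: the two mutually farthest seeds seed the training set,
#' then each step adds the seed maximizing its minimum distance to the
#' already-chosen set.  Ties break toward the lower sample index.  The
#' remaining seeds form the test set.  Distances are computed on the full
#' (windowed) spectrum, before any band selection.
#'
#' @param ds a \linkS4class{SeedSpectra}.
#' @param nTrain training-set size, 2 <= nTrain < n (73 of 89 in a typical
#'   seed-vigor study).
#' @return a \linkS4class{TrainTestSplit}.
#' @examples
#' ss <- SeedSpectra(matrix(c(0, 1, 10)), wavelengths = 500)
#' kennardStoneSplit(ss, 2)@trainIds  # the two farthest seeds
#' @export
kennardStoneSplit <- function(ds, nTrain) {
    X <- spectraMatrix(ds)
    n <- nrow(X)
    nTrain <- .assertCount(nTrain, "nTrain", min = 2L)
    if (nTrain >= n)
        stop("'nTrain' must be smaller than the number of seeds")
    D <- as.matrix(stats::dist(X))
    if (any(D[upper.tri(D)] == 0))
        warning("duplicate spectra: zero distances present, ties break toward lower index")
    pair <- which(D == max(D), arr.ind = TRUE)
    pair <- cbind(pmin(pair[, 1L], pair[, 2L]), pmax(pair[, 1L], pair[, 2L]))
    pair <- pair[order(pair[, 1L], pair[, 2L]), , drop = FALSE]
    sel <- as.integer(pair[1L, ])
    while (length(sel) < nTrain) {
        rem <- setdiff(seq_len(n), sel)
        minD <- apply(D[rem, sel, drop = FALSE], 1L, min)
        sel <- c(sel, rem[which.max(minD)])
    }
    ids <- sampleIds(ds)
    new("TrainTestSplit", trainIds = ids[sel],
        testIds = ids[setdiff(seq_len(n), sel)], method = "kennard_stone")
}

setMethod("show", "TrainTestSplit", function(object) {
    cat(sprintf("TrainTestSplit[%s]: %d train / %d test\n", object@method,
                length(object@trainIds), length(object@testIds)))
})

.asXy <- function(X) {
    if (is(X, "SeedSpectra"))
        list(X = spectraMatrix(X), wl = wavelengths(X))
    else
        list(X = as.matrix(X), wl = as.numeric(colnames(X) %||% rep(NA_real_, ncol(X))))
}

# Flip each column's sign so its largest-magnitude entry is positive;
# makes eigen/singular vectors reproducible across LAPACK builds.
.fixSigns <- function(V) {
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    V
}

#' Principal component regression
#'
#' Centers spectra and trait by their training means, takes the first
#' \code{q} principal components of the centered spectra, and regresses the
#' centered trait on the component scores by least squares.  Coefficients
#' are mapped back to band space, so prediction is a plain affine map.
#'
#' @param X training spectra, a seeds x bands matrix or
#'   \linkS4class{SeedSpectra}.
#' @param y training trait vector.
#' @param q number of components, 1 <= q <= min(n - 1, p); values above the
#'   numerical rank are truncated with a warning.
#' @param trait optional trait name stored in the model.
#' @return a \linkS4class{PCRModel}.
#' @export
fitPCR <- function(X, y, q, trait = "") {
    xx <- .asXy(X); X <- xx$X
    n <- nrow(X); p <- ncol(X)
    q <- .assertCount(q, "q")
    if (q > min(n - 1L, p))
        stop("invalid config: 'q' exceeds min(n - 1, p)")
    xMean <- colMeans(X)
    Xc <- sweep(X, 2L, xMean)
    yMean <- mean(y)
    yc <- y - yMean
    sv <- svd(Xc)
    r <- sum(sv$d > sv$d[1L] * 1e-10)
    if (q > r) {
        warning(sprintf("q = %d exceeds the numerical rank %d; truncated", q, r))
        q <- r
    }
    V <- .fixSigns(sv$v[, seq_len(q), drop = FALSE])
    S <- Xc %*% V
    gamma <- drop(crossprod(S, yc)) / colSums(S^2)
    new("PCRModel", trait = trait, q = q, xMean = xMean, yMean = yMean,
        bandWavelengths = xx$wl, rotation = V,
        coefficients = drop(V %*% gamma))
}

#' Partial least squares regression (univariate NIPALS)
#'
#' Standard PLS1: weight vectors of unit Euclidean norm, score/loading
#' extraction with deflation of both the spectra and the trait after each
#' latent variable.  Coefficients are mapped back to band space.
#'
#' @inheritParams fitPCR
#' @param q number of latent variables, 1 <= q <= min(n - 1, p).
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y, q, trait = "") {
    xx <- .asXy(X); X <- xx$X
    n <- nrow(X); p <- ncol(X)
    q <- .assertCount(q, "q")
    if (q > min(n - 1L, p))
        stop("invalid config: 'q' exceeds min(n - 1, p)")
    if (stats::sd(y) == 0)
        stop("degenerate target: trait is constant")
    xMean <- colMeans(X)
    yMean <- mean(y)
    Xd <- sweep(X, 2L, xMean)
    yd <- y - yMean
    W <- P <- matrix(0, p, q)
    qvec <- numeric(q)
    used <- 0L
    for (a in seq_len(q)) {
        w <- drop(crossprod(Xd, yd))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) {
            warning(sprintf("PLS stopped after %d component(s): spectra deflated to zero covariance", used))
            break
        }
        w <- w / nw
        t <- drop(Xd %*% w)
        tt <- sum(t^2)
        pl <- drop(crossprod(Xd, t)) / tt
        qa <- sum(yd * t) / tt
        Xd <- Xd - tcrossprod(t, pl)
        yd <- yd - qa * t
        W[, a] <- w; P[, a] <- pl; qvec[a] <- qa
        used <- a
    }
    if (used == 0L) stop("degenerate target: no PLS component could be extracted")
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    qvec <- qvec[seq_len(used)]
    coef <- drop(W %*% solve(crossprod(P, W), qvec))
    new("PLSModel", trait = trait, q = used, xMean = xMean, yMean = yMean,
        bandWavelengths = xx$wl, weights = W, loadings = P,
        coefficients = coef)
}

# Gaussian kernel matrix, k(x, y) = exp(-||x - y||^2 / sigma): sigma divides
# the squared distance directly (no factor of 2).
.kernelMatrix <- function(A, B, sigma, kernel) {
    if (kernel == "linear") return(tcrossprod(A, B))
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / sigma)
}

#' Kernel principal component regression
#'
#' PCR in the feature space of the Gaussian radial basis kernel
#' \code{k(x, y) = exp(-||x - y||^2 / sigma)}: the training kernel matrix is
#' double-centered in feature space, eigendecomposed, and the centered trait
#' is regressed on the top-\code{q} kernel principal scores.  Prediction
#' uses the centered cross-kernel between new and training seeds, so the
#' training spectra are stored in the model.  \code{kernel = "linear"}
#' replaces the RBF with the plain inner product, which reproduces PCR and
#' is used for equivalence checks.
#'
#' @inheritParams fitPCR
#' @param q number of kernel components, 1 <= q <= n - 1.
#' @param sigma kernel bandwidth (divides the squared distance; default 50,
#'   on the reflectance scale).
#' @param kernel "gaussian" (default) or "linear".
#' @return a \linkS4class{KPCRModel}.
#' @export
fitKPCR <- function(X, y, q, sigma = 50, kernel = c("gaussian", "linear"),
                    trait = "") {
    kernel <- match.arg(kernel)
    xx <- .asXy(X); X <- xx$X
    n <- nrow(X)
    q <- .assertCount(q, "q")
    if (q > n - 1L) stop("invalid config: 'q' exceeds n - 1")
    if (sigma <= 0) stop("invalid config: 'sigma' must be positive")
    K <- .kernelMatrix(X, X, sigma, kernel)
    km <- colMeans(K)
    kg <- mean(K)
    Kc <- K - matrix(km, n, n) - matrix(km, n, n, byrow = TRUE) + kg
    eig <- eigen(Kc, symmetric = TRUE)
    r <- sum(eig$values > max(eig$values[1L], 0) * 1e-10)
    if (r == 0L) stop("degenerate kernel: centered kernel matrix has rank 0")
    if (q > r) {
        warning(sprintf("q = %d exceeds the kernel rank %d; truncated", q, r))
        q <- r
    }
    V <- .fixSigns(eig$vectors[, seq_len(q), drop = FALSE])
    lam <- eig$values[seq_len(q)]
    yMean <- mean(y)
    # scores are sqrt(lam) * V; with orthonormal V the regression reduces to
    # beta_j = v_j' (y - yMean) / sqrt(lam_j)
    beta <- drop(crossprod(V, y - yMean)) / sqrt(lam)
    new("KPCRModel", trait = trait, q = q, xMean = colMeans(X), yMean = yMean,
        bandWavelengths = xx$wl, Xtrain = X, sigma = sigma, kernel = kernel,
        eigvec = V, eigval = lam, beta = beta, kColMeans = km, kGrandMean = kg)
}

.checkBands <- function(object, xx) {
    p <- length(object@xMean)
    if (ncol(xx$X) != p)
        stop(sprintf("schema error: model expects %d bands, got %d", p, ncol(xx$X)))
    mwl <- object@bandWavelengths
    if (!anyNA(mwl) && !anyNA(xx$wl) && length(mwl) == length(xx$wl)) {
        off <- which(abs(mwl - xx$wl) > 1e-6)
        if (length(off))
            stop("schema error: wavelength mismatch at ",
                 paste(sprintf("%.1f!=%.1f", mwl[utils::head(off, 5L)],
                               xx$wl[utils::head(off, 5L)]), collapse = ", "))
    }
}

.predNames <- function(X) {
    if (is(X, "SeedSpectra")) sampleIds(X) else rownames(X)
}

#' @describeIn fitPCR predict trait values for new spectra (same bands, same
#'   order as at training time).
#' @param object a fitted model.
#' @param newdata seeds x bands matrix or \linkS4class{SeedSpectra}.
#' @param ... unused.
#' @export
setMethod("predict", "PCRModel", function(object, newdata, ...) {
    xx <- .asXy(newdata)
    .checkBands(object, xx)
    yhat <- drop(sweep(xx$X, 2L, object@xMean) %*% object@coefficients) +
        object@yMean
    stats::setNames(yhat, .predNames(newdata))
})

#' @describeIn fitPLS predict trait values for new spectra.
#' @param object a fitted model.
#' @param newdata seeds x bands matrix or \linkS4class{SeedSpectra}.
#' @param ... unused.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    xx <- .asXy(newdata)
    .checkBands(object, xx)
    yhat <- drop(sweep(xx$X, 2L, object@xMean) %*% object@coefficients) +
        object@yMean
    stats::setNames(yhat, .predNames(newdata))
})

#' @describeIn fitKPCR predict trait values for new spectra via the centered
#'   cross-kernel against the stored training spectra.
#' @param object a fitted model.
#' @param newdata seeds x bands matrix or \linkS4class{SeedSpectra}.
#' @param ... unused.
#' @export
setMethod("predict", "KPCRModel", function(object, newdata, ...) {
    xx <- .asXy(newdata)
    .checkBands(object, xx)
    Knew <- .kernelMatrix(xx$X, object@Xtrain, object@sigma, object@kernel)
    Kc <- Knew - matrix(rowMeans(Knew), nrow(Knew), ncol(Knew)) -
        matrix(object@kColMeans, nrow(Knew), ncol(Knew), byrow = TRUE) +
        object@kGrandMean
    S <- Kc %*% sweep(object@eigvec, 2L, sqrt(object@eigval), "/")
    yhat <- drop(S %*% object@beta) + object@yMean
    stats::setNames(yhat, .predNames(newdata))
})

setMethod("show", "SpectralModel", function(object) {
    cat(sprintf("%s%s: q = %d, %d bands\n", class(object),
                if (nzchar(object@trait)) paste0(" (", object@trait, ")") else "",
                object@q, length(object@xMean)))
})

# ---- component-count selection by leave-one-out cross-validation ----------
# All three models have orthogonal score structures, so one fit per fold
# yields held-out predictions for every component count at once.

.pcrPathPredict <- function(Xtr, ytr, Xte, qMax) {
    xm <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2L, xm)
    sv <- svd(Xc)
    r <- sum(sv$d > sv$d[1L] * 1e-10)
    q <- min(qMax, r)
    V <- sv$v[, seq_len(q), drop = FALSE]
    S <- Xc %*% V
    gamma <- drop(crossprod(S, ytr - mean(ytr))) / colSums(S^2)
    Ste <- sweep(Xte, 2L, xm) %*% V
    contrib <- sweep(Ste, 2L, gamma, "*")
    preds <- t(apply(contrib, 1L, cumsum))
    if (q == 1L) preds <- matrix(preds, ncol = 1L)
    if (qMax > q)
        preds <- cbind(preds, matrix(preds[, q], nrow(Xte), qMax - q))
    mean(ytr) + preds
}

.plsPathPredict <- function(Xtr, ytr, Xte, qMax) {
    xm <- colMeans(Xtr)
    Xd <- sweep(Xtr, 2L, xm)
    yd <- ytr - mean(ytr)
    Xr <- sweep(Xte, 2L, xm)
    preds <- matrix(mean(ytr), nrow(Xte), qMax)
    acc <- rep(mean(ytr), nrow(Xte))
    for (a in seq_len(qMax)) {
        w <- drop(crossprod(Xd, yd))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) { preds[, a:qMax] <- acc; break }
        w <- w / nw
        t <- drop(Xd %*% w)
        tt <- sum(t^2)
        pl <- drop(crossprod(Xd, t)) / tt
        qa <- sum(yd * t) / tt
        tte <- drop(Xr %*% w)
        acc <- acc + qa * tte
        preds[, a] <- acc
        Xd <- Xd - tcrossprod(t, pl)
        yd <- yd - qa * t
        Xr <- Xr - tcrossprod(tte, pl)
    }
    preds
}

.kpcrPathPredict <- function(Xtr, ytr, Xte, qMax, sigma, kernel) {
    n <- nrow(Xtr)
    K <- .kernelMatrix(Xtr, Xtr, sigma, kernel)
    km <- colMeans(K); kg <- mean(K)
    Kc <- K - matrix(km, n, n) - matrix(km, n, n, byrow = TRUE) + kg
    eig <- eigen(Kc, symmetric = TRUE)
    r <- sum(eig$values > max(eig$values[1L], 0) * 1e-10)
    q <- min(qMax, r)
    V <- eig$vectors[, seq_len(q), drop = FALSE]
    lam <- eig$values[seq_len(q)]
    beta <- drop(crossprod(V, ytr - mean(ytr))) / sqrt(lam)
    Knew <- .kernelMatrix(Xte, Xtr, sigma, kernel)
    KcN <- Knew - matrix(rowMeans(Knew), nrow(Knew), n) -
        matrix(km, nrow(Knew), n, byrow = TRUE) + kg
    Ste <- KcN %*% sweep(V, 2L, sqrt(lam), "/")
    contrib <- sweep(Ste, 2L, beta, "*")
    preds <- t(apply(contrib, 1L, cumsum))
    if (q == 1L) preds <- matrix(preds, ncol = 1L)
    if (qMax > q)
        preds <- cbind(preds, matrix(preds[, q], nrow(Xte), qMax - q))
    mean(ytr) + preds
}

#' Choose the number of components by leave-one-out cross-validation
#'
#' Scans q = 1..qMax and returns the q minimizing the LOO RMSE on the
#' training set (ties toward the smaller q).  LOO is affordable at the
#' sample sizes of single-tray seed studies (n of order 100).
#'
#' @param kind "pcr", "kpcr" or "pls".
#' @param X training spectra (matrix or \linkS4class{SeedSpectra}).
#' @param y training trait vector.
#' @param qMax largest component count scanned (default 20, capped at the
#'   admissible maximum for the model kind).
#' @param sigma,kernel KPCR kernel parameters.
#' @return list with \code{q} (chosen) and \code{cvRmse} (per candidate q).
#' @export
chooseComponents <- function(kind = c("pcr", "kpcr", "pls"), X, y, qMax = 20L,
                             sigma = 50, kernel = "gaussian") {
    kind <- match.arg(kind)
    X <- .asXy(X)$X
    n <- nrow(X)
    adm <- if (kind == "kpcr") n - 2L else min(n - 2L, ncol(X))
    qMax <- min(.assertCount(qMax, "qMax"), max(adm, 1L))
    se <- matrix(NA_real_, n, qMax)
    for (i in seq_len(n)) {
        preds <- switch(kind,
            pcr = .pcrPathPredict(X[-i, , drop = FALSE], y[-i],
                                  X[i, , drop = FALSE], qMax),
            pls = .plsPathPredict(X[-i, , drop = FALSE], y[-i],
                                  X[i, , drop = FALSE], qMax),
            kpcr = .kpcrPathPredict(X[-i, , drop = FALSE], y[-i],
                                    X[i, , drop = FALSE], qMax, sigma, kernel))
        se[i, ] <- (y[i] - preds)^2
    }
    cv <- sqrt(colMeans(se))
    list(q = which.min(cv), cvRmse = cv)
}
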