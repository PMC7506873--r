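oneBand <- function(v) SeedSpectra(matrix(v, ncol = 1), wavelengths = 500)

test_that("Kennard-Stone picks max-min-distance samples with the stated ties", {
    expect_equal(kennardStoneSplit(oneBand(c(0, 1, 10)), 2)@trainIds,
                 c("seed001", "seed003"))
    sp <- kennardStoneSplit(oneBand(0:9), 3)
    expect_equal(sp@trainIds, c("seed001", "seed010", "seed005"))
    expect_equal(sp@testIds, sprintf("seed%03d", c(2:4, 6:9)))
    expect_error(kennardStoneSplit(oneBand(0:9), 10), "smaller")
    expect_error(kennardStoneSplit(oneBand(0:9), 1), "invalid config")
})

test_that("Kennard-Stone partitions deterministically and handles duplicates", {
    ds <- tinySpectra(n = 25, p = 6, seed = 12)
    s1 <- kennardStoneSplit(ds, 18)
    s2 <- kennardStoneSplit(ds, 18)
    expect_identical(s1@trainIds, s2@trainIds)
    expect_length(intersect(s1@trainIds, s1@testIds), 0)
    expect_setequal(c(s1@trainIds, s1@testIds), sampleIds(ds))
    X <- spectraMatrix(ds)
    X[2, ] <- X[1, ]
    dup <- SeedSpectra(X, wavelengths = wavelengths(ds))
    expect_warning(kennardStoneSplit(dup, 5), "duplicate")
})

test_that("PCR and PLS at full rank reproduce least squares on training data", {
    set.seed(31)
    n <- 20; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.3)
    ols <- unname(fitted(lm(y ~ X)))
    pcr <- fitPCR(X, y, q = p)
    pls <- fitPLS(X, y, q = p)
    expect_equal(unname(predict(pcr, X)), ols, tolerance = 1e-8)
    expect_equal(unname(predict(pls, X)), ols, tolerance = 1e-8)
})

test_that("noiseless linear targets are fit exactly at full rank", {
    set.seed(32)
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- drop(X %*% c(1, -2, 0.5, 3)) + 7
    expect_lt(max(abs(predict(fitPCR(X, y, 4), X) - y)), 1e-8)
    expect_lt(max(abs(predict(fitPLS(X, y, 4), X) - y)), 1e-8)
})

test_that("centering contract: shifting y shifts all predictions equally", {
    set.seed(33)
    X <- matrix(rnorm(18 * 5), 18, 5)
    y <- rnorm(18)
    Xnew <- matrix(rnorm(4 * 5), 4, 5)
    for (fitter in list(function(yy) fitPCR(X, yy, 3),
                        function(yy) fitPLS(X, yy, 3),
                        function(yy) fitKPCR(X, yy, 3, sigma = 50))) {
        p0 <- predict(fitter(y), Xnew)
        p5 <- predict(fitter(y + 5), Xnew)
        expect_equal(unname(p5 - p0), rep(5, 4), tolerance = 1e-8)
    }
})

test_that("PLS specialisations: one predictor equals the simple line, unit weights", {
    set.seed(34)
    x <- rnorm(12)
    y <- 2 * x + rnorm(12, 0, 0.1)
    fit <- fitPLS(matrix(x), y, 1)
    line <- lm(y ~ x)
    expect_equal(unname(predict(fit, matrix(x))), unname(fitted(line)),
                 tolerance = 1e-10)
    multi <- fitPLS(matrix(rnorm(60), 15, 4), rnorm(15), 3)
    expect_equal(unname(colSums(multi@weights^2)), rep(1, 3),
                 tolerance = 1e-12)
    expect_error(fitPLS(matrix(rnorm(20), 5), rep(1, 5), 2),
                 "degenerate target")
})

test_that("the Gaussian kernel matches its formula", {
    km <- vigorspec:::.kernelMatrix
    x <- matrix(c(1, 2, 3), 1)
    expect_equal(km(x, x, 50, "gaussian")[1, 1], 1)
    y <- x + sqrt(50 / 3)  # squared distance exactly sigma
    expect_equal(km(x, y, 50, "gaussian")[1, 1], exp(-1), tolerance = 1e-12)
    skip_if_not_installed("kernlab")
    set.seed(35)
    A <- matrix(rnorm(40), 8, 5)
    ours <- km(A, A, 50, "gaussian")
    ref <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / 50), A)
    expect_equal(ours, unclass(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("KPCR with the linear kernel reproduces full-rank PCR", {
    set.seed(36)
    n <- 16; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.2)
    Xnew <- matrix(rnorm(5 * p), 5, p)
    kp <- fitKPCR(X, y, q = p, kernel = "linear")
    pc <- fitPCR(X, y, q = p)
    expect_equal(unname(predict(kp, X)), unname(predict(pc, X)),
                 tolerance = 1e-6)
    expect_equal(unname(predict(kp, Xnew)), unname(predict(pc, Xnew)),
                 tolerance = 1e-6)
})

test_that("model guards: component bounds, sigma, constant targets", {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    expect_error(fitPCR(X, y, 5), "invalid config")
    expect_error(fitPLS(X, y, 4), "invalid config")
    expect_error(fitKPCR(X, y, 10), "invalid config")
    expect_error(fitKPCR(X, y, 2, sigma = 0), "invalid config")
    # constant y: PCR predicts the mean everywhere
    cst <- fitPCR(X, rep(4, 10), 2)
    expect_equal(unname(predict(cst, X)), rep(4, 10), tolerance = 1e-12)
})

test_that("prediction checks band compatibility and names samples", {
    ds <- tinySpectra(n = 12, p = 5, seed = 37)
    y <- rnorm(12)
    fit <- fitPCR(ds, y, 2)
    pr <- predict(fit, ds)
    expect_named(pr, sampleIds(ds))
    wrong <- tinySpectra(n = 3, p = 4, seed = 1)
    expect_error(predict(fit, wrong), "schema error")
    shifted <- SeedSpectra(spectraMatrix(ds), wavelengths = wavelengths(ds) + 3)
    expect_error(predict(fit, shifted), "schema error")
})

test_that("training-sample order does not change predictions", {
    set.seed(38)
    n <- 22; p <- 7
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.4)
    Xnew <- matrix(rnorm(6 * p), 6, p)
    perm <- sample(n)
    for (pair in list(
        list(function(a, b) fitPCR(a, b, 4), NULL),
        list(function(a, b) fitPLS(a, b, 4), NULL),
        list(function(a, b) fitKPCR(a, b, 4, sigma = 50), NULL))) {
        f1 <- pair[[1]](X, y)
        f2 <- pair[[1]](X[perm, ], y[perm])
        expect_equal(unname(predict(f1, Xnew)), unname(predict(f2, Xnew)),
                     tolerance = 1e-8)
    }
})

test_that("per-component prediction paths agree with the fitted models", {
    set.seed(39)
    Xtr <- matrix(rnorm(25 * 8), 25, 8)
    ytr <- drop(Xtr %*% rnorm(8)) + rnorm(25, 0, 0.3)
    Xte <- matrix(rnorm(5 * 8), 5, 8)
    for (q in c(1L, 3L, 6L)) {
        expect_equal(vigorspec:::.pcrPathPredict(Xtr, ytr, Xte, q)[, q],
                     unname(predict(fitPCR(Xtr, ytr, q), Xte)),
                     tolerance = 1e-10)
        expect_equal(vigorspec:::.plsPathPredict(Xtr, ytr, Xte, q)[, q],
                     unname(predict(fitPLS(Xtr, ytr, q), Xte)),
                     tolerance = 1e-10)
        expect_equal(vigorspec:::.kpcrPathPredict(Xtr, ytr, Xte, q, 50,
                                                  "gaussian")[, q],
                     unname(predict(fitKPCR(Xtr, ytr, q, sigma = 50), Xte)),
                     tolerance = 1e-10)
    }
})

test_that("LOO component selection returns a sensible q", {
    set.seed(40)
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- drop(X[, 1:2] %*% c(2, -1)) + rnorm(30, 0, 0.2)
    for (kind in c("pcr", "kpcr", "pls")) {
        ch <- chooseComponents(kind, X, y, qMax = 8)
        expect_true(ch$q >= 1 && ch$q <= 8)
        expect_length(ch$cvRmse, 8)
        expect_equal(ch$q, which.min(ch$cvRmse))
    }
})
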