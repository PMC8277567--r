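actPath <- system.file("extdata", "tmdapdc_activities.csv",
                       package = "aldipose")
kinPath <- system.file("extdata", "tmdapdc_kinetics.csv",
                       package = "aldipose")

test_that("the packaged activity table returns the printed cells", {
    act <- loadActivityTable(actPath)
    row <- function(v, s) act[act$variant == v & act$substrate == s, ]

    wt <- row("WT", "meso-DAP")
    expect_equal(wt$activity, 675)
    expect_equal(wt$stderr, 70)
    expect_true(wt$detectable)

    et <- row("E315T", "2-APA")
    expect_equal(et$activity, 482)
    expect_equal(et$stderr, 36)

    na <- row("WT", "D-glutamate")
    expect_false(na$detectable)
    expect_true(is.na(na$activity))
    expect_equal(attr(act, "detectionLimit"), 1)

    # panel shape: 8 variants x 7 substrates
    expect_identical(nrow(act), 56L)
    expect_identical(sum(act$detectable), 29L)
})

test_that("malformed activity cells fail with row/column coordinates", {
    p <- tempfile(fileext = ".csv")
    writeLines(c("variant,DAP", "WT,12 (", "E315T,5 (1)"), p)
    expect_error(loadActivityTable(p), "row 1, column 'DAP'")
    unlink(p)
})

test_that("the packaged kinetics table returns the printed parameters", {
    kin <- loadKinetics(kinPath)
    wt <- kin[kin$variant == "Wild-type" & kin$substrate == "DAP", ]
    expect_equal(wt$KM, 0.27)
    expect_equal(wt$KM_err, 0.06)
    expect_equal(wt$kcat, 0.075)
    expect_equal(wt$kcat_err, 0.004)
    et <- kin[kin$variant == "E315T" & kin$substrate == "APA", ]
    expect_equal(et$KM, 0.32)
    expect_equal(et$kcat, 0.2)

    p <- tempfile(fileext = ".csv")
    writeLines(c("variant,substrate,KM,KM_err,kcat,kcat_err",
                 "X,S,0.3,0.1,0,0.001"), p)
    expect_error(loadKinetics(p), "kcat must be positive")
    unlink(p)
})

test_that("turnover fold change reproduces the variant-over-wild-type gain", {
    kin <- loadKinetics(kinPath)
    fold <- foldRatio(kin, c("E315T", "APA"), c("Wild-type", "DAP"))
    expect_equal(fold, 0.2 / 0.075)
    expect_gte(fold, 2.6)
    expect_equal(foldRatio(kin, c("E315T", "APA"), c("E315T", "APA")), 1)
    expect_error(foldRatio(kin, c("E315X", "APA"), c("Wild-type", "DAP")),
                 "no kinetics row")
})

test_that("docking-score aggregation takes the numerically lowest as best", {
    res <- meanTopScores(list(v = -(1:10)), topK = 3L, expectedN = 10L)
    expect_equal(res$mean_top, -9)
    expect_equal(res$mean_all, -5.5)

    const <- meanTopScores(list(v = rep(2.5, 20)), topK = 5L,
                           expectedN = 20L)
    expect_equal(const$mean_top, 2.5)
    expect_equal(const$mean_all, 2.5)

    withr::with_seed(53, {
        for (k in 1:20) {
            s <- stats::rnorm(500)
            res <- meanTopScores(list(m = s), topK = 50L)
            expect_identical(res$mean_top, mean(sort(s)[1:50]))
            expect_lte(res$mean_top, res$mean_all)
        }
    })

    expect_error(meanTopScores(list(tiny = 1:3), topK = 50L),
                 "variant tiny")
})

test_that("pearsonR matches the definitional formula and its invariances", {
    expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6))@r, 1)
    expect_equal(pearsonR(c(1, 2, 3), c(6, 4, 2))@r, -1)
    # hand computation: centered cross-product 4, sd product 5
    expect_equal(pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))@r, 0.8)

    expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
    expect_error(pearsonR(1:2, 2:3), "insufficient data")
    expect_error(pearsonR(1:4, 1:3), "equal length")

    withr::with_seed(59, {
        for (k in 1:25) {
            x <- stats::rnorm(10)
            y <- stats::rnorm(10)
            r <- pearsonR(x, y)@r
            defn <- sum((x - mean(x)) * (y - mean(y))) /
                sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
            expect_equal(r, defn, tolerance = 1e-12)
            expect_equal(pearsonR(y, x)@r, r)
            a <- stats::runif(1, 0.1, 5)
            b <- stats::rnorm(1)
            expect_equal(pearsonR(a * x + b, y)@r, r, tolerance = 1e-12)
            expect_equal(pearsonR(-a * x, y)@r, -r, tolerance = 1e-12)
        }
    })
})

test_that("pose-activity correlation is exact in the noise-free limit", {
    # true fractions are exact multiples of 1/nFrames, so the measured
    # counts are exactly linear in activity
    spec <- panelSpec(nVariants = 10L, nFrames = 40L, noiseSd = 0,
                      seed = 61L)
    panel <- simulatePanel(spec)
    rm <- syntheticRoleMap()
    crit <- reactiveCriteria("DAP")
    summaries <- lapply(panel$trajectories, function(tr)
        summarizeTrajectory(tr, rm, crit))
    res <- correlateWithActivity(summaries, panel$activity, "synthetic")
    expect_equal(res@r, 1, tolerance = 1e-12)

    # oracle equality with the generator's own truth table
    oracle <- pearsonR(panel$truth$n_reactive_truth, panel$truth$activity)
    resCount <- correlateWithActivity(summaries, panel$activity, "synthetic",
                                      measure = "count")
    expect_equal(resCount@r, oracle@r, tolerance = 1e-12)
})

test_that("degenerate panels are rejected", {
    spec <- panelSpec(nVariants = 5L, nFrames = 20L,
                      trueFractions = rep(0.5, 5), noiseSd = 0, seed = 67L)
    panel <- simulatePanel(spec)
    rm <- syntheticRoleMap()
    summaries <- lapply(panel$trajectories, function(tr)
        summarizeTrajectory(tr, rm, reactiveCriteria("DAP")))
    expect_error(correlateWithActivity(summaries, panel$activity,
                                       "synthetic"), "zero variance")

    expect_error(correlateWithActivity(summaries[1:2],
                                       panel$activity[1:2, ], "synthetic"),
                 "insufficient data")
})

test_that("non-detectable activities are excluded or substituted on request", {
    act <- data.frame(variant = c("A", "B", "C", "D"),
                      substrate = "S",
                      activity = c(10, 20, NA, 40),
                      stderr = NA_real_,
                      detectable = c(TRUE, TRUE, FALSE, TRUE))
    mkSummary <- function(label, n) new("PoseSummary", variantLabel = label,
        nFrames = 50L, nReactive = as.integer(n), fraction = n / 50,
        perCriterionPass = stats::setNames(rep(50L, 4),
                                           c("d1", "theta1", "chi1", "d2")))
    summaries <- Map(mkSummary, c("A", "B", "C", "D"), c(5, 10, 15, 20))
    excl <- correlateWithActivity(summaries, act, "S")
    expect_identical(excl@n, 3L)
    expect_false("C" %in% excl@pairs$label)
    zero <- correlateWithActivity(summaries, act, "S", nondetect = "zero")
    expect_identical(zero@n, 4L)
    expect_equal(zero@pairs$y[zero@pairs$label == "C"], 0)
    lim <- correlateWithActivity(summaries, act, "S", nondetect = "limit")
    expect_equal(lim@pairs$y[lim@pairs$label == "C"], 1)
})

test_that("variant ranking orders by count, fraction, then label", {
    mk <- function(label, nf, nr) new("PoseSummary", variantLabel = label,
        nFrames = as.integer(nf), nReactive = as.integer(nr),
        fraction = nr / nf,
        perCriterionPass = stats::setNames(rep(as.integer(nf), 4),
                                           c("d1", "theta1", "chi1", "d2")))
    rk <- rankVariants(list(mk("a", 100, 12), mk("b", 100, 40),
                            mk("c", 100, 7)))
    expect_identical(rk$variant_label, c("b", "a", "c"))

    # tie on counts broken by fraction (shorter trajectory, same count)
    rk2 <- rankVariants(list(mk("long", 200, 30), mk("short", 100, 30)))
    expect_identical(rk2$variant_label, c("short", "long"))

    single <- rankVariants(list(mk("only", 10, 1)))
    expect_identical(nrow(single), 1L)
    expect_error(rankVariants(list()), "at least one")
})

test_that("zero-slope panels carry no structural signal", {
    spec <- panelSpec(nVariants = 12L, nFrames = 20L, intercept = 300,
                      slope = 0, noiseSd = 50, seed = 71L)
    panel <- simulatePanel(spec)
    rm <- syntheticRoleMap()
    summaries <- lapply(panel$trajectories, function(tr)
        summarizeTrajectory(tr, rm, reactiveCriteria("DAP")))
    res <- correlateWithActivity(summaries, panel$activity, "synthetic")
    oracle <- pearsonR(panel$truth$n_reactive_truth, panel$truth$activity)
    expect_equal(res@r, oracle@r, tolerance = 1e-12)
    expect_lt(abs(res@r), 0.9)
})
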