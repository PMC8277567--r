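# Experimental activity / kinetics tables, docking-score aggregation and
# the prediction-vs-activity correlation. Printed values are consumed as
# data: no Michaelis-Menten refitting, no confidence intervals on r.

.DETECTION_LIMIT <- 1  # mU/mg; below this, activity is "not detectable"

.parseActivityCell <- function(cell, where) {
    cell <- trimws(cell)
    if (tolower(cell) %in% c("n.a.", "na", "n.a"))
        return(list(activity = NA_real_, stderr = NA_real_,
                    detectable = FALSE))
    m <- regmatches(cell,
        regexec("^([0-9]*\\.?[0-9]+)\\s*\\(([0-9]*\\.?[0-9]+)\\)$", cell))[[1L]]
    if (length(m) == 3L)
        return(list(activity = as.numeric(m[2L]),
                    stderr = as.numeric(m[3L]), detectable = TRUE))
    v <- suppressWarnings(as.numeric(cell))
    if (!is.na(v))
        return(list(activity = v, stderr = NA_real_, detectable = TRUE))
    stop("malformed activity cell at ", where, ": '", cell, "'",
         call. = FALSE)
}

#' Load a specific-activity table
#'
#' Reads a CSV with a `variant` column and one column per substrate;
#' cells are `"value (err)"` (mU/mg, standard deviation in parentheses)
#' or `"n.a."` for activity below the 1 mU/mg detection limit. The
#' packaged fixture `tmdapdc_activities.csv` transcribes the printed
#' variant-panel activities.
#'
#' @param path path to the CSV file.
#' @return long data.frame with columns `variant`, `substrate`,
#'   `activity`, `stderr`, `detectable`; the detection limit is recorded
#'   in `attr(, "detectionLimit")`.
#' @examples
#' act <- loadActivityTable(
#'   system.file("extdata", "tmdapdc_activities.csv", package = "aldipose"))
#' subset(act, variant == "WT" & substrate == "meso-DAP")
#' @export
loadActivityTable <- function(path) {
    raw <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
    if (!"variant" %in% names(raw))
        stop("activity table needs a 'variant' column", call. = FALSE)
    substrates <- setdiff(names(raw), "variant")
    rows <- list()
    for (i in seq_len(nrow(raw))) {
        for (s in substrates) {
            p <- .parseActivityCell(raw[[s]][i],
                                    paste0("row ", i, ", column '", s, "'"))
            rows[[length(rows) + 1L]] <- data.frame(
                variant = raw$variant[i], substrate = s,
                activity = p$activity, stderr = p$stderr,
                detectable = p$detectable, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (any(out$detectable & out$activity < 0))
        stop("negative activity in table", call. = FALSE)
    attr(out, "detectionLimit") <- .DETECTION_LIMIT
    out
}

#' Load a kinetic-parameter table
#'
#' Reads a CSV with columns `variant`, `substrate`, `KM`, `KM_err`,
#' `kcat`, `kcat_err` (mM and 1/s). Non-positive KM or kcat is a
#' validation error. The packaged fixture `tmdapdc_kinetics.csv`
#' transcribes the printed kinetic parameters.
#'
#' @param path path to the CSV file.
#' @return data.frame with the columns above.
#' @export
loadKinetics <- function(path) {
    k <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("variant", "substrate", "KM", "kcat")
    missing <- setdiff(need, names(k))
    if (length(missing))
        stop("kinetics table lacks column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (any(!is.finite(k$KM) | k$KM <= 0))
        stop("KM must be positive", call. = FALSE)
    if (any(!is.finite(k$kcat) | k$kcat <= 0))
        stop("kcat must be positive", call. = FALSE)
    k
}

.kinLookup <- function(kin, key) {
    i <- which(kin$variant == key[1L] & kin$substrate == key[2L])
    if (!length(i))
        stop("no kinetics row for (", key[1L], ", ", key[2L], ")",
             call. = FALSE)
    i[1L]
}

#' Fold change between two turnover numbers
#'
#' Ratio kcat(numerator) / kcat(denominator) for two (variant, substrate)
#' keys, e.g. the engineered variant on the non-native substrate over the
#' wild-type on the native one.
#'
#' @param kin table from [loadKinetics()].
#' @param numerator,denominator character(2): `c(variant, substrate)`.
#' @return dimensionless fold change.
#' @export
foldRatio <- function(kin, numerator, denominator) {
    kin$kcat[.kinLookup(kin, numerator)] /
        kin$kcat[.kinLookup(kin, denominator)]
}

#' Aggregate docking scores per variant
#'
#' Interface-energy-style scores, lower = better. Returns for each
#' variant the mean over all scores and the mean over the `topK` best
#' (numerically lowest) scores, the protocol used to pick starting
#' structures (top 50 of 500 output models per variant).
#'
#' @param scores named list: variant -> numeric vector of scores.
#' @param topK number of best scores to average.
#' @param expectedN expected scores per variant; a mismatch only warns.
#' @return data.frame with columns `variant`, `n`, `mean_all`,
#'   `mean_top`.
#' @export
meanTopScores <- function(scores, topK = 50L, expectedN = 500L) {
    stopifnot(is.list(scores), !is.null(names(scores)))
    out <- lapply(names(scores), function(v) {
        s <- scores[[v]]
        if (length(s) < topK)
            stop("variant ", v, " has ", length(s),
                 " scores, fewer than topK = ", topK, call. = FALSE)
        if (!is.null(expectedN) && length(s) != expectedN)
            warning("variant ", v, " has ", length(s),
                    " scores, expected ", expectedN, call. = FALSE)
        data.frame(variant = v, n = length(s), mean_all = mean(s),
                   mean_top = mean(sort(s)[seq_len(topK)]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Sample Pearson correlation
#'
#' Thin, validated wrapper around the product-moment correlation: equal
#' lengths, at least three pairs, and non-degenerate variance on both
#' sides are required.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param labels optional pair labels.
#' @return a [CorrelationResult-class].
#' @export
pearsonR <- function(x, y, labels = NULL) {
    if (length(x) != length(y))
        stop("x and y must have equal length", call. = FALSE)
    n <- length(x)
    if (n < 3L)
        stop("insufficient data: need at least 3 pairs, got ", n,
             call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: zero variance", call. = FALSE)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    new("CorrelationResult", r = stats::cor(x, y), n = as.integer(n),
        pairs = data.frame(label = labels, x = x, y = y,
                           stringsAsFactors = FALSE))
}

setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf("Pearson correlation: r = %.3f over n = %d pairs\n",
                object@r, object@n))
})

#' Correlate reactive-pose statistics with measured activity
#'
#' Pairs each variant's reactive-pose count (or fraction) with its
#' specific activity for one substrate and computes the Pearson
#' correlation. Variants must overlap in at least three labels.
#' Non-detectable activities are excluded by default; alternatively they
#' can stand in as 0 or as the detection limit.
#'
#' @param summaries list of [PoseSummary-class] objects (variant labels
#'   must match the activity table's `variant` column).
#' @param act activity table from [loadActivityTable()] (or the
#'   generator's equivalent).
#' @param substrate substrate name to select from `act`.
#' @param measure `"count"` (default; trajectories share length under
#'   the study protocol) or `"fraction"`.
#' @param nondetect handling of non-detectable activities: `"exclude"`,
#'   `"zero"` or `"limit"`.
#' @return a [CorrelationResult-class].
#' @export
correlateWithActivity <- function(summaries, act, substrate,
                                  measure = c("count", "fraction"),
                                  nondetect = c("exclude", "zero",
                                                "limit")) {
    measure <- match.arg(measure)
    nondetect <- match.arg(nondetect)
    if (is(summaries, "PoseSummary")) summaries <- list(summaries)
    st <- summaryTable(summaries)
    a <- act[act$substrate == substrate, , drop = FALSE]
    if (nondetect == "exclude") {
        a <- a[a$detectable, , drop = FALSE]
    } else {
        fill <- if (nondetect == "zero") 0 else .DETECTION_LIMIT
        a$activity[!a$detectable] <- fill
    }
    merged <- merge(st, a, by.x = "variant_label", by.y = "variant")
    if (nrow(merged) < 3L)
        stop("insufficient data: only ", nrow(merged),
             " variants overlap between summaries and activities",
             call. = FALSE)
    x <- if (measure == "count") merged$n_reactive else merged$fraction
    pearsonR(x, merged$activity, labels = merged$variant_label)
}

#' Rank variants by reactive-pose statistics
#'
#' Descending by reactive count, ties by fraction, then lexicographic
#' variant label.
#'
#' @param summaries list of [PoseSummary-class] objects.
#' @return data.frame in rank order: `variant_label`, `n_reactive`,
#'   `fraction`.
#' @export
rankVariants <- function(summaries) {
    if (is(summaries, "PoseSummary")) summaries <- list(summaries)
    if (!length(summaries))
        stop("need at least one summary", call. = FALSE)
    st <- summaryTable(summaries)
    ord <- order(-st$n_reactive, -st$fraction, st$variant_label)
    st[ord, c("variant_label", "n_reactive", "fraction"), drop = FALSE] |>
        (\(d) {rownames(d) <- NULL; d})()
}
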