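# Signal-versus-distance statistics: the decile moving median, threshold
# group comparisons, upstream torsion sums, the SD outlier filter, and
# switch-point localization.

#' Decile window size for the moving median
#'
#' One tenth of the promoter set, forced odd (by subtracting 1 when even) so
#' a centered window splits into the focal promoter plus two equal
#' half-windows. For the 16,972-promoter catalogue this gives 1,697
#' (848 promoters with greater and 848 with lesser inter-promoter distance).
#'
#' @param nPromoters number of promoters (>= 10).
#' @return Odd integer window size.
#' @examples
#' decileWindow(16972) # 1697
#' @export
decileWindow <- function(nPromoters) {
    if (nPromoters < 10) stop("need at least 10 promoters for decile windows")
    w <- nPromoters %/% 10L
    if (w %% 2L == 0L) w <- w - 1L
    as.integer(w)
}

#' Moving median (or mean) of signal along the distance ranking
#'
#' Promoters are sorted by inter-promoter distance from greatest to least
#' (ties broken by promoter ID); for every position with a full centered
#' window the curve gets one point: the window median of distances paired
#' with the window median (or mean) of signal. Positions without a full
#' window are omitted, preserving the equal half-window symmetry.
#'
#' @param signal named per-promoter signal (e.g. [regionSum()] output).
#' @param distances named per-promoter nearest-upstream distances
#'   ([annotateSpacing()]); promoters with `NA` distance (no upstream
#'   neighbor) are excluded.
#' @param window odd window size, typically [decileWindow()].
#' @param statistic `"median"` (accessibility convention) or `"mean"`
#'   (torsion convention).
#' @return data.frame with `median_distance`, `median_signal`, `n_window`,
#'   ordered by decreasing distance; attributes `window` and `statistic`.
#' @export
movingMedianCurve <- function(signal, distances, window,
                              statistic = c("median", "mean")) {
    statistic <- match.arg(statistic)
    distances <- distances[!is.na(distances)]
    common <- intersect(names(signal), names(distances))
    if (!length(common)) stop("signal and distance names do not overlap")
    s <- signal[common]
    d <- distances[common]
    n <- length(common)
    if (window > n) stop("window (", window, ") exceeds number of promoters (",
                         n, ")")
    if (window %% 2L == 0L) stop("window must be odd")
    ord <- order(-d, common)
    s <- as.numeric(s[ord])
    d <- as.numeric(d[ord])
    roll <- function(x) {
        if (statistic == "median") {
            if (window == 1L) x
            else stats::runmed(x, window, endrule = "keep")[
                seq((window + 1L) / 2L, n - (window - 1L) / 2L)]
        } else {
            cs <- cumsum(c(0, x))
            (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
        }
    }
    md <- if (statistic == "median") roll(d) else {
        cs <- cumsum(c(0, d))
        (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
    }
    ms <- roll(s)
    out <- data.frame(median_distance = md, median_signal = ms,
                      n_window = window)
    attr(out, "window") <- window
    attr(out, "statistic") <- statistic
    out
}

#' Group medians above and below a distance threshold
#'
#' Splits promoters into close (`distance < threshold`) and far
#' (`distance >= threshold`) strata and reports per-stratum medians. When a
#' second condition's signal is supplied, a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test compares the two conditions within each stratum — the
#' rank-based test matching the median framing of the comparison.
#'
#' @param signal named per-promoter signal for the (treated) condition.
#' @param distances named nearest-upstream distances; `NA` excluded.
#' @param threshold bp threshold (study convention 2,000).
#' @param control optional named per-promoter signal for the control
#'   condition.
#' @return data.frame with one row per stratum: `stratum`, `n`, `median`,
#'   and, when `control` is given, `median_control`, `W`, `p_value`.
#' @export
thresholdGroupMedians <- function(signal, distances, threshold = 2000,
                                  control = NULL) {
    distances <- distances[!is.na(distances)]
    common <- intersect(names(signal), names(distances))
    d <- distances[common]
    close <- common[d < threshold]
    far <- common[d >= threshold]
    if (!length(close)) stop("empty stratum: no promoters closer than ",
                             threshold, " bp")
    if (!length(far)) stop("empty stratum: no promoters at or beyond ",
                           threshold, " bp")
    strata <- list(close = close, far = far)
    rows <- lapply(names(strata), function(nm) {
        ids <- strata[[nm]]
        row <- data.frame(stratum = nm, n = length(ids),
                          median = stats::median(signal[ids]))
        if (!is.null(control)) {
            wt <- stats::wilcox.test(signal[ids], control[ids],
                                     alternative = "two.sided", exact = FALSE)
            row$median_control <- stats::median(control[ids])
            row$W <- unname(wt$statistic)
            row$p_value <- wt$p.value
        }
        row
    })
    do.call(rbind, rows)
}

#' Strand-oriented upstream signal sum
#'
#' Sums track signal over `[TSS - window, TSS)` in the transcriptional
#' direction — the torsion-profiling convention of summing signal 200 bp
#' upstream of each TSS (the TSS base itself is excluded).
#'
#' @param track a [CoverageTrack-class].
#' @param promoters a promoter `GRanges`.
#' @param window bp upstream (default 200).
#' @return Named per-promoter numeric vector.
#' @export
upstreamSum <- function(track, promoters, window = 200) {
    if (window <= 0) stop("window must be positive")
    regionSum(track, promoters, upstream = window, downstream = 0)
}

#' Remove extreme high outliers by z-score
#'
#' Single pass: the mean and SD are computed once from the full input (or
#' taken as given), and entries with `z = (x - mean)/sd` strictly greater
#' than `thresholdSds` are removed. The default threshold of 64 SDs removes
#' only catastrophic outliers while leaving the heavy right tail of genomic
#' signal untouched.
#'
#' @param values named per-promoter numeric vector (n >= 3).
#' @param thresholdSds z-score threshold (strict `>`).
#' @param center,scale optional externally supplied mean and SD; by default
#'   both are computed from `values`.
#' @return list with `values` (the retained entries) and `report`, a
#'   data.frame of removed entries (`promoter_id`, `value`, `z`) carrying
#'   attributes `mean`, `sd`, `threshold_sds`.
#' @export
filterOutliers <- function(values, thresholdSds = 64, center = NULL,
                           scale = NULL) {
    if (length(values) < 3L && (is.null(center) || is.null(scale)))
        stop("need at least 3 values to estimate mean and SD")
    m <- if (is.null(center)) mean(values) else center
    s <- if (is.null(scale)) stats::sd(values) else scale
    if (is.na(s) || s == 0) {
        warning("SD is zero; no outliers removed")
        removed <- logical(length(values))
        z <- rep(NA_real_, length(values))
    } else {
        z <- (values - m) / s
        removed <- z > thresholdSds
    }
    report <- data.frame(promoter_id = names(values)[removed],
                         value = unname(values[removed]),
                         z = unname(z[removed]))
    attr(report, "mean") <- m
    attr(report, "sd") <- s
    attr(report, "threshold_sds") <- thresholdSds
    list(values = values[!removed], report = report)
}

#' Switch point between two distance-response curves
#'
#' The distance below which `curveA` consistently exceeds `curveB`: the
#' curves are scanned in decreasing-distance order and the longest suffix on
#' which `curveA > curveB` at every point is found; the estimate is that
#' suffix's largest median distance. Returns `NA` when the last point is not
#' dominant (no stable crossing).
#'
#' @param curveA,curveB [movingMedianCurve()] outputs on the same promoter
#'   set (identical distance grids).
#' @return bp estimate, or `NA_real_`.
#' @export
switchPoint <- function(curveA, curveB) {
    if (nrow(curveA) != nrow(curveB) ||
        max(abs(curveA$median_distance - curveB$median_distance)) > 1e-8)
        stop("curves must share the same distance grid")
    dom <- curveA$median_signal > curveB$median_signal
    n <- length(dom)
    if (!dom[n]) return(NA_real_)
    lastFail <- if (all(dom)) 0L else max(which(!dom))
    curveA$median_distance[lastFail + 1L]
}
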