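# Treatment-versus-control fold-change profiles and expression-quintile
# stratification.

#' Per-bin fold-change profile between two matrices
#'
#' Averages each matrix over a promoter subset per bin, then divides
#' (treated mean / control mean) bin-wise. No pseudocount is applied:
#' bins with a zero control mean are reported as `NA`. On the log2 scale the
#' ratio's log2 is returned where defined.
#'
#' @param treated,control [CoverageMatrix-class] objects on the same bin
#'   grid and promoter set.
#' @param subset optional character vector of promoter IDs (default: all
#'   shared rows).
#' @param scale `"linear"` or `"log2"`.
#' @return data.frame with `bin_center`, `ratio`, `n_rows`; attributes
#'   `scale` and `subset_label`.
#' @export
foldChangeProfile <- function(treated, control, subset = NULL,
                              scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    if (binSize(treated) != binSize(control) ||
        treated@upstream != control@upstream ||
        treated@downstream != control@downstream)
        stop("matrices have mismatched bin grids")
    tv <- matrixValues(treated)
    cv <- matrixValues(control)
    if (!setequal(rownames(tv), rownames(cv)))
        stop("matrices cover different promoter sets")
    cv <- cv[rownames(tv), , drop = FALSE]
    if (is.null(subset)) subset <- rownames(tv)
    if (!length(subset)) stop("subset is empty")
    missing <- setdiff(subset, rownames(tv))
    if (length(missing))
        stop("subset IDs not in matrices: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    tm <- colMeans(tv[subset, , drop = FALSE], na.rm = TRUE)
    cm <- colMeans(cv[subset, , drop = FALSE], na.rm = TRUE)
    ratio <- ifelse(cm > 0, tm / cm, NA_real_)
    if (scale == "log2") ratio <- log2(ratio)
    out <- data.frame(bin_center = binCenters(treated), ratio = ratio,
                      n_rows = length(subset))
    attr(out, "scale") <- scale
    out
}

#' Expression quintiles
#'
#' Sorts genes by expression in descending order (ties broken by promoter
#' ID) and splits them into five contiguous blocks, Q1 the most expressed,
#' Q5 the least. Block sizes are as equal as possible; when n is not a
#' multiple of 5 the extra members go to the top quintiles.
#'
#' @param expression named nonnegative per-promoter expression values
#'   (n >= 5).
#' @return Named factor (levels `Q1`..`Q5`), names are promoter IDs.
#' @export
expressionQuintiles <- function(expression) {
    n <- length(expression)
    if (n < 5L) stop("need at least 5 genes for quintiles")
    if (is.null(names(expression)) || anyDuplicated(names(expression)))
        stop("expression must be named by unique promoter IDs")
    ord <- order(-expression, names(expression))
    base <- n %/% 5L
    rem <- n %% 5L
    sizes <- base + as.integer(seq_len(5L) <= rem)
    q <- factor(rep(paste0("Q", 1:5), times = sizes),
                levels = paste0("Q", 1:5))
    stats::setNames(q[order(ord)], names(expression))
}

#' Display transform for expression values
#'
#' `x -> log10(x + 1)`: the constant 1 keeps genes with zero expression
#' visible on a log axis. Display only — quintile ranking always uses the
#' raw values (adding a constant does not change ranks anyway).
#'
#' @param expression nonnegative numeric vector.
#' @return `log10(expression + 1)`, names preserved.
#' @export
logDisplayTransform <- function(expression) {
    if (any(expression < 0)) stop("expression values must be nonnegative")
    log10(expression + 1)
}

#' Fold-change profiles stratified by quintile and orientation
#'
#' One [foldChangeProfile()] per (expression quintile, promoter orientation)
#' cell; empty cells are omitted with a warning.
#'
#' @param treated,control [CoverageMatrix-class] on the same grid, typically
#'   built over the -100/+500 bp promoter-proximal window.
#' @param quintiles [expressionQuintiles()] output.
#' @param annotations [annotateSpacing()] output (supplies orientation).
#' @param scale `"linear"` or `"log2"`.
#' @return Named list of profiles (`"Q1.divergent"`, ...).
#' @export
stratifiedProfiles <- function(treated, control, quintiles, annotations,
                               scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    rows <- rownames(matrixValues(treated))
    ori <- stats::setNames(annotations$orientation, annotations$promoter_id)
    out <- list()
    for (q in levels(quintiles)) {
        for (o in c("divergent", "tandem")) {
            ids <- rows[rows %in% names(quintiles)[quintiles == q] &
                        ori[rows] == o]
            cell <- paste(q, o, sep = ".")
            if (!length(ids)) {
                warning("empty stratum ", cell, " omitted")
                next
            }
            prof <- foldChangeProfile(treated, control, subset = ids,
                                      scale = scale)
            attr(prof, "subset_label") <- cell
            out[[cell]] <- prof
        }
    }
    out
}
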