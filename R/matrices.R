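# TSS-anchored binned matrices, promoter clustering, and profile extraction.

# 1-based bin start coordinates for one promoter window, transcription-
# oriented: bin 1 is the most upstream bin; for minus-strand promoters the
# genomic coordinates run rightward of the TSS.
.binStarts <- function(tss1, isPlus, upstream, nbins, binSize) {
    j <- seq_len(nbins)
    if (isPlus) tss1 - upstream + (j - 1L) * binSize
    else        tss1 + upstream - j * binSize + 1L
}

#' TSS-anchored binned coverage matrix
#'
#' One row per promoter, one column per `binSize`-bp bin from `upstream` bp
#' before to `downstream` bp after the TSS, in the transcriptional sense
#' (minus-strand rows are reversed so bin order always runs upstream to
#' downstream). Bin values are per-base means (or sums) of the track within
#' the bin. Windows overrunning a chromosome end contribute only covered
#' bases; bins entirely off the end are `NA`.
#'
#' @param track a [CoverageTrack-class].
#' @param promoters a promoter `GRanges` from [promoterSet()].
#' @param upstream,downstream window extent in bp (each divisible by
#'   `binSize`). Default +/- 2,500 bp.
#' @param binSize bin width in bp (default 10).
#' @param binStat `"mean"` (default) or `"sum"` per bin.
#' @return A [CoverageMatrix-class].
#' @export
tssMatrix <- function(track, promoters, upstream = 2500, downstream = 2500,
                      binSize = 10, binStat = c("mean", "sum")) {
    binStat <- match.arg(binStat)
    if (upstream %% binSize != 0 || downstream %% binSize != 0)
        stop("binSize must divide both upstream and downstream")
    nbins <- as.integer((upstream + downstream) / binSize)
    rl <- trackValues(track)
    chs <- as.character(seqnames(promoters))
    if (!all(chs %in% names(rl)))
        stop("promoter on undeclared chromosome: ",
             paste(unique(setdiff(chs, names(rl))), collapse = ", "))
    ids <- mcols(promoters)$id
    tss1 <- start(promoters)
    plus <- as.character(strand(promoters)) == "+"
    M <- matrix(NA_real_, length(promoters), nbins,
                dimnames = list(ids, NULL))
    for (ch in unique(chs)) {
        sel <- which(chs == ch)
        len <- length(rl[[ch]])
        st <- t(vapply(sel, function(i)
            .binStarts(tss1[i], plus[i], upstream, nbins, binSize),
            numeric(nbins)))
        cs <- pmax(as.vector(st), 1)
        ce <- pmin(as.vector(st) + binSize - 1, len)
        ok <- cs <= ce
        vals <- rep(NA_real_, length(cs))
        if (any(ok)) {
            vw <- Views(rl[[ch]], start = as.integer(cs[ok]),
                        end = as.integer(ce[ok]))
            vals[ok] <- if (binStat == "mean") viewMeans(vw) else viewSums(vw)
        }
        M[sel, ] <- matrix(vals, length(sel), nbins)
    }
    new("CoverageMatrix", values = M, binSize = as.integer(binSize),
        upstream = as.integer(upstream), downstream = as.integer(downstream),
        binStat = binStat)
}

#' K-means clustering of promoters by their matrix rows
#'
#' Standard Euclidean k-means on the rows of a [CoverageMatrix-class] with
#' multiple random restarts, followed by deterministic relabeling: clusters
#' are renamed `I`, `II`, ... in order of descending mean signal, so the
#' most accessible cluster is always `I` regardless of the seed.
#'
#' By default rows are `log1p`-scaled before clustering: coverage noise is
#' multiplicative, so on the raw scale the within-cluster scatter of
#' high-signal promoters dwarfs the separation between low-signal clusters
#' and Euclidean k-means splits the top cluster instead. The log scale keeps
#' distances comparable across the dynamic range. Relabeling and the
#' returned assignment always refer to the raw-scale mean signal.
#'
#' @param matrix a [CoverageMatrix-class].
#' @param k number of clusters (the study convention is 3).
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts (best inertia wins).
#' @param transform `"log1p"` (default) or `"none"`: row scaling applied
#'   before the Euclidean k-means step.
#' @return A [ClusterAssignment-class].
#' @export
kmeansPromoters <- function(matrix, k = 3, seed = 1L, nstart = 10,
                            transform = c("log1p", "none")) {
    transform <- match.arg(transform)
    vals <- matrixValues(matrix)
    if (anyNA(vals)) {
        warning("NA bins (chromosome-edge windows) replaced by 0 for clustering")
        vals[is.na(vals)] <- 0
    }
    raw <- vals
    if (transform == "log1p") vals <- log1p(vals)
    if (k < 1) stop("k must be >= 1")
    ids <- rownames(vals)
    ndistinct <- nrow(unique(vals))
    if (ndistinct < k) {
        warning("only ", ndistinct, " distinct row profile(s); reporting ",
                ndistinct, " effective cluster(s)")
        k_eff <- ndistinct
    } else k_eff <- k
    if (k_eff == 1L || nrow(vals) == 1L) {
        cl <- rep(1L, nrow(vals))
    } else {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)
        km <- stats::kmeans(vals, centers = k_eff, nstart = nstart,
                            iter.max = 100)
        cl <- km$cluster
    }
    # relabel by descending raw-scale mean signal
    means <- tapply(rowMeans(raw), cl, mean)
    ord <- order(-means)
    relab <- integer(length(means))
    relab[as.integer(names(means))[ord]] <- seq_along(ord)
    labels <- as.character(utils::as.roman(relab[cl]))
    fac <- factor(labels, levels = as.character(utils::as.roman(seq_len(k_eff))))
    names(fac) <- ids
    new("ClusterAssignment", clusters = fac, k = as.integer(k),
        seed = as.integer(seed))
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Reorder a matrix by cluster, then by descending row mean
#'
#' A stable reordering for heatmap display and for applying one dataset's
#' clustering to another dataset's matrix (rows are matched by promoter ID;
#' values are never changed).
#'
#' @param matrix a [CoverageMatrix-class].
#' @param clusters a [ClusterAssignment-class] covering the matrix rows.
#' @return The reordered [CoverageMatrix-class].
#' @export
applyClusters <- function(matrix, clusters) {
    vals <- matrixValues(matrix)
    lab <- clusterLabels(clusters)
    missing <- setdiff(rownames(vals), names(lab))
    if (length(missing))
        stop("cluster assignment missing promoter ID(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    rl <- lab[rownames(vals)]
    ord <- order(as.integer(rl), -rowMeans(vals, na.rm = TRUE),
                 rownames(vals))
    new("CoverageMatrix", values = vals[ord, , drop = FALSE],
        binSize = matrix@binSize, upstream = matrix@upstream,
        downstream = matrix@downstream, binStat = matrix@binStat)
}

#' Per-bin mean profile over (a subset of) matrix rows
#'
#' @param matrix a [CoverageMatrix-class].
#' @param rowSubset optional character vector of promoter IDs.
#' @return data.frame with `bin_center` (bp relative to TSS), `value`
#'   (per-bin mean over rows, `NA` bins excluded) and `n_rows`.
#' @export
meanProfile <- function(matrix, rowSubset = NULL) {
    vals <- matrixValues(matrix)
    if (!is.null(rowSubset)) {
        if (!length(rowSubset)) stop("row subset is empty")
        missing <- setdiff(rowSubset, rownames(vals))
        if (length(missing))
            stop("subset IDs not in matrix: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        vals <- vals[rowSubset, , drop = FALSE]
    }
    data.frame(bin_center = binCenters(matrix),
               value = colMeans(vals, na.rm = TRUE),
               n_rows = nrow(vals))
}

#' Binned per-condition signal over one genomic region
#'
#' The generic computation behind locus-level average-coverage plots (e.g.
#' over a histone gene cluster): mean signal per fixed-width bin across a
#' region, for each condition's track.
#'
#' @param tracks named list of [CoverageTrack-class] (names are conditions).
#' @param chrom chromosome label.
#' @param start,end region in 0-based half-open coordinates.
#' @param binSize bin width in bp; a final partial bin is averaged over its
#'   actual width.
#' @return data.frame with `condition`, `bin_start` (0-based), `bin_center`,
#'   `value`.
#' @export
regionProfile <- function(tracks, chrom, start, end, binSize = 10) {
    if (end <= start) stop("empty region")
    if (!length(tracks)) stop("no tracks given")
    out <- list()
    for (cond in names(tracks)) {
        rl <- trackValues(tracks[[cond]])
        if (!chrom %in% names(rl))
            stop("region chromosome ", chrom, " not in track '", cond, "'")
        len <- length(rl[[chrom]])
        if (start < 0 || end > len)
            stop("region outside chromosome ", chrom)
        bs <- seq(start, end - 1L, by = binSize)
        be <- pmin(bs + binSize, end)
        vw <- Views(rl[[chrom]], start = as.integer(bs + 1L),
                    end = as.integer(be))
        out[[cond]] <- data.frame(condition = cond, bin_start = bs,
                                  bin_center = (bs + be) / 2,
                                  value = viewMeans(vw))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Strand-oriented promoter-proximal signal sum
#'
#' Sums per-base signal over `[TSS - upstream, TSS + downstream)` in the
#' transcriptional direction (for minus-strand promoters "downstream" runs
#' toward smaller coordinates). The study convention for promoter
#' accessibility is 100 bp upstream to 500 bp downstream.
#'
#' @param track a [CoverageTrack-class].
#' @param promoters a promoter `GRanges` (one or many).
#' @param upstream,downstream window extent in bp.
#' @return Named numeric vector of per-promoter sums (names are IDs).
#' @export
regionSum <- function(track, promoters, upstream = 100, downstream = 500) {
    rl <- trackValues(track)
    chs <- as.character(seqnames(promoters))
    if (!all(chs %in% names(rl)))
        stop("promoter on undeclared chromosome: ",
             paste(unique(setdiff(chs, names(rl))), collapse = ", "))
    tss1 <- start(promoters)
    plus <- as.character(strand(promoters)) == "+"
    ws <- ifelse(plus, tss1 - upstream, tss1 - downstream + 1)
    we <- ifelse(plus, tss1 + downstream - 1, tss1 + upstream)
    res <- numeric(length(promoters))
    for (ch in unique(chs)) {
        sel <- which(chs == ch)
        len <- length(rl[[ch]])
        cs <- pmax(ws[sel], 1)
        ce <- pmin(we[sel], len)
        ok <- cs <= ce
        v <- numeric(length(sel))
        if (any(ok))
            v[ok] <- viewSums(Views(rl[[ch]], start = as.integer(cs[ok]),
                                    end = as.integer(ce[ok])))
        res[sel] <- v
    }
    stats::setNames(res, mcols(promoters)$id)
}
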