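# Brute-force oracles and fixture builders, independent of the package's
# implementation paths: per-base loops and all-pairs searches only.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

# A track as plain per-base numeric vectors (element i = 0-based position
# i - 1), keyed by chromosome.
trackAsVectors <- function(track) {
    lapply(as.list(trackValues(track)), as.numeric)
}

vectorsAsTrack <- function(vecs, calibration = "raw", scaleUsed = 1) {
    rl <- as(lapply(vecs, Rle), "SimpleRleList")
    cutacProfiler:::CoverageTrack(rl, calibration = calibration,
                                  scaleUsed = scaleUsed)
}

# fragments: data.frame(chrom, start, end), 0-based half-open
bruteForcePileup <- function(frags, chromLens) {
    out <- lapply(chromLens, function(L) numeric(L))
    for (i in seq_len(nrow(frags))) {
        ch <- frags$chrom[i]
        for (p in seq(frags$start[i], frags$end[i] - 1L))
            out[[ch]][p + 1L] <- out[[ch]][p + 1L] + 1
    }
    out
}

# promoters: data.frame(id, chrom, tss (0-based), strand)
# track: list of per-base vectors. Returns promoters x bins matrix.
bruteForceMatrix <- function(track, prom, upstream, downstream, binSize,
                             stat = "mean") {
    nbins <- (upstream + downstream) / binSize
    M <- matrix(NA_real_, nrow(prom), nbins, dimnames = list(prom$id, NULL))
    for (i in seq_len(nrow(prom))) {
        v <- track[[prom$chrom[i]]]
        L <- length(v)
        for (j in seq_len(nbins)) {
            tt <- (-upstream + (j - 1L) * binSize):(-upstream + j * binSize - 1L)
            g <- if (prom$strand[i] == "+") prom$tss[i] + tt
                 else prom$tss[i] - tt
            g <- g[g >= 0 & g < L]
            if (length(g))
                M[i, j] <- if (stat == "mean") mean(v[g + 1L]) else sum(v[g + 1L])
        }
    }
    M
}

bruteForceRegionSum <- function(track, prom, upstream, downstream) {
    res <- numeric(nrow(prom))
    for (i in seq_len(nrow(prom))) {
        v <- track[[prom$chrom[i]]]
        L <- length(v)
        tt <- (-upstream):(downstream - 1L)
        g <- if (prom$strand[i] == "+") prom$tss[i] + tt else prom$tss[i] - tt
        g <- g[g >= 0 & g < L]
        res[i] <- sum(v[g + 1L])
    }
    setNames(res, prom$id)
}

# All-pairs nearest-upstream search.
bruteForceSpacing <- function(prom) {
    n <- nrow(prom)
    neighbor <- rep(NA_character_, n)
    distance <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        cand <- which(prom$chrom == prom$chrom[i] &
            if (prom$strand[i] == "+") prom$tss < prom$tss[i]
            else prom$tss > prom$tss[i])
        if (!length(cand)) next
        dd <- abs(prom$tss[cand] - prom$tss[i])
        cand <- cand[dd == min(dd)]
        if (length(cand) > 1L) {
            opp <- cand[prom$strand[cand] != prom$strand[i]]
            if (length(opp)) cand <- opp
            cand <- cand[order(prom$id[cand])]
        }
        neighbor[i] <- prom$id[cand[1L]]
        distance[i] <- abs(prom$tss[cand[1L]] - prom$tss[i])
    }
    orientation <- ifelse(is.na(neighbor), "none",
        ifelse(prom$strand[match(neighbor, prom$id)] != prom$strand,
               "divergent", "tandem"))
    data.frame(promoter_id = prom$id, neighbor_id = neighbor,
               distance = distance, orientation = orientation)
}

bruteForceMovingStat <- function(signal, distances, window, stat = "median") {
    ids <- intersect(names(signal), names(distances[!is.na(distances)]))
    d <- distances[ids]; s <- signal[ids]
    ord <- order(-d, ids)
    d <- as.numeric(d[ord]); s <- as.numeric(s[ord])
    h <- (window - 1L) / 2L
    f <- if (stat == "median") median else mean
    idx <- (h + 1L):(length(d) - h)
    data.frame(
        median_distance = vapply(idx, function(i) f(d[(i - h):(i + h)]),
                                 numeric(1)),
        median_signal = vapply(idx, function(i) f(s[(i - h):(i + h)]),
                               numeric(1)))
}

# Random instance builders --------------------------------------------------

randomGenomeDf <- function(nChrom = 2, maxLen = 10000, minLen = 2000) {
    lens <- sample(minLen:maxLen, nChrom, replace = TRUE)
    setNames(lens, paste0("chr", seq_len(nChrom)))
}

randomFragmentsDf <- function(chromLens, n = 100, maxLen = 50) {
    ch <- sample(names(chromLens), n, replace = TRUE)
    w <- sample(1:maxLen, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i)
        sample(0:(chromLens[[ch[i]]] - w[i]), 1L), numeric(1))
    data.frame(chrom = ch, start = start, end = start + w)
}

randomPromotersDf <- function(chromLens, n = 30) {
    ch <- sample(names(chromLens), n, replace = TRUE)
    tss <- vapply(seq_len(n), function(i)
        sample(0:(chromLens[[ch[i]]] - 1L), 1L), numeric(1))
    # dedupe (chrom, tss, strand) triples
    str <- sample(c("+", "-"), n, replace = TRUE)
    keep <- !duplicated(paste(ch, tss, str))
    data.frame(id = sprintf("p%03d", seq_len(sum(keep))),
               chrom = ch[keep], tss = tss[keep], strand = str[keep])
}

randomTrackVectors <- function(chromLens) {
    lapply(chromLens, function(L) round(runif(L, 0, 5), 2))
}

promotersFromDf <- function(prom, chromLens) {
    promoterSet(prom$chrom, prom$tss, prom$strand, prom$id,
                SyntheticGenome(chromLens))
}
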