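# Synthetic data generation: promoter tables, condition-specific fragment
# sets with plantable effects, expression tables and torsion tracks.
#
# All generators are seeded and reproducible: the same arguments and seed
# give byte-identical output. Coordinates are 0-based half-open in every
# file written; 1-based closed in the GRanges held in memory.

.withSeed <- function(seed, expr) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    expr
}

# Draw n inter-promoter gaps from a spacing-law spec.
.sampleGaps <- function(n, law) {
    g <- switch(law$dist,
        fixed = rep(law$gap, n),
        lognormal = stats::rlnorm(n, meanlog = law$meanlog,
                                  sdlog = law$sdlog),
        uniform = stats::runif(n, law$min, law$max),
        mixture = {
            modes <- law$modes
            w <- if (is.null(law$weights)) rep(1 / length(modes),
                                               length(modes)) else law$weights
            sdlog <- if (is.null(law$sdlog)) 0.2 else law$sdlog
            pick <- sample.int(length(modes), n, replace = TRUE, prob = w)
            stats::rlnorm(n, meanlog = log(modes[pick]), sdlog = sdlog)
        },
        stop("unknown spacing law: ", law$dist))
    pmax(1, round(g))
}

#' Default promoter spacing law
#'
#' Lognormal inter-promoter gaps with median 1,300 bp and sdlog 1, chosen so
#' roughly 40% of promoters sit within 1 kb of their upstream neighbor — a
#' realistic density for a compact metazoan genome.
#'
#' @return A spacing-law list usable as `spacingLaw` in
#'   [simulatePromoters()].
#' @export
defaultSpacingLaw <- function() {
    list(dist = "lognormal", meanlog = log(1300), sdlog = 1)
}

#' Generate a synthetic promoter table
#'
#' Places promoters along the genome with inter-promoter gaps drawn from
#' `spacingLaw`, and assigns strands by a Markov rule: each promoter's
#' strand is flipped relative to the previous promoter's with probability
#' `divergentFraction`, so the realized fraction of divergently oriented
#' neighbor pairs approximates the request.
#'
#' @param nPromoters number of promoters (>= 2).
#' @param genome a [SyntheticGenome-class].
#' @param spacingLaw spacing-law list: `list(dist = "fixed", gap = )`,
#'   `list(dist = "lognormal", meanlog = , sdlog = )`,
#'   `list(dist = "uniform", min = , max = )` or
#'   `list(dist = "mixture", modes = , weights = , sdlog = )`.
#' @param divergentFraction target fraction of divergent neighbor pairs in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @return A promoter `GRanges` sorted by chromosome and coordinate, with
#'   unique IDs `P00001`, ...
#' @export
simulatePromoters <- function(nPromoters, genome,
                              spacingLaw = defaultSpacingLaw(),
                              divergentFraction = 0.5, seed = 1L) {
    if (nPromoters < 2) stop("need at least 2 promoters")
    if (divergentFraction < 0 || divergentFraction > 1)
        stop("divergentFraction must be in [0, 1]")
    .withSeed(seed, {
        cl <- chromLengths(genome)
        # promoters allocated to chromosomes proportionally to length
        alloc <- floor(nPromoters * cl / sum(cl))
        rem <- nPromoters - sum(alloc)
        if (rem > 0) {
            extra <- order(-(nPromoters * cl / sum(cl) - alloc))
            alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1L
        }
        chrom <- character(0); tss <- numeric(0); str <- character(0)
        for (ch in names(cl)) {
            k <- alloc[[ch]]
            if (k == 0) next
            gaps <- .sampleGaps(k, spacingLaw)
            pos <- cumsum(gaps)
            if (pos[k] >= cl[[ch]])
                stop("genome too short to place ", nPromoters,
                     " promoters without coordinate collisions (chromosome ",
                     ch, " needs ", pos[k] + 1, " bp, has ", cl[[ch]], ")")
            s <- character(k)
            # deterministic minus-strand start: with divergentFraction = 1
            # the first pair is head-to-head (divergent), not convergent
            s[1L] <- "-"
            if (k > 1L) {
                flip <- stats::runif(k - 1L) < divergentFraction
                for (i in 2:k)
                    s[i] <- if (flip[i - 1L])
                        setdiff(c("+", "-"), s[i - 1L]) else s[i - 1L]
            }
            chrom <- c(chrom, rep(ch, k))
            tss <- c(tss, pos)
            str <- c(str, s)
        }
        ids <- sprintf("P%05d", seq_along(chrom))
        promoterSet(chrom, tss, str, ids, genome)
    })
}

#' Assign planted cluster classes to promoters
#'
#' Random class labels 1..3 used with `classRates` in [EffectModel()] to
#' plant three accessibility levels for clustering tests. Default
#' proportions mimic the small highly accessible / medium / large background
#' cluster structure of promoter accessibility data.
#'
#' @param promoters a promoter `GRanges`.
#' @param proportions length-3 class proportions (summing to 1).
#' @param seed RNG seed.
#' @return Named integer vector of classes in `{1, 2, 3}` (1 = highest
#'   rate by convention of `classRates`).
#' @export
assignPromoterClasses <- function(promoters,
                                  proportions = c(0.08, 0.32, 0.60),
                                  seed = 1L) {
    .withSeed(seed, {
        cls <- sample.int(3L, length(promoters), replace = TRUE,
                          prob = proportions)
        stats::setNames(cls, mcols(promoters)$id)
    })
}

#' Generate a synthetic fragment set with planted effects
#'
#' Fragments concentrate near TSSs with per-promoter rates
#' `baselineRate * classRates[class] * boost`, where the boost applies to
#' divergent promoters closer than `distanceCutoff` bp to their upstream
#' neighbor (computed with [annotateSpacing()]). Per-promoter counts are
#' negative-binomial with the model's dispersion; a background fraction is
#' placed uniformly over the genome. Fragment lengths are uniform in
#' `[50, 300]` bp (nucleosomal/subnucleosomal); midpoints are normal around
#' the TSS shifted `downstreamShift` bp downstream. The requested
#' `spikeCount` is carried verbatim on the returned [FragmentSet-class].
#'
#' @param promoters a promoter `GRanges` (nonempty).
#' @param effects an [EffectModel-class].
#' @param nTotal expected total fragment count (> 0).
#' @param spikeCount spike-in fragment count (> 0), stored verbatim.
#' @param sampleId sample label.
#' @param classes optional named class vector from
#'   [assignPromoterClasses()]; default: every promoter class 2.
#' @return A [FragmentSet-class].
#' @export
simulateFragments <- function(promoters, effects, nTotal, spikeCount,
                              sampleId = "sample", classes = NULL) {
    if (!length(promoters)) stop("empty promoter list")
    if (nTotal <= 0) stop("nTotal must be > 0")
    if (spikeCount <= 0) stop("spikeCount must be > 0")
    ids <- mcols(promoters)$id
    if (is.null(classes)) classes <- stats::setNames(rep(2L, length(ids)), ids)
    spacing <- annotateSpacing(promoters)
    boosted <- !is.na(spacing$distance) &
        spacing$orientation == "divergent" &
        spacing$distance < effects@distanceCutoff
    rate <- effects@baselineRate * effects@classRates[classes[ids]] *
        ifelse(boosted, effects@divergentCloseBoost, 1)
    .withSeed(effects@seed, {
        nSig <- round((1 - effects@backgroundFraction) * nTotal)
        nBg <- round(effects@backgroundFraction * nTotal)
        mu <- nSig * rate / sum(rate)
        counts <- if (effects@noiseDispersion == 0)
            stats::rpois(length(mu), mu)
        else stats::rnbinom(length(mu), mu = mu,
                            size = 1 / effects@noiseDispersion)
        tss1 <- start(promoters)
        plus <- as.character(strand(promoters)) == "+"
        chs <- as.character(seqnames(promoters))
        mid <- rep(tss1, counts) +
            ifelse(rep(plus, counts), 1, -1) *
            round(stats::rnorm(sum(counts), mean = effects@downstreamShift,
                               sd = effects@footprintSd))
        fragChrom <- rep(chs, counts)
        len <- round(stats::runif(sum(counts), 50, 300))
        fs <- round(mid - len / 2)
        # background uniform over the genome
        cl <- chromLengths(promoters)
        if (nBg > 0) {
            bgChrom <- sample(names(cl), nBg, replace = TRUE,
                              prob = cl / sum(cl))
            bgLen <- round(stats::runif(nBg, 50, 300))
            bgStart <- floor(stats::runif(nBg) *
                             (cl[bgChrom] - bgLen)) + 1
            fragChrom <- c(fragChrom, bgChrom)
            fs <- c(fs, bgStart)
            len <- c(len, bgLen)
        }
        # shift fragments fully inside their chromosome
        lim <- cl[fragChrom]
        fs <- pmin(pmax(fs, 1), lim - len + 1)
        gr <- GRanges(fragChrom, IRanges(start = fs, width = len),
                      seqinfo = asSeqinfo(stats::setNames(as.numeric(cl),
                                                          names(cl))))
        gr <- sort(gr)
        names(gr) <- sprintf("frag_%07d", seq_along(gr))
        FragmentSet(gr, spikeCount = spikeCount, sampleId = sampleId)
    })
}

#' Expected total-signal gain of a planted effect model
#'
#' The factor by which an effect model's boosts raise the expected total
#' promoter signal relative to the same model with no boost. Useful for
#' choosing a depth-consistent spike count: a sample whose true signal is
#' `g`-fold higher captures `1/g` as many spike fragments at equal
#' sequencing depth, so passing `spikeCount = baseline / g` to
#' [simulateFragments()] makes spike calibration restore unboosted
#' promoters to control levels while boosted promoters gain.
#'
#' @param promoters a promoter `GRanges`.
#' @param effects an [EffectModel-class].
#' @param classes optional class vector ([assignPromoterClasses()]).
#' @return The gain factor `g >= 1`.
#' @export
accessibilityGain <- function(promoters, effects, classes = NULL) {
    ids <- mcols(promoters)$id
    if (is.null(classes)) classes <- stats::setNames(rep(2L, length(ids)), ids)
    spacing <- annotateSpacing(promoters)
    boosted <- !is.na(spacing$distance) &
        spacing$orientation == "divergent" &
        spacing$distance < effects@distanceCutoff
    base <- effects@baselineRate * effects@classRates[classes[ids]]
    sum(base * ifelse(boosted, effects@divergentCloseBoost, 1)) / sum(base)
}

#' Generate a synthetic expression table
#'
#' Per-orientation lognormal expression with the requested group medians
#' (lognormal median = exp(meanlog), so realized group medians converge on
#' the targets). Promoters without an upstream neighbor get the tandem
#' median. `dispersion = 0` makes every gene exactly its group median.
#'
#' @param promoters a promoter `GRanges`.
#' @param divergentMedian,tandemMedian group medians (>= 0); defaults are
#'   the divergent/tandem medians observed for fly promoter catalogues
#'   (210.3 and 34.5 expression units).
#' @param dispersion lognormal sdlog (>= 0).
#' @param seed RNG seed.
#' @return data.frame with `promoter_id`, `value`.
#' @export
simulateExpression <- function(promoters, divergentMedian = 210.3,
                               tandemMedian = 34.5, dispersion = 1,
                               seed = 1L) {
    if (divergentMedian < 0 || tandemMedian < 0)
        stop("group medians must be nonnegative")
    spacing <- annotateSpacing(promoters)
    med <- ifelse(spacing$orientation == "divergent",
                  divergentMedian, tandemMedian)
    .withSeed(seed, {
        value <- ifelse(med > 0,
            med * exp(stats::rnorm(length(med), 0, dispersion)), 0)
        data.frame(promoter_id = spacing$promoter_id, value = value)
    })
}

#' Write / read a two-column expression TSV
#'
#' @param expression data.frame with `promoter_id`, `value`.
#' @param path file path.
#' @export
writeExpression <- function(expression, path) {
    utils::write.table(expression[c("promoter_id", "value")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpression
#' @return `readExpression`: named numeric vector of expression values.
#' @export
readExpression <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stats::setNames(df$value, df$promoter_id)
}

#' Generate a synthetic torsion track
#'
#' Emulates an intercalation-based supercoiling readout: short reads pile up
#' in the 200 bp upstream of each TSS, with `closePairEnrichment`-fold more
#' reads at promoters whose nearest upstream neighbor is closer than
#' `distanceCutoff`, over a thin uniform background.
#'
#' @param promoters a promoter `GRanges`.
#' @param closePairEnrichment fold enrichment (>= 1) at close promoters.
#' @param distanceCutoff bp cutoff defining "close" (default 1,000).
#' @param baseReads expected reads per non-enriched promoter window.
#' @param upstreamWindow bp upstream of the TSS receiving promoter reads.
#' @param seed RNG seed.
#' @return A raw [CoverageTrack-class].
#' @export
simulateTorsionTrack <- function(promoters, closePairEnrichment = 1,
                                 distanceCutoff = 1000, baseReads = 20,
                                 upstreamWindow = 200, seed = 1L) {
    if (closePairEnrichment < 1) stop("enrichment must be >= 1")
    spacing <- annotateSpacing(promoters)
    close <- !is.na(spacing$distance) & spacing$distance < distanceCutoff
    rate <- baseReads * ifelse(close, closePairEnrichment, 1)
    .withSeed(seed, {
        counts <- stats::rpois(length(rate), rate)
        tss1 <- start(promoters)
        plus <- as.character(strand(promoters)) == "+"
        chs <- as.character(seqnames(promoters))
        readLen <- 50
        # uniform placement inside the strand-oriented upstream window
        off <- floor(stats::runif(sum(counts)) * (upstreamWindow - readLen))
        s <- ifelse(rep(plus, counts),
                    rep(tss1, counts) - upstreamWindow + off,
                    rep(tss1, counts) + upstreamWindow - off - readLen + 1)
        cl <- chromLengths(promoters)
        nBg <- max(1L, round(0.05 * sum(counts)))
        bgChrom <- sample(names(cl), nBg, replace = TRUE,
                          prob = cl / sum(cl))
        bgStart <- floor(stats::runif(nBg) * (cl[bgChrom] - readLen)) + 1
        chrom <- c(rep(chs, counts), bgChrom)
        starts <- c(s, bgStart)
        lim <- cl[chrom]
        starts <- pmin(pmax(starts, 1), lim - readLen + 1)
        gr <- GRanges(chrom, IRanges(start = starts, width = readLen),
                      seqinfo = asSeqinfo(stats::setNames(as.numeric(cl),
                                                          names(cl))))
        CoverageTrack(coverage(gr), calibration = "raw", scaleUsed = 1)
    })
}

# chromLengths for a promoter GRanges (from its seqinfo)
setMethod("chromLengths", "GRanges", function(x) {
    sl <- seqlengths(x)
    stats::setNames(as.numeric(sl), names(sl))
})
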