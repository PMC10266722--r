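# Nearest-upstream promoter spacing and divergent/tandem orientation.
#
# "Upstream" is relative to the focal promoter's own strand: for a plus-
# strand promoter the upstream neighbor is the promoter (either strand) with
# the largest TSS strictly below its own on the same chromosome; for a
# minus-strand promoter, the smallest TSS strictly above. A neighbor on the
# opposite strand makes the pair divergent (head-to-head), a same-strand
# neighbor makes it tandem. Distances are TSS-to-TSS in bp. Neighbors are
# never searched across chromosome boundaries.

#' Annotate nearest-upstream spacing and orientation
#'
#' For each promoter, finds its nearest upstream neighbor (see Details),
#' the TSS-to-TSS distance, and the divergent/tandem orientation call.
#' Promoters with no upstream neighbor on their chromosome get orientation
#' `"none"` and `NA` distance. When two upstream promoters are equidistant
#' (same TSS, opposite strands), the opposite-strand one is chosen, then the
#' lexicographically smaller ID.
#'
#' @param promoters a promoter `GRanges` from [promoterSet()].
#' @return A `data.frame` with columns `promoter_id`, `neighbor_id`,
#'   `distance` and `orientation` (`divergent`/`tandem`/`none`), in the
#'   input promoter order.
#' @examples
#' gn <- SyntheticGenome(c(chr1 = 2e4))
#' pr <- promoterSet("chr1", c(9500, 10000), c("-", "+"),
#'                   c("a", "b"), gn)
#' annotateSpacing(pr) # head-to-head pair, both divergent at 500 bp
#' @export
annotateSpacing <- function(promoters) {
    ids <- mcols(promoters)$id
    chs <- as.character(seqnames(promoters))
    tss <- start(promoters)  # 1-based; differences are convention-free
    str <- as.character(strand(promoters))
    key <- paste(chs, tss, str)
    if (anyDuplicated(key))
        stop("duplicate (chrom, tss, strand): ",
             key[which(duplicated(key))[1L]])
    n <- length(promoters)
    neighbor <- rep(NA_character_, n)
    distance <- rep(NA_real_, n)
    for (ch in unique(chs)) {
        sel <- which(chs == ch)
        o <- sel[order(tss[sel], ids[sel])]
        t <- tss[o]
        ut <- sort(unique(t))
        pos <- match(t, ut)  # rank of own TSS among distinct TSSs
        for (k in seq_along(o)) {
            i <- o[k]
            target <- if (str[i] == "+") {
                if (pos[k] == 1L) NA_real_ else ut[pos[k] - 1L]
            } else {
                if (pos[k] == length(ut)) NA_real_ else ut[pos[k] + 1L]
            }
            if (is.na(target)) next
            cand <- o[t == target]
            if (length(cand) > 1L) {
                opp <- cand[str[cand] != str[i]]
                cand <- if (length(opp)) opp else cand
                cand <- cand[order(ids[cand])]
            }
            neighbor[i] <- ids[cand[1L]]
            distance[i] <- abs(tss[i] - target)
        }
    }
    orientation <- ifelse(is.na(neighbor), "none",
        ifelse(str != str[match(neighbor, ids)], "divergent", "tandem"))
    data.frame(promoter_id = ids, neighbor_id = neighbor,
               distance = distance, orientation = orientation)
}

#' Divergent fractions below distance cutoffs
#'
#' For each cutoff, counts promoters whose nearest-upstream distance is
#' strictly below the cutoff and reports what fraction of them are
#' divergently oriented. Promoters with no upstream neighbor are excluded
#' from both numerator and denominator.
#'
#' @param annotations output of [annotateSpacing()].
#' @param distanceCutoffs positive bp cutoffs (the study reports 2,000 and
#'   1,000 bp).
#' @return data.frame with `cutoff`, `n_divergent`, `n_total`, `fraction`
#'   (`NA` when the stratum is empty).
#' @export
orientationFractions <- function(annotations,
                                 distanceCutoffs = c(2000, 1000)) {
    if (any(distanceCutoffs <= 0)) stop("cutoffs must be positive")
    has <- !is.na(annotations$distance)
    res <- lapply(distanceCutoffs, function(cut) {
        inStratum <- has & annotations$distance < cut
        nTot <- sum(inStratum)
        nDiv <- sum(inStratum & annotations$orientation == "divergent")
        data.frame(cutoff = cut, n_divergent = nDiv, n_total = nTot,
                   fraction = if (nTot > 0) nDiv / nTot else NA_real_)
    })
    do.call(rbind, res)
}

#' Write spacing annotations and orientation subsets
#'
#' Writes the annotation TSV plus BED files of the divergent and tandem
#' promoter subsets for reuse as matrix row sets.
#'
#' @param annotations output of [annotateSpacing()].
#' @param promoters the promoter `GRanges` the annotations came from.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
writeSpacing <- function(annotations, promoters, dir, prefix = "spacing") {
    tsv <- file.path(dir, paste0(prefix, ".tsv"))
    utils::write.table(annotations, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(annotations = tsv)
    for (ori in c("divergent", "tandem")) {
        ids <- annotations$promoter_id[annotations$orientation == ori]
        p <- file.path(dir, paste0(prefix, "_", ori, ".bed"))
        writePromoterBed(promoters[mcols(promoters)$id %in% ids], p)
        paths[[ori]] <- p
    }
    invisible(paths)
}
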