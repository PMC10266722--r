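# Promoter tables are plain GRanges: width-1 anchors at the TSS with strand
# and an `id` metadata column. Constructors/readers validate the invariants
# (TSS inside its chromosome, unique IDs, +/- strand).

#' Build a promoter table
#'
#' @param chrom chromosome labels.
#' @param tss 0-based TSS coordinates (the TSS base itself).
#' @param strand `"+"` or `"-"` per promoter.
#' @param id unique promoter IDs.
#' @param genome a [SyntheticGenome-class] or named vector of chromosome sizes.
#' @return A `GRanges` of width-1 TSS anchors, sorted by chromosome and
#'   coordinate, with an `id` metadata column.
#' @examples
#' gn <- SyntheticGenome(c(chr1 = 1e5))
#' promoterSet("chr1", c(1000, 5000), c("+", "-"), c("p1", "p2"), gn)
#' @export
promoterSet <- function(chrom, tss, strand, id, genome) {
    if (anyDuplicated(id))
        stop("promoter IDs must be unique")
    if (!all(strand %in% c("+", "-")))
        stop("promoter strand must be '+' or '-'")
    si <- asSeqinfo(genome)
    if (!all(chrom %in% seqlevels(si)))
        stop("promoter on undeclared chromosome: ",
             paste(unique(setdiff(chrom, seqlevels(si))), collapse = ", "))
    sl <- seqlengths(si)[as.character(chrom)]
    if (any(tss < 0 | tss >= sl))
        stop("TSS coordinate outside chromosome for promoter ",
             id[which(tss < 0 | tss >= sl)[1L]])
    gr <- GRanges(chrom, IRanges(start = as.integer(tss) + 1L, width = 1L),
                  strand = strand, seqinfo = si)
    mcols(gr)$id <- as.character(id)
    gr <- gr[order(as.factor(seqnames(gr)), start(gr), mcols(gr)$id)]
    gr
}

#' 0-based TSS coordinates of a promoter table
#'
#' @param promoters a promoter `GRanges` from [promoterSet()].
#' @return named numeric vector of 0-based TSS coordinates.
#' @export
promoterTss <- function(promoters) {
    stats::setNames(start(promoters) - 1, mcols(promoters)$id)
}

#' Read / write promoter tables as BED6
#'
#' The on-disk convention is BED6 with the TSS encoded as a 1-bp 0-based
#' half-open interval, the promoter ID in the name column and strand in
#' column 6.
#'
#' @param path file path.
#' @param genome chromosome sizes ([SyntheticGenome-class] or named vector).
#' @return `readPromoterBed`: a promoter `GRanges`.
#' @export
readPromoterBed <- function(path, genome) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6L)
        stop("promoter BED must have 6 columns (chrom start end name score strand)")
    if (any(df[[3L]] - df[[2L]] != 1L))
        stop("promoter BED intervals must be exactly 1 bp (TSS anchors)")
    promoterSet(df[[1L]], df[[2L]], df[[6L]], df[[4L]], genome)
}

#' @rdname readPromoterBed
#' @param promoters a promoter `GRanges`.
#' @return `writePromoterBed`: the path, invisibly.
#' @export
writePromoterBed <- function(promoters, path) {
    df <- data.frame(chrom = as.character(seqnames(promoters)),
                     start = start(promoters) - 1L,
                     end = start(promoters),
                     name = mcols(promoters)$id,
                     score = 0L,
                     strand = as.character(strand(promoters)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write fragment sets as 4-column BED with a JSON spike sidecar
#'
#' Fragments are stored as BED4 (chrom, start, end, name) in 0-based
#' half-open coordinates; the spike-in fragment count and sample ID live in
#' a `<path>.spike.json` sidecar so a fragment file is self-describing.
#'
#' @param path BED file path.
#' @param genome chromosome sizes.
#' @param spikeCount spike count override; when `NULL` the sidecar is read.
#' @param sampleId sample label override.
#' @return `readFragmentBed`: a [FragmentSet-class].
#' @export
readFragmentBed <- function(path, genome, spikeCount = NULL, sampleId = NULL) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    sidecar <- paste0(path, ".spike.json")
    if (is.null(spikeCount) || is.null(sampleId)) {
        if (!file.exists(sidecar) && is.null(spikeCount))
            stop("no spike sidecar at ", sidecar, " and no spikeCount given")
        meta <- if (file.exists(sidecar))
            jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
        if (is.null(spikeCount)) spikeCount <- meta$spike_count
        if (is.null(sampleId))
            sampleId <- if (!is.null(meta$sample_id)) meta$sample_id
                        else sub("\\.bed$", "", basename(path))
    }
    FragmentSet(data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]]),
                spikeCount = spikeCount, sampleId = sampleId, genome = genome)
}

#' @rdname readFragmentBed
#' @param frags a [FragmentSet-class].
#' @return `writeFragmentBed`: the path, invisibly.
#' @export
writeFragmentBed <- function(frags, path) {
    gr <- fragments(frags)
    nm <- names(gr)
    if (is.null(nm)) nm <- sprintf("frag_%06d", seq_along(gr))
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr), name = nm)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
        list(sample_id = sampleId(frags), spike_count = spikeCount(frags)),
        paste0(path, ".spike.json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read a UCSC two-column chromosome-size file
#'
#' @param path TSV with columns chrom, length.
#' @return a [SyntheticGenome-class].
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    SyntheticGenome(stats::setNames(df[[2L]], df[[1L]]))
}

#' @rdname readChromSizes
#' @param genome a [SyntheticGenome-class].
#' @export
writeChromSizes <- function(genome, path) {
    cl <- chromLengths(genome)
    utils::write.table(data.frame(names(cl), unname(cl)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}
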