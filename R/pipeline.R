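# Pipeline orchestration: config-driven runs with file-based stage outputs,
# so each stage is independently inspectable and resumable.

#' Read and validate a run configuration
#'
#' The configuration is a single YAML file with a sample table (sample_id,
#' condition, fragments path, spike_count), a chromosome-size file, a
#' promoter BED, optional expression and torsion paths, and parameters.
#' Exactly one condition must be designated as the control.
#'
#' @param path YAML file path.
#' @return Validated config list (paths resolved relative to the YAML's
#'   directory).
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p) if (is.null(p) || file.exists(p)) p
                           else file.path(base, p)
    cfg$chrom_sizes <- resolve(cfg$chrom_sizes)
    cfg$promoters <- resolve(cfg$promoters)
    cfg$expression <- resolve(cfg$expression)
    cfg$torsion <- resolve(cfg$torsion)
    for (i in seq_along(cfg$samples))
        cfg$samples[[i]]$fragments <- resolve(cfg$samples[[i]]$fragments)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from `yaml::read_yaml`).
#' @export
validateRunConfig <- function(cfg) {
    defaults <- list(bin_size = 10, flank = 2500, sum_upstream = 100,
                     sum_downstream = 500, distance_threshold = 2000,
                     k = 3, spike_constant = 10000, outlier_sds = 64,
                     torsion_window = 200, seed = 1L)
    cfg$params <- utils::modifyList(defaults,
                                    if (is.null(cfg$params)) list()
                                    else cfg$params)
    if (any(unlist(cfg$params[names(cfg$params) != "seed"]) <= 0))
        stop("config error: all parameters must be positive")
    if (is.null(cfg$samples) || !length(cfg$samples))
        stop("config error: no samples")
    conds <- vapply(cfg$samples, function(s) s$condition, character(1))
    if (is.null(cfg$control_condition))
        stop("config error: control_condition not designated")
    if (sum(unique(conds) == cfg$control_condition) != 1L ||
        !cfg$control_condition %in% conds)
        stop("config error: exactly one control condition must be present")
    for (s in cfg$samples) {
        if (is.null(s$spike_count) || s$spike_count <= 0)
            stop("config error: sample ", s$sample_id,
                 " has no positive spike_count")
        if (!file.exists(s$fragments))
            stop("config error: missing fragment file ", s$fragments)
    }
    for (p in c("chrom_sizes", "promoters"))
        if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
            stop("config error: missing ", p, " file")
    cfg
}

#' Run the full analysis pipeline
#'
#' Stages: `tracks` (per-condition pooled pileup, spike calibration,
#' bedGraph export), `matrix` (TSS matrices per condition), `cluster`
#' (k-means on the control matrix, exported as BED), `spacing`
#' (nearest-upstream annotation), `distcurve` (promoter-proximal sums,
#' decile moving-median curves, switch points and threshold-group
#' comparisons against the control; torsion upstream sums with the SD
#' outlier filter when a torsion track is configured), and `profiles`
#' (per-bin fold-change profiles split by orientation, plus
#' expression-quintile stratification when expression is configured).
#' Stage outputs are files under `outDir`; a `summary.json` records every
#' parameter, input checksum and output path. Deterministic given the
#' config seed.
#'
#' @param config a config list ([readRunConfig()]) or YAML path.
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages to run (default: all, in order).
#' @return The summary list, invisibly; written to `outDir/summary.json`.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("tracks", "matrix", "cluster", "spacing",
                                   "distcurve", "profiles")) {
    cfg <- if (is.character(config)) readRunConfig(config)
           else validateRunConfig(config)
    p <- cfg$params
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logmsg <- function(...) message("[pipeline] ", ...)
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    genome <- readChromSizes(cfg$chrom_sizes)
    promoters <- readPromoterBed(cfg$promoters, genome)
    conds <- vapply(cfg$samples, function(s) s$condition, character(1))
    outputs <- list()
    tracksByCond <- list()

    logmsg("reading fragments for ", length(cfg$samples), " sample(s)")
    fsets <- lapply(cfg$samples, function(s)
        readFragmentBed(s$fragments, genome, spikeCount = s$spike_count,
                        sampleId = s$sample_id))
    for (cond in unique(conds)) {
        sel <- which(conds == cond)
        pooled <- do.call(c, lapply(fsets[sel], fragments))
        spikes <- sum(vapply(fsets[sel], spikeCount, numeric(1)))
        fs <- FragmentSet(pooled, spikeCount = spikes, sampleId = cond)
        raw <- fragmentPileup(fs)
        tracksByCond[[cond]] <- calibrateSpike(raw,
            spikeScaleFactor(spikes, p$spike_constant))
    }

    if ("tracks" %in% stages) runStage("tracks", {
        for (cond in names(tracksByCond)) {
            f <- file.path(outDir, paste0("track_", cond, ".bedGraph"))
            writeBedGraph(tracksByCond[[cond]], f)
            outputs[[paste0("track_", cond)]] <- f
        }
        logmsg("wrote ", length(tracksByCond), " calibrated track(s)")
    })

    mats <- lapply(tracksByCond, tssMatrix, promoters = promoters,
                   upstream = p$flank, downstream = p$flank,
                   binSize = p$bin_size)
    if ("matrix" %in% stages) runStage("matrix", {
        for (cond in names(mats)) {
            f <- file.path(outDir, paste0("matrix_", cond, ".tsv.gz"))
            writeCoverageMatrix(mats[[cond]], f)
            outputs[[paste0("matrix_", cond)]] <- f
        }
    })

    if ("cluster" %in% stages) runStage("cluster", {
        cl <- kmeansPromoters(mats[[cfg$control_condition]], k = p$k,
                              seed = p$seed)
        lab <- clusterLabels(cl)
        f <- file.path(outDir, "clusters.tsv")
        utils::write.table(data.frame(promoter_id = names(lab),
                                      cluster = as.character(lab)),
                           f, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs$clusters <- f
        fb <- file.path(outDir, "clusters.bed")
        o <- promoters[match(names(lab), mcols(promoters)$id)]
        df <- data.frame(chrom = as.character(seqnames(o)),
                         start = start(o) - 1L, end = start(o),
                         name = paste0(names(lab), "_", as.character(lab)),
                         score = 0L, strand = as.character(strand(o)))
        utils::write.table(df, fb, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        outputs$clusters_bed <- fb
        logmsg("clustered ", length(lab), " promoters into k = ", p$k)
    })

    spacing <- annotateSpacing(promoters)
    if ("spacing" %in% stages) runStage("spacing", {
        paths <- writeSpacing(spacing, promoters, outDir)
        outputs$spacing <- unname(paths["annotations"])
        outputs$spacing_divergent <- unname(paths["divergent"])
        outputs$spacing_tandem <- unname(paths["tandem"])
    })

    distances <- stats::setNames(spacing$distance, spacing$promoter_id)
    if ("distcurve" %in% stages) runStage("distcurve", {
        sums <- lapply(tracksByCond, regionSum, promoters = promoters,
                       upstream = p$sum_upstream,
                       downstream = p$sum_downstream)
        w <- decileWindow(sum(!is.na(distances)))
        curves <- lapply(sums, movingMedianCurve, distances = distances,
                         window = w)
        for (cond in names(curves)) {
            f <- file.path(outDir, paste0("distcurve_", cond, ".tsv"))
            utils::write.table(curves[[cond]], f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outputs[[paste0("distcurve_", cond)]] <- f
        }
        comp <- list()
        for (cond in setdiff(names(sums), cfg$control_condition)) {
            tg <- thresholdGroupMedians(sums[[cond]], distances,
                threshold = p$distance_threshold,
                control = sums[[cfg$control_condition]])
            comp[[cond]] <- list(
                medians = stats::setNames(as.list(tg$median), tg$stratum),
                control_medians = stats::setNames(as.list(tg$median_control),
                                                  tg$stratum),
                n = stats::setNames(as.list(tg$n), tg$stratum),
                U = stats::setNames(as.list(tg$W), tg$stratum),
                p_value = stats::setNames(as.list(tg$p_value), tg$stratum),
                switch_point = switchPoint(curves[[cond]],
                                           curves[[cfg$control_condition]]))
        }
        f <- file.path(outDir, "distance_comparisons.json")
        jsonlite::write_json(comp, f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
        outputs$distance_comparisons <- f
        if (!is.null(cfg$torsion)) {
            tor <- readBedGraph(cfg$torsion, genome)
            us <- upstreamSum(tor, promoters, window = p$torsion_window)
            filt <- filterOutliers(us, thresholdSds = p$outlier_sds)
            fo <- file.path(outDir, "torsion_outliers.tsv")
            utils::write.table(filt$report, fo, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outputs$torsion_outliers <- fo
            keep <- names(filt$values)
            wt <- decileWindow(sum(!is.na(distances[keep])))
            tc <- movingMedianCurve(filt$values, distances[keep],
                                    window = wt, statistic = "mean")
            ft <- file.path(outDir, "torsion_distcurve.tsv")
            utils::write.table(tc, ft, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outputs$torsion_distcurve <- ft
        }
    })

    if ("profiles" %in% stages) runStage("profiles", {
        proxMats <- lapply(tracksByCond, tssMatrix, promoters = promoters,
                           upstream = p$sum_upstream,
                           downstream = p$sum_downstream,
                           binSize = p$bin_size)
        ctrl <- proxMats[[cfg$control_condition]]
        oriIds <- split(spacing$promoter_id, spacing$orientation)
        for (cond in setdiff(names(proxMats), cfg$control_condition)) {
            profs <- list(all = foldChangeProfile(proxMats[[cond]], ctrl))
            for (ori in c("divergent", "tandem"))
                if (length(oriIds[[ori]]))
                    profs[[ori]] <- foldChangeProfile(proxMats[[cond]], ctrl,
                                                      subset = oriIds[[ori]])
            for (nm in names(profs)) {
                f <- file.path(outDir,
                               paste0("foldchange_", cond, "_", nm, ".tsv"))
                utils::write.table(profs[[nm]], f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                outputs[[paste0("foldchange_", cond, "_", nm)]] <- f
            }
            if (!is.null(cfg$expression)) {
                expr <- readExpression(cfg$expression)
                q <- expressionQuintiles(expr)
                fq <- file.path(outDir, "quintiles.tsv")
                utils::write.table(data.frame(promoter_id = names(q),
                                              quintile = as.character(q)),
                                   fq, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                outputs$quintiles <- fq
                strat <- suppressWarnings(
                    stratifiedProfiles(proxMats[[cond]], ctrl, q, spacing))
                for (nm in names(strat)) {
                    f <- file.path(outDir, paste0("stratified_", cond, "_",
                                                  nm, ".tsv"))
                    utils::write.table(strat[[nm]], f, sep = "\t",
                                       quote = FALSE, row.names = FALSE)
                    outputs[[paste0("stratified_", cond, "_", nm)]] <- f
                }
            }
        }
    })

    inputs <- c(cfg$chrom_sizes, cfg$promoters, cfg$expression, cfg$torsion,
                vapply(cfg$samples, function(s) s$fragments, character(1)))
    summary <- list(
        params = p,
        control_condition = cfg$control_condition,
        samples = cfg$samples,
        input_checksums = as.list(tools::md5sum(unlist(inputs))),
        output_checksums = as.list(tools::md5sum(unlist(outputs))),
        outputs = outputs)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}

#' One-command synthetic demo
#'
#' Generates a ~2,000-promoter two-chromosome dataset with four conditions —
#' control, a no-effect drug, a mildly boosting drug, and a strong
#' divergent-close booster (3x below 1 kb) — together with expression and a
#' torsion track, writes all inputs and a config, and runs the full
#' pipeline.
#'
#' @param seed integer seed controlling every random draw.
#' @param outDir output directory; inputs go to `outDir/inputs`, results to
#'   `outDir/results`.
#' @param nPromoters number of promoters (default 2,000).
#' @param nFragments expected fragments per condition (default 60,000).
#' @return The pipeline summary, invisibly.
#' @export
demoSynthetic <- function(seed = 1L, outDir = tempfile("cutac_demo"),
                          nPromoters = 2000, nFragments = 60000) {
    seed <- as.integer(seed)
    inDir <- file.path(outDir, "inputs")
    dir.create(inDir, showWarnings = FALSE, recursive = TRUE)
    genome <- SyntheticGenome(c(chrA = 3.2e6, chrB = 1.6e6))
    writeChromSizes(genome, file.path(inDir, "chrom.sizes"))
    promoters <- simulatePromoters(nPromoters, genome, seed = seed)
    writePromoterBed(promoters, file.path(inDir, "promoters.bed"))
    classes <- assignPromoterClasses(promoters, seed = seed + 1L)
    boosts <- c(control = 1, doxo_like = 1, actd_like = 1.35, acla_like = 3)
    samples <- list()
    for (i in seq_along(boosts)) {
        cond <- names(boosts)[i]
        em <- EffectModel(divergentCloseBoost = boosts[[cond]],
                          distanceCutoff = 1000,
                          classRates = c(25, 5, 1),
                          seed = seed + 10L + i)
        # depth-consistent spike-in: a condition whose true accessibility is
        # g-fold higher captures 1/g as many spike fragments at equal depth
        spike <- round(10000 / accessibilityGain(promoters, em, classes))
        fs <- simulateFragments(promoters, em, nTotal = nFragments,
                                spikeCount = spike,
                                sampleId = paste0(cond, "_1"),
                                classes = classes)
        f <- file.path(inDir, paste0(cond, ".bed"))
        writeFragmentBed(fs, f)
        samples[[i]] <- list(sample_id = paste0(cond, "_1"),
                             condition = cond, fragments = f,
                             spike_count = spike)
    }
    expr <- simulateExpression(promoters, seed = seed + 20L)
    writeExpression(expr, file.path(inDir, "expression.tsv"))
    tor <- simulateTorsionTrack(promoters, closePairEnrichment = 4,
                                seed = seed + 30L)
    writeBedGraph(tor, file.path(inDir, "torsion.bedGraph"))
    cfg <- list(samples = samples, control_condition = "control",
                chrom_sizes = file.path(inDir, "chrom.sizes"),
                promoters = file.path(inDir, "promoters.bed"),
                expression = file.path(inDir, "expression.tsv"),
                torsion = file.path(inDir, "torsion.bedGraph"),
                params = list(seed = seed))
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
    runPipeline(cfg, file.path(outDir, "results"))
}

#' Export a CoverageMatrix as gzipped TSV with a JSON header line
#'
#' First line: `# ` + JSON with bin size, flanks, bin stat and row count;
#' then one row per promoter (ID + per-bin values).
#'
#' @param matrix a [CoverageMatrix-class].
#' @param path output path (`.tsv.gz`).
#' @export
writeCoverageMatrix <- function(matrix, path) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    hdr <- jsonlite::toJSON(list(bin_size = binSize(matrix),
                                 upstream = matrix@upstream,
                                 downstream = matrix@downstream,
                                 bin_stat = matrix@binStat,
                                 n_rows = nrow(matrixValues(matrix))),
                            auto_unbox = TRUE)
    writeLines(paste0("# ", hdr), con)
    vals <- matrixValues(matrix)
    utils::write.table(data.frame(promoter_id = rownames(vals), vals,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname writeCoverageMatrix
#' @return `readCoverageMatrix`: the [CoverageMatrix-class].
#' @export
readCoverageMatrix <- function(path) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(con, n = 1L)))
    df <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(vals) <- list(df[[1L]], NULL)
    new("CoverageMatrix", values = vals,
        binSize = as.integer(hdr$bin_size),
        upstream = as.integer(hdr$upstream),
        downstream = as.integer(hdr$downstream), binStat = hdr$bin_stat)
}
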