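# Control-file front end and the per-marker parallel pipeline: read data,
# build units, distance matrix, Ward clustering, origin priors, then
# per-marker EM + statistic + bootstrap across a worker pool, writing one
# TSV row per input marker.  Per-marker RNG streams are a pure function of
# (seed, marker index), so output is byte-identical for any worker count.

.CONTROL_KEYS <- c("input", "format", "subpopulations", "threads", "nodes",
                   "bootstraps", "seed", "out", "counted_allele", "tol",
                   "max_iter", "epsilon")

#' Construct a pipeline run configuration
#'
#' @param input Path prefix of the PLINK dataset (without extension).
#' @param out Path of the results TSV.
#' @param K Number of subpopulations for the clustering step (>= 1).
#' @param format `"text"`, `"binary"`, or `"auto"` (detect from files).
#' @param threads Worker count (>= 1); never changes the results.
#' @param B Bootstrap replicates (>= 2).
#' @param seed Global integer seed.
#' @param countedAllele Counted-allele policy, see [readPlinkText()].
#' @param tol,maxIter EM controls.
#' @param epsilon Origin-prior smoothing.
#' @return A `caplRunConfig` list.
#' @export
caplRunConfig <- function(input, out, K, format = "auto", threads = 1L,
                          B = 200L, seed = 1L, countedAllele = "auto",
                          tol = 1e-6, maxIter = 50L, epsilon = 0.01) {
    K <- as.integer(K); threads <- as.integer(threads); B <- as.integer(B)
    if (is.na(K) || K < 1L) stop("parameter error: subpopulations must be >= 1")
    if (is.na(threads) || threads < 1L)
        stop("parameter error: threads must be >= 1")
    if (is.na(B) || B < 2L) stop("parameter error: bootstraps must be >= 2")
    if (!format %in% c("auto", "text", "binary"))
        stop("parameter error: format must be text, binary or auto")
    cfg <- list(input = input, out = out, K = K, format = format,
                threads = threads, B = B, seed = as.integer(seed),
                countedAllele = countedAllele, tol = tol,
                maxIter = as.integer(maxIter), epsilon = epsilon)
    class(cfg) <- "caplRunConfig"
    cfg
}

#' Parse a key=value control file
#'
#' Lines hold `key = value` pairs; keys are case-insensitive; `#` starts a
#' comment.  Recognised keys: `input`, `format`, `subpopulations`,
#' `threads`, `nodes` (accepted, ignored with a warning — a single-machine
#' worker pool replaces cluster deployment), `bootstraps`, `seed`, `out`,
#' `counted_allele`, `tol`, `max_iter`, `epsilon`.  `input`,
#' `subpopulations` and `out` are required.
#'
#' @param path Control file path.
#' @return A `caplRunConfig` (see [caplRunConfig()]).
#' @export
parseControlFile <- function(path) {
    if (!file.exists(path)) stop("control file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    vals <- list()
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        if (!grepl("=", ln, fixed = TRUE))
            stop(sprintf("control file parse error at line %d: expected key=value",
                         i))
        key <- tolower(trimws(sub("=.*$", "", ln)))
        val <- trimws(sub("^[^=]*=", "", ln))
        if (!key %in% .CONTROL_KEYS)
            stop(sprintf("control file error at line %d: unknown key '%s'",
                         i, key))
        vals[[key]] <- val
    }
    missing <- setdiff(c("input", "subpopulations", "out"), names(vals))
    if (length(missing))
        stop("control file error: missing required key(s): ",
             paste(missing, collapse = ", "))
    if (!is.null(vals$nodes))
        warning("control file key 'nodes' is ignored (single-machine worker",
                " pool)")
    num <- function(key, default) if (is.null(vals[[key]])) default else
        as.numeric(vals[[key]])
    caplRunConfig(
        input = vals$input, out = vals$out,
        K = num("subpopulations", NA),
        format = if (is.null(vals$format)) "auto" else tolower(vals$format),
        threads = num("threads", 1), B = num("bootstraps", 200),
        seed = num("seed", 1),
        countedAllele = if (is.null(vals$counted_allele)) "auto" else
            tolower(vals$counted_allele),
        tol = num("tol", 1e-6), maxIter = num("max_iter", 50),
        epsilon = num("epsilon", 0.01))
}

#' Write a run configuration as a control file
#'
#' Round-trips through [parseControlFile()].
#'
#' @param config A `caplRunConfig`.
#' @param path Output path.
#' @export
writeControlFile <- function(config, path) {
    writeLines(c(
        paste("input =", config$input),
        paste("format =", config$format),
        paste("subpopulations =", config$K),
        paste("threads =", config$threads),
        paste("bootstraps =", config$B),
        paste("seed =", config$seed),
        paste("out =", config$out),
        paste("counted_allele =", config$countedAllele),
        paste("tol =", format(config$tol, digits = 15)),
        paste("max_iter =", config$maxIter),
        paste("epsilon =", format(config$epsilon, digits = 15))), path)
    invisible(path)
}

#' Partition marker indices evenly across workers
#'
#' Contiguous ranges whose sizes differ by at most one and whose
#' concatenation is `1..M` in order.
#'
#' @param M Number of markers.
#' @param workers Worker count (>= 1); ranges beyond `M` come back empty.
#' @return List of integer index vectors.
#' @examples
#' lengths(partitionMarkers(10, 3))  # 4 3 3
#' @export
partitionMarkers <- function(M, workers) {
    stopifnot(workers >= 1L)
    sizes <- rep(M %/% workers, workers)
    extra <- M %% workers
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    lapply(seq_len(workers), function(w)
        if (sizes[w] == 0L) integer(0) else starts[w]:ends[w])
}

# per-marker substream seed: pure function of (global seed, marker index),
# kept below 2^31
.markerSeed <- function(seed, m) {
    as.integer((as.double(seed %% 65536L) * 32749 + as.double(m) * 7919) %%
               2147483647) + 1L
}

#' Analyse every marker of a study with the CAPL test
#'
#' The programmatic core of the pipeline: clusters once on the full sample
#' (when `K > 1`), then runs the per-marker EM, statistic and bootstrap,
#' markers distributed evenly over `threads` forked workers.  Rows come
#' back in input marker order whatever the worker count.
#'
#' @param study A [CaplStudy-class].
#' @param K Number of subpopulations.
#' @param threads Worker count.
#' @param B,seed,epsilon,tol,maxIter See [caplMarkerTest()].
#' @param verbose Log stage timings to stderr.
#' @return A `data.frame` with one row per marker: `CHR`, `SNP`, `BP`,
#'   `A1`, `A2`, `N_FAM_USED`, `P_HAT_1..K`, `Z0`, `Z1`, `Z2`, `EM_ITER`,
#'   `T`, `BOOT_SD`, `Z`, `P`, `STATUS`, plus attribute `"labels"` with
#'   the full-sample cluster assignment.
#' @export
caplAnalyze <- function(study, K = 1L, threads = 1L, B = 200L, seed = 1L,
                        epsilon = 0.01, tol = 1e-6, maxIter = 50L,
                        verbose = TRUE) {
    say <- function(fmt, ...) if (verbose)
        message(sprintf(paste0("[capl] ", fmt), ...))
    units <- familyUnits(study)
    g <- genotypes(study)
    mk <- markerInfo(study)
    M <- nrow(g)
    K <- as.integer(K)

    if (M == 0L) {
        res <- data.frame(CHR = character(0), SNP = character(0),
                          BP = integer(0), A1 = character(0),
                          A2 = character(0), N_FAM_USED = integer(0),
                          stringsAsFactors = FALSE)
        for (k in seq_len(K)) res[[sprintf("P_HAT_%d", k)]] <- numeric(0)
        for (cn in c("Z0", "Z1", "Z2")) res[[cn]] <- numeric(0)
        res$EM_ITER <- integer(0)
        for (cn in c("T", "BOOT_SD", "Z", "P")) res[[cn]] <- numeric(0)
        res$STATUS <- character(0)
        attr(res, "labels") <- rep(1L, ncol(g))
        return(res)
    }

    labels <- rep(1L, ncol(g)); d <- NULL
    if (K > 1L) {
        t0 <- Sys.time()
        d <- ibsDistanceMatrix(study)$d
        say("distance matrix: %.2fs", as.numeric(Sys.time() - t0, "secs"))
        t0 <- Sys.time()
        labels <- wardCluster(d, K)
        say("Ward clustering (K=%d): %.2fs", K,
            as.numeric(Sys.time() - t0, "secs"))
    }

    oneMarker <- function(m) {
        if (isTRUE(mk$multiallelic[m])) {
            row <- caplMarkerTest(units, rep(NA_integer_, ncol(g)),
                                  labels, d, K, B = B, seed = 1L)
            row$status <- "untestable"
            return(row)
        }
        caplMarkerTest(units, g[m, ], labels, d, K, B = B,
                       seed = .markerSeed(seed, m), epsilon = epsilon,
                       tol = tol, maxIter = maxIter)
    }

    t0 <- Sys.time()
    chunks <- partitionMarkers(M, threads)
    runChunk <- function(idx) lapply(idx, oneMarker)
    rowLists <- if (threads > 1L)
        parallel::mclapply(chunks, runChunk, mc.cores = threads)
    else lapply(chunks, runChunk)
    rows <- do.call(c, rowLists)
    say("%d marker(s) analysed on %d worker(s): %.2fs", M, threads,
        as.numeric(Sys.time() - t0, "secs"))

    pHat <- do.call(rbind, lapply(rows, function(r)
        matrix(r$pHat[[1L]], nrow = 1L)))
    colnames(pHat) <- sprintf("P_HAT_%d", seq_len(K))
    flat <- do.call(rbind, lapply(rows, function(r)
        r[, setdiff(names(r), "pHat"), drop = FALSE]))
    res <- data.frame(CHR = mk$chromosome, SNP = mk$id, BP = mk$position,
                      A1 = mk$allele1, A2 = mk$allele2,
                      N_FAM_USED = flat$nFamUsed,
                      stringsAsFactors = FALSE)
    res <- cbind(res, as.data.frame(pHat))
    res$Z0 <- flat$z0; res$Z1 <- flat$z1; res$Z2 <- flat$z2
    res$EM_ITER <- flat$emIterations
    res$T <- flat$T; res$BOOT_SD <- flat$bootSd
    res$Z <- flat$zScore; res$P <- flat$pValue
    res$STATUS <- flat$status
    attr(res, "labels") <- labels
    res
}

#' Write a results table as TSV
#'
#' @param results Data frame from [caplAnalyze()].
#' @param path Output path.
#' @export
writeCaplResults <- function(results, path) {
    write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Stages, in order: read data, build family units, distance matrix, Ward
#' clustering, origin priors, per-marker (EM, T, bootstrap) in parallel,
#' results written sorted by input marker order.  For a fixed
#' configuration (seed included) the output file is byte-identical
#' regardless of `threads`.
#'
#' @param config A `caplRunConfig` or the path of a control file.
#' @param dumpClusters Optional path for a diagnostic TSV of (individual,
#'   cluster label).
#' @param verbose Log stage timings to stderr.
#' @return The results `data.frame`, invisibly.
#' @export
caplPipeline <- function(config, dumpClusters = NULL, verbose = TRUE) {
    if (is.character(config)) config <- parseControlFile(config)
    stopifnot(inherits(config, "caplRunConfig"))
    fmt <- config$format
    if (fmt == "auto")
        fmt <- if (file.exists(paste0(config$input, ".bed"))) "binary" else
            "text"
    study <- if (fmt == "binary")
        readPlinkBinary(paste0(config$input, ".bed"),
                        paste0(config$input, ".bim"),
                        paste0(config$input, ".fam"),
                        countedAllele = config$countedAllele)
    else
        readPlinkText(paste0(config$input, ".ped"),
                      paste0(config$input, ".map"),
                      countedAllele = config$countedAllele)
    res <- caplAnalyze(study, K = config$K, threads = config$threads,
                       B = config$B, seed = config$seed,
                       epsilon = config$epsilon, tol = config$tol,
                       maxIter = config$maxIter, verbose = verbose)
    if (!is.null(dumpClusters)) {
        lab <- data.frame(IID = individualInfo(study)$individualId,
                          LABEL = attr(res, "labels"))
        write.table(lab, dumpClusters, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    writeCaplResults(res, config$out)
    invisible(res)
}
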