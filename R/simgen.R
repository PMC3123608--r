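# Synthetic stratified-pedigree generator: Balding-Nichols subpopulation
# allele frequencies, HWE founders, Mendelian transmission with tracked
# gametes (true IBD), penetrance-based affection, and design-pattern
# ascertainment by rejection sampling.  Doubles as the fixture factory for
# the whole test suite; exposes true subpopulation labels, true
# frequencies and true sib-pair IBD states.

#' Configuration for the synthetic-data generator
#'
#' @param counts `data.frame` with one row per subpopulation and integer
#'   columns `cases`, `controls`, `triads`, `multiplex`.
#' @param nMarkers Number of biallelic markers.
#' @param fst Balding-Nichols drift parameter per subpopulation (recycled);
#'   0 means no drift from the ancestral frequency.
#' @param freqRange Range of the uniform ancestral frequency draw.
#' @param causalIndex Marker index of the disease locus.
#' @param grr Multiplicative genotype relative risk of the counted allele
#'   (1 = null).
#' @param baselinePenetrance P(affected | 0 copies), in (0, 1).
#' @param mode `"linked"`: the analysed marker at `causalIndex` is itself
#'   the disease locus (complete linkage).  `"unlinked"`: the disease locus
#'   segregates independently of every analysed marker (a hidden locus with
#'   ancestral frequency `causalFreq`).
#' @param causalFreq Ancestral frequency of the hidden disease locus
#'   (unlinked mode only).
#' @param seed Integer seed.
#' @return A `caplSimConfig` list.
#' @seealso [scenarioOneConfig()], [scenarioTwoConfig()], [simulateStudy()]
#' @export
simConfig <- function(counts = data.frame(cases = 50, controls = 50,
                                          triads = 25, multiplex = 25),
                      nMarkers = 200L, fst = 0.1, freqRange = c(0.1, 0.9),
                      causalIndex = 1L, grr = 1, baselinePenetrance = 0.1,
                      mode = c("linked", "unlinked"), causalFreq = 0.3,
                      seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(all(unlist(counts) >= 0), nMarkers >= 1L,
              baselinePenetrance > 0, baselinePenetrance < 1, grr > 0,
              causalIndex >= 1L, causalIndex <= nMarkers,
              all(fst >= 0), all(fst < 1))
    cfg <- list(counts = counts, nSubpops = nrow(counts),
                fst = rep_len(fst, nrow(counts)), nMarkers = as.integer(nMarkers),
                freqRange = freqRange, causalIndex = as.integer(causalIndex),
                grr = grr, baselinePenetrance = baselinePenetrance,
                mode = mode, causalFreq = causalFreq,
                seed = as.integer(seed))
    class(cfg) <- "caplSimConfig"
    cfg
}

#' Single-population scenario: cases, controls, triads and multiplex
#' families
#'
#' One homogeneous population with 2000 cases, 2000 controls, 750 triads
#' and 750 multiplex families (parents and two affected siblings).
#'
#' @param nMarkers Number of markers (desk-scale default 500).
#' @param scale Multiplier applied to all unit counts (e.g. `scale = 0.1`
#'   for a miniature with the same design mix).
#' @param ... Passed to [simConfig()].
#' @export
scenarioOneConfig <- function(nMarkers = 500L, scale = 1, ...) {
    simConfig(counts = data.frame(cases = round(2000 * scale),
                                  controls = round(2000 * scale),
                                  triads = round(750 * scale),
                                  multiplex = round(750 * scale)),
              nMarkers = nMarkers, fst = 0, ...)
}

#' Two-population scenario with design imbalance across populations
#'
#' 1000 cases, 1000 controls and 750 triad families from one population and
#' 1000 cases, 1000 controls and 750 multiplex families from a second,
#' drifted population — the stratified configuration in which an
#' uncorrected analysis inflates type-I error.
#'
#' @param nMarkers Number of markers.
#' @param fst Drift between the two populations (default 0.1).
#' @param scale Multiplier applied to all unit counts.
#' @param ... Passed to [simConfig()].
#' @export
scenarioTwoConfig <- function(nMarkers = 500L, fst = 0.1, scale = 1, ...) {
    simConfig(counts = data.frame(
                  cases = round(c(1000, 1000) * scale),
                  controls = round(c(1000, 1000) * scale),
                  triads = round(c(750, 0) * scale),
                  multiplex = round(c(0, 750) * scale)),
              nMarkers = nMarkers, fst = fst, ...)
}

#' Draw per-marker subpopulation allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on `freqRange`; each subpopulation's
#' frequency is Beta(p0 (1-F)/F, (1-p0)(1-F)/F) around the ancestral p0
#' (drawn directly as p0 when F = 0), clamped to \[0.01, 0.99\].
#'
#' @param config A `caplSimConfig`.
#' @return `list(ancestral = <length-M>, p = <M x K matrix>)`.
#' @export
drawSubpopFreqs <- function(config) {
    M <- config$nMarkers; K <- config$nSubpops
    p0 <- runif(M, config$freqRange[1L], config$freqRange[2L])
    p <- matrix(0, M, K)
    for (k in seq_len(K)) {
        F <- config$fst[k]
        p[, k] <- if (F <= 0) p0 else
            rbeta(M, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    }
    p <- pmin(pmax(p, 0.01), 0.99)
    list(ancestral = p0, p = p)
}

# penetrance of genotype g under the multiplicative model
.penetrance <- function(g, f0, grr) pmin(f0 * grr^g, 1)

# vectorised rejection sampler for singleton individuals of a given
# phenotype at the causal locus
.sampleSingletons <- function(n, pc, f0, grr, wantAffected, maxTries = 1e6) {
    out <- integer(0)
    tried <- 0
    while (length(out) < n) {
        batch <- max(2L * (n - length(out)), 64L)
        tried <- tried + batch
        if (tried > maxTries)
            stop("ascertainment failure; consider a larger penetrance")
        g <- rbinom(batch, 2L, pc)
        aff <- runif(batch) < .penetrance(g, f0, grr)
        keep <- if (wantAffected) aff else !aff
        out <- c(out, g[keep])
    }
    out[seq_len(n)]
}

# vectorised rejection sampler for families at the causal locus.
# Returns parents' genotypes, children's genotypes and, for two-child
# designs, the true IBD state from the gamete coins.
.sampleFamilies <- function(n, nChild, pc, f0, grr, maxTries = 1e6) {
    gf <- gm <- integer(0)
    gc <- matrix(integer(0), 0L, nChild)
    ibd <- integer(0)
    tried <- 0
    while (length(gf) < n) {
        batch <- max(2L * (n - length(gf)), 64L)
        tried <- tried + batch
        if (tried > maxTries)
            stop("ascertainment failure; consider a larger penetrance")
        bgf <- rbinom(batch, 2L, pc)
        bgm <- rbinom(batch, 2L, pc)
        # labelled alleles: allele slot 1 of a heterozygote carries the
        # counted allele; coins pick the transmitted slot
        cf <- matrix(sample(1:2, batch * nChild, TRUE), batch, nChild)
        cm <- matrix(sample(1:2, batch * nChild, TRUE), batch, nChild)
        tf <- (bgf == 2L) + (bgf == 1L) * (cf == 1L)
        tm <- (bgm == 2L) + (bgm == 1L) * (cm == 1L)
        bg <- tf + tm
        aff <- matrix(runif(batch * nChild) <
                      .penetrance(bg, f0, grr), batch, nChild)
        keep <- rowSums(aff) == nChild
        gf <- c(gf, bgf[keep]); gm <- c(gm, bgm[keep])
        gc <- rbind(gc, bg[keep, , drop = FALSE])
        if (nChild == 2L)
            ibd <- c(ibd, ((cf[, 1L] == cf[, 2L]) +
                           (cm[, 1L] == cm[, 2L]))[keep])
    }
    keep <- seq_len(n)
    list(gf = gf[keep], gm = gm[keep], gc = gc[keep, , drop = FALSE],
         ibd = if (nChild == 2L) ibd[keep] else integer(0))
}

# HWE genotypes for founders at all non-causal markers: n x M
.founderMarkers <- function(n, pk) {
    matrix(rbinom(n * length(pk), 2L, rep(pk, each = n)), n, length(pk))
}

# Mendelian transmissions from parent genotype matrices (children x M)
.childMarkers <- function(GF, GM) {
    tf <- (GF == 2L) + (GF == 1L) * (runif(length(GF)) < 0.5)
    tm <- (GM == 2L) + (GM == 1L) * (runif(length(GM)) < 0.5)
    matrix(as.integer(tf + tm), nrow(GF), ncol(GF))
}

#' Simulate a stratified family/case-control study
#'
#' Draws subpopulation allele frequencies, then per subpopulation generates
#' unrelated cases and controls, triads (parents + one affected child) and
#' multiplex families (parents + two affected children), ascertained by
#' rejection sampling at the disease locus.  Parents' phenotypes are drawn
#' from the penetrance model but play no role in ascertainment.
#'
#' @param config A `caplSimConfig` from [simConfig()].
#' @param seed Optional override of `config$seed`.
#' @return A [CaplStudy-class]; `metadata(x)$truth` holds the true
#'   subpopulation labels, allele frequencies, causal index, the sib-pair
#'   IBD states of multiplex families at the disease locus, and the
#'   generating parameters.
#' @export
simulateStudy <- function(config, seed = NULL) {
    stopifnot(inherits(config, "caplSimConfig"))
    set.seed(if (is.null(seed)) config$seed else as.integer(seed))
    M <- config$nMarkers; K <- config$nSubpops
    fr <- drawSubpopFreqs(config)
    f0 <- config$baselinePenetrance; grr <- config$grr
    linked <- config$mode == "linked"
    ci <- config$causalIndex

    # hidden disease-locus frequencies for unlinked mode
    pcK <- if (linked) fr$p[ci, ] else {
        p0 <- config$causalFreq
        vapply(seq_len(K), function(k) {
            F <- config$fst[k]
            v <- if (F <= 0) p0 else
                rbeta(1L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
            min(max(v, 0.01), 0.99)
        }, numeric(1))
    }

    ind <- list(); genoBlocks <- list(); subpop <- integer(0)
    ibdTab <- data.frame(familyId = character(0), ibd = integer(0),
                         stringsAsFactors = FALSE)
    famCounter <- 0L

    addInd <- function(fid, iid, pat, mat, sex, aff) {
        data.frame(familyId = fid, individualId = iid,
                   fatherId = pat, motherId = mat, sex = sex,
                   phenotype = ifelse(aff, "affected", "unaffected"),
                   stringsAsFactors = FALSE)
    }

    for (k in seq_len(K)) {
        pk <- fr$p[, k]; pc <- pcK[k]
        cnt <- config$counts[k, ]

        # unrelated cases and controls
        for (design in c("case", "control")) {
            n <- as.integer(if (design == "case") cnt$cases else cnt$controls)
            if (n == 0L) next
            gCausal <- .sampleSingletons(n, pc, f0, grr, design == "case")
            G <- .founderMarkers(n, pk)
            if (linked) G[, ci] <- gCausal
            fid <- sprintf("S%d%s%d", k, toupper(substr(design, 1L, 2L)),
                           seq_len(n))
            ind[[length(ind) + 1L]] <- addInd(fid, fid, NA, NA, "unknown",
                                              design == "case")
            genoBlocks[[length(genoBlocks) + 1L]] <- G
            subpop <- c(subpop, rep(k, n))
        }

        # families
        for (design in c("triads", "multiplex")) {
            n <- as.integer(cnt[[design]])
            if (n == 0L) next
            nChild <- if (design == "triads") 1L else 2L
            fam <- .sampleFamilies(n, nChild, pc, f0, grr)
            fids <- sprintf("S%dF%d", k, famCounter + seq_len(n))
            famCounter <- famCounter + n
            GF <- .founderMarkers(n, pk); GM <- .founderMarkers(n, pk)
            if (linked) { GF[, ci] <- fam$gf; GM[, ci] <- fam$gm }
            affF <- runif(n) < .penetrance(if (linked) GF[, ci] else
                rbinom(n, 2L, pc), f0, grr)
            affM <- runif(n) < .penetrance(if (linked) GM[, ci] else
                rbinom(n, 2L, pc), f0, grr)
            ind[[length(ind) + 1L]] <- addInd(fids, paste0(fids, "_F"),
                                              NA, NA, "male", affF)
            genoBlocks[[length(genoBlocks) + 1L]] <- GF
            ind[[length(ind) + 1L]] <- addInd(fids, paste0(fids, "_M"),
                                              NA, NA, "female", affM)
            genoBlocks[[length(genoBlocks) + 1L]] <- GM
            for (ch in seq_len(nChild)) {
                GC <- .childMarkers(GF, GM)
                if (linked) GC[, ci] <- fam$gc[, ch]
                ind[[length(ind) + 1L]] <- addInd(
                    fids, sprintf("%s_C%d", fids, ch),
                    paste0(fids, "_F"), paste0(fids, "_M"), "unknown", TRUE)
                genoBlocks[[length(genoBlocks) + 1L]] <- GC
            }
            subpop <- c(subpop, rep(k, n * (2L + nChild)))
            if (nChild == 2L)
                ibdTab <- rbind(ibdTab, data.frame(
                    familyId = fids, ibd = fam$ibd, stringsAsFactors = FALSE))
        }
    }

    individuals <- do.call(rbind, ind)
    geno <- t(do.call(rbind, genoBlocks))          # markers x individuals
    markers <- data.frame(
        id = sprintf("snp%d", seq_len(M)),
        chromosome = "1",
        position = seq_len(M) * 1000L,
        allele1 = "A", allele2 = "C",
        multiallelic = FALSE, stringsAsFactors = FALSE)

    truth <- list(subpop = subpop, freqs = fr$p, ancestral = fr$ancestral,
                  causalIndex = if (linked) ci else NA_integer_,
                  causalFreqs = pcK, ibdCausal = ibdTab,
                  grr = grr, baselinePenetrance = f0, mode = config$mode)
    CaplStudy(geno, markers, individuals, metadata = list(truth = truth))
}

#' Write a study as PLINK 1 text or binary files
#'
#' Text: `.ped`/`.map` with counted-allele homozygotes written as `A A`,
#' heterozygotes `A C`, other homozygotes `C C` (alleles from the marker
#' table) and missing as `0 0`.  Binary: SNP-major `.bed` (magic `6C 1B`,
#' mode `01`) with `.bim`/`.fam`, A1 = counted allele.
#'
#' @param study A [CaplStudy-class].
#' @param prefix Output path prefix.
#' @param format `"text"` or `"binary"`.
#' @return The written file paths, invisibly.
#' @export
writePlink <- function(study, prefix, format = c("text", "binary")) {
    format <- match.arg(format)
    g <- genotypes(study)
    mk <- markerInfo(study)
    ii <- individualInfo(study)
    M <- nrow(mk); N <- nrow(ii)
    sexCode <- c(male = "1", female = "2", unknown = "0")[ii$sex]
    phenoCode <- c(affected = "2", unaffected = "1", missing = "0")[
        ii$phenotype]
    famCols <- cbind(ii$familyId, ii$individualId,
                     ifelse(is.na(ii$fatherId), "0", ii$fatherId),
                     ifelse(is.na(ii$motherId), "0", ii$motherId),
                     sexCode, phenoCode)

    if (format == "text") {
        pedPath <- paste0(prefix, ".ped"); mapPath <- paste0(prefix, ".map")
        writeLines(if (M) paste(mk$chromosome, mk$id, 0, mk$position)
                   else character(0), mapPath)
        alleleStr <- matrix("0 0", nrow = M, ncol = N)
        for (m in seq_len(M)) {
            lut <- c(paste(mk$allele2[m], mk$allele2[m]),
                     paste(mk$allele1[m], mk$allele2[m]),
                     paste(mk$allele1[m], mk$allele1[m]))
            gm <- g[m, ]
            ok <- !is.na(gm)
            alleleStr[m, ok] <- lut[gm[ok] + 1L]
        }
        rows <- vapply(seq_len(N), function(i)
            paste(c(famCols[i, ], alleleStr[, i]), collapse = " "),
            character(1))
        writeLines(rows, pedPath)
        return(invisible(c(pedPath, mapPath)))
    }

    bedPath <- paste0(prefix, ".bed"); bimPath <- paste0(prefix, ".bim")
    famPath <- paste0(prefix, ".fam")
    writeLines(if (M) paste(mk$chromosome, mk$id, 0, mk$position,
                            mk$allele1, mk$allele2, sep = "\t")
               else character(0), bimPath)
    writeLines(if (N) apply(famCols, 1L, paste, collapse = " ")
               else character(0), famPath)
    # 2-bit codes: 0 copies of A1 -> 11, 1 -> 10, 2 -> 00, missing -> 01
    codeLut <- c(3L, 2L, 0L)
    bpm <- ceiling(N / 4)
    body <- raw(0)
    if (M > 0L) {
        codes <- matrix(1L, nrow = M, ncol = 4L * bpm)
        ok <- !is.na(g)
        codes[, seq_len(N)][ok] <- codeLut[g[ok] + 1L]
        if (N < 4L * bpm) codes[, (N + 1L):(4L * bpm)] <- 0L
        shift <- rep(c(1L, 4L, 16L, 64L), bpm)
        bytes <- matrix(0L, nrow = M, ncol = bpm)
        for (s in 1:4)
            bytes <- bytes + codes[, seq(s, 4L * bpm, by = 4L),
                                   drop = FALSE] * shift[s]
        body <- as.raw(t(bytes))
    }
    writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), body), bedPath)
    invisible(c(bedPath, bimPath, famPath))
}
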