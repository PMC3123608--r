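# PLINK 1 text/binary readers, pedigree validation and nuclear family-unit
# construction.  Genotypes are recoded everywhere as copies of the "counted"
# allele: by default PLINK A1 for binary input and the lexicographically
# smaller observed allele for text input.

.PHENO_LEVELS <- c("affected", "unaffected", "missing")

.decodePhenotype <- function(x) {
    out <- rep("missing", length(x))
    out[x == "2"] <- "affected"
    out[x == "1"] <- "unaffected"
    bad <- !(x %in% c("2", "1", "0", "-9"))
    if (any(bad))
        warning(sum(bad), " unrecognised phenotype code(s) treated as missing")
    out
}

.decodeSex <- function(x) {
    out <- rep("unknown", length(x))
    out[x == "1"] <- "male"
    out[x == "2"] <- "female"
    out
}

.individualsFrame <- function(fam) {
    data.frame(
        familyId = as.character(fam[[1L]]),
        individualId = as.character(fam[[2L]]),
        fatherId = ifelse(fam[[3L]] %in% c("0", ""), NA_character_,
                          as.character(fam[[3L]])),
        motherId = ifelse(fam[[4L]] %in% c("0", ""), NA_character_,
                          as.character(fam[[4L]])),
        sex = .decodeSex(as.character(fam[[5L]])),
        phenotype = .decodePhenotype(as.character(fam[[6L]])),
        stringsAsFactors = FALSE)
}

#' Read a PLINK 1 text dataset (.ped / .map)
#'
#' Parses the classic whitespace-delimited PLINK text pair and recodes
#' genotypes as counts of the counted allele.  Markers showing more than two
#' distinct alleles are flagged `multiallelic` and their genotypes set
#' missing, with a warning.  A half-missing allele pair makes the whole
#' genotype missing (PLINK convention).
#'
#' @param pedPath,mapPath Paths to the `.ped` and `.map` files.
#' @param countedAllele `"auto"` (text default: lexicographically smaller
#'   observed allele), `"lexmin"`, or `"lexmax"`.
#' @return A [CaplStudy-class] with family units built by
#'   [buildFamilyUnits()].
#' @seealso [readPlinkBinary()], [writePlink()]
#' @export
readPlinkText <- function(pedPath, mapPath,
                          countedAllele = c("auto", "lexmin", "lexmax")) {
    countedAllele <- match.arg(countedAllele)
    if (countedAllele == "auto") countedAllele <- "lexmin"
    if (!file.exists(pedPath)) stop("ped file not found: ", pedPath)
    if (!file.exists(mapPath)) stop("map file not found: ", mapPath)

    map <- if (file.size(mapPath) == 0)
        data.frame(V1 = character(0), V2 = character(0), V3 = character(0),
                   V4 = character(0)) else
        data.table::fread(mapPath, header = FALSE, colClasses = "character",
                          data.table = FALSE)
    if (nrow(map) && ncol(map) < 4L)
        stop("map file must have 4 columns (CHR SNP CM BP)")
    M <- nrow(map)

    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    lens <- lengths(toks)
    expLen <- 6L + 2L * M
    if (any(lens != expLen))
        stop(sprintf("ped parse error: line %d has %d fields, expected %d",
                     which(lens != expLen)[1L], lens[lens != expLen][1L],
                     expLen))
    N <- length(toks)
    tok <- if (N) matrix(unlist(toks), nrow = N, byrow = TRUE) else
        matrix(character(0), nrow = 0L, ncol = expLen)

    fam <- as.data.frame(tok[, 1:6, drop = FALSE], stringsAsFactors = FALSE)
    individuals <- .individualsFrame(fam)

    geno <- matrix(NA_integer_, nrow = M, ncol = N)
    allele1 <- character(M); allele2 <- character(M)
    multi <- logical(M)
    for (m in seq_len(M)) {
        a <- tok[, 5L + 2L * m]
        b <- tok[, 6L + 2L * m]
        miss <- a == "0" | b == "0"
        obs <- sort(unique(c(a[!miss], b[!miss])))
        if (length(obs) > 2L) {
            multi[m] <- TRUE
            allele1[m] <- obs[1L]; allele2[m] <- obs[2L]
            next
        }
        if (length(obs) == 0L) { allele1[m] <- "?"; allele2[m] <- "0"; next }
        if (length(obs) == 1L) obs <- c(obs, "0")
        if (countedAllele == "lexmax") obs <- rev(obs)
        allele1[m] <- obs[1L]; allele2[m] <- obs[2L]
        g <- (a == obs[1L]) + (b == obs[1L])
        g[miss] <- NA_integer_
        geno[m, ] <- as.integer(g)
    }
    if (any(multi))
        warning(sum(multi), " multiallelic marker(s) excluded (genotypes set",
                " missing): ", paste(map[multi, 2L], collapse = ", "))

    markers <- data.frame(
        id = as.character(map[[2L]]),
        chromosome = if (M) as.character(map[[1L]]) else character(0),
        position = if (M) as.integer(map[[4L]]) else integer(0),
        allele1 = allele1, allele2 = allele2,
        multiallelic = multi, stringsAsFactors = FALSE)

    CaplStudy(geno, markers, individuals)
}

# 256 x 4 lookup: PLINK 1 2-bit codes within a byte, low bits first.
# 00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies.
.BED_DECODE <- local({
    two <- c(2L, NA_integer_, 1L, 0L)
    dec <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
    for (byte in 0:255)
        dec[byte + 1L, ] <- two[bitwAnd(bitwShiftR(byte, c(0L, 2L, 4L, 6L)),
                                        3L) + 1L]
    dec
})

#' Read a PLINK 1 binary dataset (.bed / .bim / .fam)
#'
#' Decodes SNP-major PLINK 1 `.bed` data (magic bytes `6C 1B`, mode `01`).
#' By default the counted allele is the `.bim` A1 allele, so a dataset read
#' here and its text export read with [readPlinkText()] yield identical
#' genotype matrices when A1 is the lexicographically smaller allele.
#'
#' @param bedPath,bimPath,famPath Paths to the three files.
#' @param countedAllele `"auto"` (binary default: A1), `"lexmin"`, or
#'   `"lexmax"`.
#' @return A [CaplStudy-class].
#' @export
readPlinkBinary <- function(bedPath, bimPath, famPath,
                            countedAllele = c("auto", "lexmin", "lexmax")) {
    countedAllele <- match.arg(countedAllele)
    for (p in c(bedPath, bimPath, famPath))
        if (!file.exists(p)) stop("file not found: ", p)

    bim <- if (file.size(bimPath) == 0)
        as.data.frame(matrix(character(0), 0L, 6L)) else
        data.table::fread(bimPath, header = FALSE, colClasses = "character",
                          data.table = FALSE)
    if (nrow(bim) && ncol(bim) != 6L)
        stop("bim file must have 6 columns (CHR SNP CM BP A1 A2)")
    famTab <- if (file.size(famPath) == 0)
        as.data.frame(matrix(character(0), 0L, 6L)) else
        data.table::fread(famPath, header = FALSE,
                          colClasses = "character", data.table = FALSE)
    individuals <- .individualsFrame(famTab)
    M <- nrow(bim); N <- nrow(individuals)

    raw <- readBin(bedPath, what = "raw", n = file.info(bedPath)$size)
    if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
        stop("bed format error: missing PLINK magic bytes 6C 1B")
    if (raw[3L] != as.raw(0x01))
        stop("bed format error: only SNP-major mode (01) is supported")
    bpm <- ceiling(N / 4)
    body <- raw[-(1:3)]
    if (length(body) != M * bpm)
        stop(sprintf("bed truncation error: %d body bytes, expected %d",
                     length(body), M * bpm))

    geno <- matrix(NA_integer_, nrow = M, ncol = N)
    if (M > 0L && N > 0L) {
        bytes <- matrix(as.integer(body), nrow = bpm)  # bytes x markers
        for (m in seq_len(M)) {
            g4 <- .BED_DECODE[bytes[, m] + 1L, , drop = FALSE]
            geno[m, ] <- as.vector(t(g4))[seq_len(N)]
        }
    }

    allele1 <- if (M) as.character(bim[[5L]]) else character(0)
    allele2 <- if (M) as.character(bim[[6L]]) else character(0)
    flip <- rep(FALSE, M)
    if (countedAllele == "lexmin") flip <- allele2 < allele1 & allele2 != "0"
    if (countedAllele == "lexmax") flip <- allele1 < allele2 & allele1 != "0"
    if (any(flip)) {
        geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
        tmp <- allele1[flip]; allele1[flip] <- allele2[flip]
        allele2[flip] <- tmp
    }

    markers <- data.frame(
        id = if (M) as.character(bim[[2L]]) else character(0),
        chromosome = if (M) as.character(bim[[1L]]) else character(0),
        position = if (M) as.integer(bim[[4L]]) else integer(0),
        allele1 = allele1, allele2 = allele2,
        multiallelic = rep(FALSE, M), stringsAsFactors = FALSE)

    CaplStudy(geno, markers, individuals)
}

#' Decompose a pedigree into nuclear family units
#'
#' Siblings sharing the same (possibly absent) parent pair within a family
#' form one [FamilyUnit-class]; founders with no offspring in the data
#' become case/control singletons according to their phenotype (missing
#' phenotype: excluded with a warning).  Parents' own phenotypes never make
#' them siblings — parents only condition the unit.
#'
#' @param individuals `data.frame` as in [CaplStudy()] (`familyId`,
#'   `individualId`, `fatherId`, `motherId`, `sex`, `phenotype`).
#' @return `list(units = <list of FamilyUnit>, exclusions =
#'   data.frame(individualId, reason))`.
#' @export
buildFamilyUnits <- function(individuals) {
    N <- nrow(individuals)
    key <- paste(individuals$familyId, individuals$individualId, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated (familyId, individualId) pair(s)")
    idx <- seq_len(N)
    names(idx) <- key

    resolve <- function(fid, pid) {
        out <- rep(NA_integer_, length(pid))
        has <- !is.na(pid)
        out[has] <- idx[paste(fid[has], pid[has], sep = "\r")]
        out
    }
    fatherIdx <- resolve(individuals$familyId, individuals$fatherId)
    motherIdx <- resolve(individuals$familyId, individuals$motherId)
    unresolved <- (!is.na(individuals$fatherId) & is.na(fatherIdx)) |
        (!is.na(individuals$motherId) & is.na(motherIdx))
    if (any(unresolved))
        warning(sum(unresolved), " individual(s) with parent id(s) not in the",
                " data; treated as absent parents")

    # pedigree cycle check: an individual must never be its own ancestor
    for (i in seq_len(N)) {
        frontier <- c(fatherIdx[i], motherIdx[i])
        frontier <- frontier[!is.na(frontier)]
        depth <- 0L
        while (length(frontier)) {
            if (i %in% frontier || (depth <- depth + 1L) > N)
                stop("pedigree cycle involving individual ",
                     individuals$individualId[i])
            frontier <- unique(c(fatherIdx[frontier], motherIdx[frontier]))
            frontier <- frontier[!is.na(frontier)]
        }
    }

    isParent <- idx %in% c(fatherIdx, motherIdx)
    hasParent <- !is.na(fatherIdx) | !is.na(motherIdx)

    units <- list()
    exclusions <- data.frame(individualId = character(0), reason = character(0),
                             stringsAsFactors = FALSE)

    # sibships keyed by family + named parent pair (named, even if absent
    # from the data, so half-sibs never collapse into one unit)
    sibKey <- paste(individuals$familyId,
                    ifelse(is.na(individuals$fatherId), "<none>",
                           individuals$fatherId),
                    ifelse(is.na(individuals$motherId), "<none>",
                           individuals$motherId), sep = "\r")
    for (grp in split(idx[hasParent], sibKey[hasParent])) {
        grp <- grp[order(individuals$individualId[grp])]
        fi <- unique(fatherIdx[grp]); mi <- unique(motherIdx[grp])
        fi <- fi[1L]; mi <- mi[1L]
        aff <- grp[individuals$phenotype[grp] == "affected"]
        una <- grp[individuals$phenotype[grp] != "affected"]
        tag <- if (!is.na(fi) && !is.na(mi) && length(aff) == 1L &&
                   length(una) == 0L) "triad"
               else if (!is.na(fi) && !is.na(mi) && length(aff) >= 2L)
                   "multiplex"
               else "other"
        units[[length(units) + 1L]] <- FamilyUnit(
            individuals$familyId[grp[1L]], father = fi, mother = mi,
            affectedSibs = aff, unaffectedSibs = una, designTag = tag)
    }

    singles <- idx[!hasParent & !isParent]
    for (i in singles) {
        ph <- individuals$phenotype[i]
        if (ph == "missing") {
            exclusions <- rbind(exclusions, data.frame(
                individualId = individuals$individualId[i],
                reason = "founder with missing phenotype",
                stringsAsFactors = FALSE))
            next
        }
        tag <- if (ph == "affected") "case_singleton" else "control_singleton"
        units[[length(units) + 1L]] <- FamilyUnit(
            individuals$familyId[i],
            affectedSibs = if (ph == "affected") i else integer(0),
            unaffectedSibs = if (ph == "affected") integer(0) else i,
            designTag = tag)
    }
    if (nrow(exclusions))
        warning(nrow(exclusions), " individual(s) excluded: ",
                paste(unique(exclusions$reason), collapse = "; "))
    list(units = units, exclusions = exclusions)
}

#' Mendelian consistency of a family unit at one marker
#'
#' `TRUE` iff every non-missing sibling genotype is producible from the
#' non-missing parental genotypes by Mendelian transmission.  Missing
#' genotypes never create an inconsistency.
#'
#' @param unit A [FamilyUnit-class].
#' @param markerGenotypes Integer vector of genotypes for one marker,
#'   indexed by study column (0/1/2/NA).
#' @return Logical scalar.
#' @examples
#' u <- FamilyUnit("F1", father = 1L, mother = 2L, affectedSibs = 3L)
#' mendelConsistent(u, c(2L, 2L, 1L))  # AA x AA cannot yield Aa
#' @export
mendelConsistent <- function(unit, markerGenotypes) {
    gf <- if (is.na(unit@father)) NA_integer_ else markerGenotypes[unit@father]
    gm <- if (is.na(unit@mother)) NA_integer_ else markerGenotypes[unit@mother]
    kids <- c(unit@affectedSibs, unit@unaffectedSibs)
    gk <- markerGenotypes[kids]
    gk <- gk[!is.na(gk)]
    if (!length(gk)) return(TRUE)
    if (!is.na(gf) && !is.na(gm)) {
        m <- matingTypeIndex(gf, gm)
        return(all(offspringProb(gk, m) > 0))
    }
    ok <- TRUE
    for (gp in c(gf, gm)) {
        if (is.na(gp)) next
        ok <- ok && !any((gp == 2L & gk == 0L) | (gp == 0L & gk == 2L))
    }
    ok
}
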