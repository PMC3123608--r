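#' FamilyUnit: a nuclear analysis unit
#'
#' A nuclear family as analysed by the CAPL statistic: an optional father and
#' mother plus one or more siblings, all stored as column indices into the
#' genotype matrix of the owning [CaplStudy].  Unrelated cases and controls
#' are folded into the same framework as single-sib units with both parents
#' absent.
#'
#' @slot familyId Character family identifier.
#' @slot father,mother Integer column index of the parent, or `NA` when the
#'   parent is absent from the data.
#' @slot affectedSibs Integer column indices of affected siblings, sorted by
#'   individual identifier (the first two are the ones modelled exactly by
#'   the sib-pair IBD likelihood).
#' @slot unaffectedSibs Integer column indices of unaffected siblings (kept
#'   for bookkeeping and origin priors; not used in the likelihood).
#' @slot designTag One of `"triad"`, `"multiplex"`, `"case_singleton"`,
#'   `"control_singleton"`, `"other"`.
#'
#' @seealso [buildFamilyUnits()]
#' @export
setClass("FamilyUnit",
    representation(
        familyId = "character",
        father = "integer",
        mother = "integer",
        affectedSibs = "integer",
        unaffectedSibs = "integer",
        designTag = "character"
    ),
    prototype(
        familyId = NA_character_,
        father = NA_integer_,
        mother = NA_integer_,
        affectedSibs = integer(0),
        unaffectedSibs = integer(0),
        designTag = "other"
    )
)

setValidity("FamilyUnit", function(object) {
    msgs <- character(0)
    if (length(object@father) != 1L || length(object@mother) != 1L)
        msgs <- c(msgs, "father and mother must each be a single index or NA")
    nSib <- length(object@affectedSibs) + length(object@unaffectedSibs)
    if (nSib < 1L)
        msgs <- c(msgs, "a family unit must contain at least one sibling")
    if (!object@designTag %in%
        c("triad", "multiplex", "case_singleton", "control_singleton", "other"))
        msgs <- c(msgs, "unknown designTag")
    if (object@designTag %in% c("case_singleton", "control_singleton")) {
        if (!is.na(object@father) || !is.na(object@mother) || nSib != 1L)
            msgs <- c(msgs,
                "singleton units must have both parents absent and one sibling")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FamilyUnit
#'
#' @param familyId Family identifier.
#' @param father,mother Column index of the parent in the study, or `NA`.
#' @param affectedSibs,unaffectedSibs Integer column indices.
#' @param designTag Design label; see [FamilyUnit-class].
#' @return A [FamilyUnit-class] object.
#' @examples
#' FamilyUnit("F1", father = 1L, mother = 2L, affectedSibs = 3L,
#'            designTag = "triad")
#' @export
FamilyUnit <- function(familyId, father = NA_integer_, mother = NA_integer_,
                       affectedSibs = integer(0),
                       unaffectedSibs = integer(0), designTag = "other") {
    new("FamilyUnit", familyId = as.character(familyId),
        father = as.integer(father), mother = as.integer(mother),
        affectedSibs = as.integer(affectedSibs),
        unaffectedSibs = as.integer(unaffectedSibs),
        designTag = designTag)
}

#' @describeIn FamilyUnit-class All member column indices of the unit
#'   (parents first, `NA`s dropped).
#' @param unit A [FamilyUnit-class].
#' @export
unitMembers <- function(unit) {
    idx <- c(unit@father, unit@mother, unit@affectedSibs, unit@unaffectedSibs)
    idx[!is.na(idx)]
}

setMethod("show", "FamilyUnit", function(object) {
    cat(sprintf("FamilyUnit %s [%s]: father=%s mother=%s, %d affected, %d unaffected sib(s)\n",
        object@familyId, object@designTag,
        ifelse(is.na(object@father), "-", object@father),
        ifelse(is.na(object@mother), "-", object@mother),
        length(object@affectedSibs), length(object@unaffectedSibs)))
})

#' CaplStudy: genotypes, marker/individual annotation and family units
#'
#' The central data container: a [SummarizedExperiment::SummarizedExperiment]
#' whose single `"geno"` assay holds the markers x individuals genotype
#' matrix (integer 0/1/2 copies of the counted allele, `NA` missing), with
#' marker metadata as `rowData`, individual/pedigree metadata as `colData`,
#' and the nuclear [FamilyUnit-class] decomposition in the `familyUnits`
#' slot.  Individuals excluded from every unit are recorded with a reason in
#' `metadata(x)$exclusions`.
#'
#' @slot familyUnits List of [FamilyUnit-class] objects whose indices refer
#'   to columns of the assay.
#'
#' @seealso [readPlinkText()], [readPlinkBinary()], [simulateStudy()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("CaplStudy",
    contains = "SummarizedExperiment",
    representation(familyUnits = "list")
)

setValidity("CaplStudy", function(object) {
    msgs <- character(0)
    if (!"geno" %in% SummarizedExperiment::assayNames(object))
        return("assay 'geno' is required")
    g <- SummarizedExperiment::assay(object, "geno")
    if (!all(g[!is.na(g)] %in% 0:2))
        msgs <- c(msgs, "genotype entries must be 0, 1, 2 or NA")
    need <- c("id", "chromosome", "position", "allele1", "allele2")
    if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
        msgs <- c(msgs, paste("rowData must contain:",
                              paste(need, collapse = ", ")))
    needI <- c("familyId", "individualId", "fatherId", "motherId",
               "sex", "phenotype")
    if (!all(needI %in% colnames(SummarizedExperiment::colData(object))))
        msgs <- c(msgs, paste("colData must contain:",
                              paste(needI, collapse = ", ")))
    nInd <- ncol(object)
    for (u in object@familyUnits) {
        if (!is(u, "FamilyUnit")) { msgs <- c(msgs, "familyUnits must hold FamilyUnit objects"); break }
        if (any(unitMembers(u) > nInd))
            { msgs <- c(msgs, "family unit index out of range"); break }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a CaplStudy
#'
#' @param genotypes Integer matrix, markers x individuals, entries 0/1/2/NA
#'   counting copies of each marker's counted allele (`allele1`).
#' @param markers `data.frame` with columns `id`, `chromosome`, `position`,
#'   `allele1`, `allele2` (one row per marker).
#' @param individuals `data.frame` with columns `familyId`, `individualId`,
#'   `fatherId`, `motherId`, `sex`, `phenotype` (one row per individual).
#'   `phenotype` uses `"affected"`, `"unaffected"`, `"missing"`.
#' @param familyUnits Optional list of [FamilyUnit-class]; computed with
#'   [buildFamilyUnits()] when omitted.
#' @param exclusions Optional `data.frame(individualId, reason)` of
#'   individuals not assigned to any unit.
#' @param metadata Extra metadata list entries.
#' @return A [CaplStudy-class].
#' @export
CaplStudy <- function(genotypes, markers, individuals, familyUnits = NULL,
                      exclusions = NULL, metadata = list()) {
    stopifnot(nrow(genotypes) == nrow(markers),
              ncol(genotypes) == nrow(individuals))
    mode(genotypes) <- "integer"
    rownames(genotypes) <- markers$id
    colnames(genotypes) <- individuals$individualId
    if (is.null(familyUnits)) {
        bu <- buildFamilyUnits(individuals)
        familyUnits <- bu$units
        if (is.null(exclusions)) exclusions <- bu$exclusions
    }
    if (is.null(exclusions))
        exclusions <- data.frame(individualId = character(0),
                                 reason = character(0))
    md <- c(list(exclusions = exclusions), metadata)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(geno = genotypes),
        rowData = S4Vectors::DataFrame(markers),
        colData = S4Vectors::DataFrame(individuals),
        metadata = md)
    new("CaplStudy", se, familyUnits = familyUnits)
}

#' @rdname CaplStudy-class
#' @param x,object A [CaplStudy-class].
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname CaplStudy-class
#' @export
setMethod("genotypes", "CaplStudy", function(x)
    SummarizedExperiment::assay(x, "geno"))

#' @rdname CaplStudy-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname CaplStudy-class
#' @export
setMethod("markerInfo", "CaplStudy", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname CaplStudy-class
#' @export
setGeneric("individualInfo", function(x) standardGeneric("individualInfo"))

#' @rdname CaplStudy-class
#' @export
setMethod("individualInfo", "CaplStudy", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname CaplStudy-class
#' @export
setGeneric("familyUnits", function(x) standardGeneric("familyUnits"))

#' @rdname CaplStudy-class
#' @export
setMethod("familyUnits", "CaplStudy", function(x) x@familyUnits)

setMethod("show", "CaplStudy", function(object) {
    tags <- vapply(object@familyUnits, function(u) u@designTag, character(1))
    cat(sprintf("CaplStudy: %d marker(s) x %d individual(s), %d family unit(s)\n",
        nrow(object), ncol(object), length(object@familyUnits)))
    if (length(tags)) {
        tab <- table(tags)
        cat("  units:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                              collapse = ", "), "\n")
    }
    ex <- S4Vectors::metadata(object)$exclusions
    if (!is.null(ex) && nrow(ex))
        cat(sprintf("  %d individual(s) excluded\n", nrow(ex)))
})
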