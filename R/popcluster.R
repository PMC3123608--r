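# Genome-wide identity-by-state distances, Ward clustering into K
# subpopulations, and per-family origin priors.

#' Pairwise allele-sharing (IBS) distance matrix
#'
#' For individuals i, j the distance is `1 - IBS(i,j) / 2` averaged over the
#' markers non-missing in both: `d(i,j) = 1 - sum_m s_m / (2 M_ij)` with
#' `s_m = 2 - |g_i - g_j|`.  Computed once over all markers and reused
#' (indexed) by every bootstrap replicate — resampling individuals never
#' changes their pairwise distances.
#'
#' @param x A [CaplStudy-class] or a markers x individuals genotype matrix
#'   (0/1/2/NA).
#' @return `list(d = <N x N symmetric matrix in [0,1]>, pairCounts = <N x N
#'   matrix of markers used per pair>)`.
#' @examples
#' g <- rbind(c(0L, 2L), c(1L, 1L))     # 2 markers, 2 individuals
#' ibsDistanceMatrix(g)$d
#' @export
ibsDistanceMatrix <- function(x) {
    g <- if (is(x, "CaplStudy")) genotypes(x) else x
    stopifnot(is.matrix(g))
    if (nrow(g) < 1L) stop("at least one marker is required")
    mode(g) <- "integer"
    res <- .ibsDistance(g)
    off <- res$pairCounts[upper.tri(res$pairCounts)]
    if (any(off == 0)) {
        bad <- which(res$pairCounts == 0 & upper.tri(res$pairCounts),
                     arr.ind = TRUE)[1L, ]
        stop(sprintf("individuals %d and %d share no non-missing marker",
                     bad[1L], bad[2L]))
    }
    dimnames(res$d) <- list(colnames(g), colnames(g))
    res
}

#' Ward agglomerative clustering cut at K clusters
#'
#' Agglomeration minimising Ward's criterion via the Lance-Williams
#' recurrence on squared dissimilarities (the "ward.D2" convention), with
#' merge ties broken towards the smallest index pair.  Implemented in C++
#' because the bootstrap re-clusters every replicate.
#'
#' @param d Symmetric dissimilarity matrix, or the list returned by
#'   [ibsDistanceMatrix()].
#' @param K Number of clusters, `1 <= K <= N`.
#' @return Integer vector of labels in `1..K` (numbered by first
#'   appearance); every cluster is non-empty.
#' @examples
#' pts <- c(0, 0.05, 0.1, 1, 1.05)
#' wardCluster(as.matrix(dist(pts)), 2)
#' @export
wardCluster <- function(d, K) {
    if (is.list(d) && !is.null(d$d)) d <- d$d
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    K <- as.integer(K)
    if (K < 1L || K > nrow(d))
        stop("K must be between 1 and the number of individuals")
    .wardLabels(d, K)
}

#' Per-family subpopulation origin priors from cluster labels
#'
#' Smoothed multinomial priors over the K subpopulations for each family
#' unit: `pi_ik = (c_ik + eps) / (c_i + K eps)` where `c_ik` counts the
#' unit's members assigned to cluster `k`.
#'
#' @param labels Integer cluster labels per individual (as from
#'   [wardCluster()]).
#' @param units List of [FamilyUnit-class] (indices into `labels`).
#' @param K Number of subpopulations.
#' @param epsilon Smoothing constant in (0, 0.5); keeps every origin
#'   strictly positive under hard cluster assignments.
#' @return Numeric `length(units) x K` matrix; rows sum to 1.
#' @export
familyOriginPriors <- function(labels, units, K, epsilon = 0.01) {
    K <- as.integer(K)
    stopifnot(K >= 1L, epsilon > 0, epsilon < 0.5)
    pri <- matrix(0, nrow = length(units), ncol = K)
    warned <- FALSE
    for (i in seq_along(units)) {
        mem <- unitMembers(units[[i]])
        lab <- labels[mem]
        lab <- lab[!is.na(lab)]
        if (!length(lab)) {
            pri[i, ] <- 1 / K
            warned <- TRUE
            next
        }
        ck <- tabulate(lab, nbins = K)
        pri[i, ] <- (ck + epsilon) / (sum(ck) + K * epsilon)
    }
    if (warned)
        warning("unit(s) with no labelled members received a uniform prior")
    pri
}
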