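# The CAPL statistic: per-family observed-vs-expected counted-allele
# contributions, their sum T, and a bootstrap variance that repeats the
# clustering and the EM in every replicate.

#' Observed-minus-expected contribution of one family
#'
#' `c_i = X_i - n_i * sum_{k,m,j} w(k,m,j) e(m)`, where `X_i` is the total
#' counted-allele copies among the unit's genotyped affected siblings,
#' `n_i` their number, and `e(m)` the null-expected copies per offspring
#' for mating type `m`.  Control singletons have `n_i = 0` and contribute 0.
#'
#' @param unit A [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker.
#' @param weights Posterior weights from [familyWeights()].
#' @return Numeric contribution.
#' @export
familyContribution <- function(unit, markerGenotypes, weights) {
    sg <- markerGenotypes[unit@affectedSibs]
    sg <- sg[!is.na(sg)]
    X <- sum(sg); n <- length(sg)
    if (n == 0L) return(0)
    eTerm <- sum(apply(weights$w, 2L, sum) * .MT_E)
    X - n * eTerm
}

#' The CAPL statistic T at one marker
#'
#' Sum of family contributions over the units includable at the marker,
#' computed from a converged EM fit.
#'
#' @param emRun Result of [runEm()].
#' @return Numeric T (under the null of no linkage or no association its
#'   expectation is 0).
#' @export
caplT <- function(emRun) {
    md <- emRun$markerData
    inc <- emRun$posteriors$included
    sum((md$X - md$nSib * emRun$posteriors$expE)[inc])
}

# priors for a (possibly resampled) selection of units, from member labels
.selPriors <- function(md, sel, labels, K, epsilon) {
    lens <- md$memberLens[sel]
    grp <- rep(seq_along(sel), lens)
    ck <- matrix(0, length(sel), K)
    tab <- rowsum(diag(K)[labels, , drop = FALSE], grp)
    ck[as.integer(rownames(tab)), ] <- tab
    (ck + epsilon) / (rowSums(ck) + K * epsilon)
}

# one bootstrap replicate: resample units, re-cluster their members on the
# cached distance matrix, rebuild priors, re-run the EM, return T*
.bootstrapOnce <- function(md, nU, d, g, K, epsilon, tol, maxIter) {
    sel <- sample.int(nU, nU, replace = TRUE)
    mem <- unlist(md$members[sel], use.names = FALSE)
    labs <- if (K == 1L) rep(1L, length(mem)) else
        wardCluster(d[mem, mem, drop = FALSE], K)
    pri <- .selPriors(md, sel, labs, K, epsilon)
    p0 <- .emInit(g[mem], labs, K)
    fit <- .emFit(md, sel, pri, p0 = p0, tol = tol, maxIter = maxIter)
    if (is.null(fit)) stop("no includable family in replicate")
    sum((md$X[sel] - md$nSib[sel] * fit$expE)[fit$included])
}

#' Bootstrap standard deviation of the CAPL statistic
#'
#' Family units are resampled with replacement as whole units (singletons
#' included, one pooled frame).  Each replicate re-derives cluster
#' assignments by Ward clustering of the resampled individuals on the
#' cached distance matrix (entries indexed, never recomputed), rebuilds the
#' origin priors, re-runs the EM at the marker and recomputes `T`.
#' Replicates in which the EM fails are dropped and counted.
#'
#' @param units List of [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker.
#' @param d Full-sample distance matrix from [ibsDistanceMatrix()] (`$d`
#'   or the matrix itself); may be `NULL` when `K = 1`.
#' @param K Number of subpopulations.
#' @param B Number of bootstrap replicates (>= 2; typically 200-1000).
#' @param seed Integer seed; with a fixed seed the result is identical
#'   across runs and worker counts.
#' @param epsilon Prior smoothing constant.
#' @param tol,maxIter EM controls.
#' @return `list(bootSd, replicatesUsed, replicatesFailed, degenerate)`.
#' @export
bootstrapVariance <- function(units, markerGenotypes, d = NULL, K = 1L,
                              B = 200L, seed = 1L, epsilon = 0.01,
                              tol = 1e-6, maxIter = 50L) {
    stopifnot(B >= 2L)
    if (is.list(d) && !is.null(d$d)) d <- d$d
    if (K > 1L && is.null(d))
        stop("a distance matrix is required when K > 1")
    md <- .markerData(units, markerGenotypes)
    nU <- length(units)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(as.integer(seed))
    Tb <- rep(NA_real_, B)
    for (b in seq_len(B)) {
        Tb[b] <- tryCatch(
            .bootstrapOnce(md, nU, d, markerGenotypes, K, epsilon, tol,
                           maxIter),
            error = function(e) NA_real_)
    }
    used <- sum(!is.na(Tb))
    failed <- B - used
    bootSd <- if (used >= 2L) sd(Tb[!is.na(Tb)]) else NA_real_
    list(bootSd = bootSd, replicatesUsed = used, replicatesFailed = failed,
         degenerate = failed > 0.2 * B ||
             (!is.na(bootSd) && bootSd == 0))
}

#' Full CAPL test of one marker
#'
#' Runs Mendelian screening, the EM, the statistic `T`, the bootstrap SD,
#' and the two-sided normal p-value `p = 2 (1 - Phi(|T / sd|))`.
#'
#' @param units List of [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker.
#' @param labels Per-individual cluster labels (full sample).
#' @param d Cached distance matrix (may be `NULL` when `K = 1`).
#' @param K Number of subpopulations.
#' @param B Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param epsilon Prior smoothing constant.
#' @param tol,maxIter EM controls.
#' @return A one-row `data.frame` with columns `nFamUsed`, `pHat` (list
#'   column of length-K estimates), `z0`, `z1`, `z2`, `emIterations`, `T`,
#'   `bootSd`, `zScore`, `pValue`, `bootUsed`, `status` (one of `ok`,
#'   `monomorphic`, `untestable`, `degenerate_variance`).
#' @export
caplMarkerTest <- function(units, markerGenotypes, labels = NULL, d = NULL,
                           K = 1L, B = 200L, seed = 1L, epsilon = 0.01,
                           tol = 1e-6, maxIter = 50L) {
    if (is.null(labels)) labels <- rep(1L, length(markerGenotypes))
    out <- data.frame(nFamUsed = NA_integer_, z0 = NA_real_, z1 = NA_real_,
                      z2 = NA_real_, emIterations = NA_integer_,
                      T = NA_real_, bootSd = NA_real_, zScore = NA_real_,
                      pValue = NA_real_, bootUsed = NA_integer_,
                      status = "untestable", stringsAsFactors = FALSE)
    out$pHat <- list(rep(NA_real_, K))

    gObs <- markerGenotypes[!is.na(markerGenotypes)]
    if (length(gObs) == 0L || length(unique(gObs)) == 1L) {
        out$status <- "monomorphic"
        return(out)
    }
    pri <- familyOriginPriors(labels, units, K, epsilon)
    em <- runEm(units, markerGenotypes, pri, K, labels = labels, tol = tol,
                maxIter = maxIter)
    if (is.null(em)) return(out)
    out$nFamUsed <- sum(em$posteriors$included)
    out$pHat <- list(em$model$p)
    out$z0 <- em$model$z[1L]; out$z1 <- em$model$z[2L]
    out$z2 <- em$model$z[3L]
    out$emIterations <- em$model$nIterations
    out$T <- caplT(em)

    bv <- bootstrapVariance(units, markerGenotypes, d = d, K = K, B = B,
                            seed = seed, epsilon = epsilon, tol = tol,
                            maxIter = maxIter)
    out$bootSd <- bv$bootSd
    out$bootUsed <- bv$replicatesUsed
    if (bv$degenerate || is.na(bv$bootSd) || bv$bootSd == 0) {
        out$status <- "degenerate_variance"
        return(out)
    }
    out$zScore <- out$T / out$bootSd
    out$pValue <- 2 * (1 - pnorm(abs(out$zScore)))
    out$status <- "ok"
    out
}
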