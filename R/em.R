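# Per-marker EM over subpopulation allele frequencies p_k, affected-sib-pair
# IBD parameters z = (z0, z1, z2) and family probabilities of origin,
# integrating over missing parental mating types.
#
# Internally each family unit is reduced, once per marker, to a fixed data
# vector A over (mating type m, IBD state j): A = compat(m) * P(sib data |
# m, j).  The EM weight is then w(k, m, j) = pi_ik * P(m | p_k) * z_j * A,
# so every iteration is a handful of small matrix products; the bootstrap
# reuses the same A rows for resampled units.

.Z_NULL <- c(0.25, 0.5, 0.25)
.P_CLAMP <- c(1e-6, 1 - 1e-6)

# Ordered-assignment compatibility factor of each mating type with the
# observed parental genotypes: (#ordered assignments of m consistent with
# the observations) / (#ordered assignments of m).  Reduces to a 0/1
# indicator when both parents are observed or both are missing; with one
# observed parent it removes the double-counting of heterogeneous mating
# types so the implied conditional over the other parent is exactly HWE.
.compatFactor <- function(gf, gm) {
    out <- numeric(6L)
    for (m in 1:6) {
        g1 <- .MT[m, 1L]; g2 <- .MT[m, 2L]
        ords <- if (g1 == g2) list(c(g1, g2)) else
            list(c(g1, g2), c(g2, g1))
        cons <- vapply(ords, function(o)
            (is.na(gf) || o[1L] == gf) && (is.na(gm) || o[2L] == gm),
            logical(1))
        out[m] <- sum(cons) / length(ords)
    }
    out
}

# Per-marker reduction of the family units.  Returns parallel vectors over
# units: type (0 dropped / 1 no-j-dimension / 2 sib-pair), row index into
# A1 / A2, X (observed counted-allele copies in affected sibs), nSib
# (number of genotyped affected sibs), plus the A matrices and member lists.
.markerData <- function(units, g) {
    nU <- length(units)
    type <- integer(nU); row <- integer(nU)
    X <- numeric(nU); nSib <- integer(nU)
    reason <- character(nU)
    A1 <- list(); A2 <- list()
    members <- lapply(units, unitMembers)
    for (i in seq_len(nU)) {
        u <- units[[i]]
        if (!mendelConsistent(u, g)) {
            reason[i] <- "mendel_inconsistent"
            next
        }
        gf <- if (is.na(u@father)) NA_integer_ else g[u@father]
        gm <- if (is.na(u@mother)) NA_integer_ else g[u@mother]
        compat <- .compatFactor(gf, gm)
        sg <- g[u@affectedSibs]
        sg <- sg[!is.na(sg)]
        X[i] <- sum(sg); nSib[i] <- length(sg)
        lik <- sg[seq_len(min(2L, length(sg)))]
        if (length(sg) > 2L)
            reason[i] <- "extra_affected_sibs_ignored"
        # control singletons carry no statistic weight (X = n = 0) but their
        # genotype is data: it anchors the allele-frequency estimation
        if (u@designTag == "control_singleton") {
            cg <- g[u@unaffectedSibs[1L]]
            if (!is.na(cg)) lik <- cg
        }
        if (length(lik) == 2L) {
            a <- matrix(0, nrow = 6L, ncol = 3L)
            for (j in 0:2)
                a[, j + 1L] <- .SIB[[j + 1L]][lik[1L] + 1L, lik[2L] + 1L, ] *
                    compat
            if (all(a == 0)) { type[i] <- 0L; reason[i] <- "incompatible"; next }
            A2[[length(A2) + 1L]] <- as.vector(a)   # j-major blocks of 6
            type[i] <- 2L; row[i] <- length(A2)
        } else {
            a <- if (length(lik) == 1L) compat * .OFF[lik + 1L, ] else compat
            if (all(a == 0)) { type[i] <- 0L; reason[i] <- "incompatible"; next }
            A1[[length(A1) + 1L]] <- a
            type[i] <- 1L; row[i] <- length(A1)
        }
    }
    list(type = type, row = row, X = X, nSib = nSib, reason = reason,
         A1 = if (length(A1)) do.call(rbind, A1) else
             matrix(0, 0L, 6L),
         A2 = if (length(A2)) do.call(rbind, A2) else
             matrix(0, 0L, 18L),
         members = members,
         memberLens = lengths(members))
}

# One EM fit over a selection `sel` of unit indices (with repetitions under
# the bootstrap).  `priors` is aligned to `sel` (rows), p0 length K.
# Returns parameters, diagnostics and the per-selected-unit posterior
# expected offspring allele count (for the statistic) and origin matrix.
.emFit <- function(md, sel, priors, p0, z0 = .Z_NULL, tol = 1e-6,
                   maxIter = 50L, freezeZ = FALSE) {
    type <- md$type[sel]
    i1 <- which(type == 1L); i2 <- which(type == 2L)
    n1 <- length(i1); n2 <- length(i2)
    if (n1 + n2 == 0L) return(NULL)
    A1 <- md$A1[md$row[sel][i1], , drop = FALSE]
    A2 <- md$A2[md$row[sel][i2], , drop = FALSE]
    K <- length(p0)
    fit <- .emFitCpp(A1, A2, priors[i1, , drop = FALSE],
                     priors[i2, , drop = FALSE], p0, z0, tol,
                     as.integer(maxIter), freezeZ)
    expE <- rep(NA_real_, length(sel))
    origin <- matrix(NA_real_, length(sel), K)
    if (n1) { expE[i1] <- fit$expE1; origin[i1, ] <- fit$origin1 }
    if (n2) { expE[i2] <- fit$expE2; origin[i2, ] <- fit$origin2 }
    list(p = fit$p, z = fit$z, nIterations = fit$nIterations,
         converged = fit$converged,
         loglik = fit$loglikTrace[length(fit$loglikTrace)],
         loglikTrace = fit$loglikTrace,
         expE = expE, origin = origin,
         included = type > 0L)
}

# initial allele frequencies: per-cluster sample frequency among genotyped
# individuals hard-assigned to each cluster; overall frequency as fallback
.emInit <- function(g, labels, K) {
    overall <- mean(g, na.rm = TRUE) / 2
    if (!is.finite(overall)) overall <- 0.5
    p0 <- numeric(K)
    for (k in seq_len(K)) {
        gk <- g[!is.na(g) & labels == k]
        p0[k] <- if (length(gk)) mean(gk) / 2 else overall
    }
    pmin(pmax(p0, .P_CLAMP[1L]), .P_CLAMP[2L])
}

#' Posterior weights of one family over (subpopulation, mating type, IBD)
#'
#' The E-step kernel for a single family unit at one marker:
#' `w(k, m, j) proportional to pi_k P(m | p_k) compat(m) z_j P(sib data |
#' m, j)`, normalised over all states.  The IBD dimension is degenerate
#' (only `j = 0` carries weight 1-slot semantics) for units with fewer than
#' two genotyped affected sibs.  `compat(m)` is the ordered-assignment
#' consistency of `m` with any observed parental genotypes; with both
#' parents observed the weight is degenerate at the observed mating type.
#'
#' @param unit A [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker (study columns).
#' @param prior Numeric length-K origin prior for the unit (simplex).
#' @param p Numeric length-K subpopulation counted-allele frequencies.
#' @param z Length-3 IBD-sharing simplex.
#' @return `list(w = K x 6 x nJ array, origin = length-K simplex)`, or
#'   `NULL` (with a warning) when the configuration carries zero
#'   probability and the family is excluded at this marker.
#' @export
familyWeights <- function(unit, markerGenotypes, prior, p,
                          z = c(0.25, 0.5, 0.25)) {
    stopifnot(length(prior) == length(p))
    md <- .markerData(list(unit), markerGenotypes)
    if (md$type[1L] == 0L) {
        warning("family excluded at this marker: ", md$reason[1L])
        return(NULL)
    }
    K <- length(p)
    nJ <- if (md$type[1L] == 2L) 3L else 1L
    A <- if (nJ == 3L) matrix(md$A2[1L, ], 6L, 3L) else
        matrix(md$A1[1L, ], 6L, 1L)
    w <- array(0, dim = c(K, 6L, nJ))
    for (k in seq_len(K)) {
        MTk <- matingTypeProb(1:6, min(max(p[k], .P_CLAMP[1L]),
                                       .P_CLAMP[2L]))
        for (j in seq_len(nJ)) {
            zj <- if (nJ == 3L) z[j] else 1
            w[k, , j] <- prior[k] * MTk * zj * A[, j]
        }
    }
    tot <- sum(w)
    if (tot <= 0) {
        warning("family excluded at this marker: zero total weight")
        return(NULL)
    }
    w <- w / tot
    list(w = w, origin = apply(w, 1L, sum))
}

#' One E-step over all family units at a marker
#'
#' Computes per-family posterior weights under the current model and the
#' expected sufficient statistics: `Sp[k]` (posterior-expected parental
#' counted-allele copies assigned to subpopulation k), `N[k]`
#' (posterior-expected number of families of origin k), and `Sz[j]`
#' (posterior-expected count of sib pairs in IBD state j, two-affected-sib
#' units only).
#'
#' @param units List of [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker.
#' @param priors Units x K origin prior matrix (see
#'   [familyOriginPriors()]).
#' @param p,z Current model parameters.
#' @return `list(Sp, N, Sz, loglik, origin, expE, included)`; `Sz` is
#'   `NULL` when no two-affected-sib unit is present.
#' @export
emEStep <- function(units, markerGenotypes, priors, p,
                    z = c(0.25, 0.5, 0.25)) {
    md <- .markerData(units, markerGenotypes)
    if (all(md$type == 0L)) stop("no includable family at this marker")
    .emSuffStats(md, seq_along(units), priors, p, z)
}

# single E-pass returning sufficient statistics (used by emEStep and tests)
.emSuffStats <- function(md, sel, priors, p, z) {
    type <- md$type[sel]
    i1 <- which(type == 1L); i2 <- which(type == 2L)
    n1 <- length(i1); n2 <- length(i2)
    K <- length(p)
    A1 <- md$A1[md$row[sel][i1], , drop = FALSE]
    A2 <- md$A2[md$row[sel][i2], , drop = FALSE]
    pi1 <- priors[i1, , drop = FALSE]; pi2 <- priors[i2, , drop = FALSE]
    MT <- vapply(seq_len(K), function(k)
        matingTypeProb(1:6, min(max(p[k], .P_CLAMP[1L]), .P_CLAMP[2L])),
        numeric(6))
    zt <- rep(z, each = 6L)
    W1 <- vector("list", K); W2 <- vector("list", K)
    tot1 <- numeric(n1); tot2 <- numeric(n2)
    for (k in seq_len(K)) {
        if (n1) {
            W1[[k]] <- A1 * matrix(MT[, k], n1, 6L, byrow = TRUE) * pi1[, k]
            tot1 <- tot1 + rowSums(W1[[k]])
        }
        if (n2) {
            W2[[k]] <- A2 * matrix(rep(MT[, k], 3L) * zt, n2, 18L,
                                   byrow = TRUE) * pi2[, k]
            tot2 <- tot2 + rowSums(W2[[k]])
        }
    }
    inv1 <- if (n1) 1 / tot1 else numeric(0)
    inv2 <- if (n2) 1 / tot2 else numeric(0)
    Sp <- numeric(K); Nk <- numeric(K); Sz <- numeric(3L)
    a6 <- .MT_A; a18 <- rep(.MT_A, 3L); e6 <- .MT_E; e18 <- rep(.MT_E, 3L)
    expE <- rep(NA_real_, length(sel))
    origin <- matrix(NA_real_, length(sel), K)
    acc1 <- numeric(n1); acc2 <- numeric(n2)
    for (k in seq_len(K)) {
        if (n1) {
            Sp[k] <- Sp[k] + sum((W1[[k]] %*% a6) * inv1)
            Nk[k] <- Nk[k] + sum(rowSums(W1[[k]]) * inv1)
            acc1 <- acc1 + (W1[[k]] %*% e6)[, 1L]
            origin[i1, k] <- rowSums(W1[[k]]) * inv1
        }
        if (n2) {
            Sp[k] <- Sp[k] + sum((W2[[k]] %*% a18) * inv2)
            Nk[k] <- Nk[k] + sum(rowSums(W2[[k]]) * inv2)
            acc2 <- acc2 + (W2[[k]] %*% e18)[, 1L]
            origin[i2, k] <- rowSums(W2[[k]]) * inv2
            for (j in 1:3)
                Sz[j] <- Sz[j] + sum(rowSums(
                    W2[[k]][, (j - 1L) * 6L + 1:6, drop = FALSE]) * inv2)
        }
    }
    if (n1) expE[i1] <- acc1 * inv1
    if (n2) expE[i2] <- acc2 * inv2
    loglik <- (if (n1) sum(log(tot1)) else 0) +
        (if (n2) sum(log(tot2)) else 0)
    list(Sp = Sp, N = Nk, Sz = if (n2) Sz else NULL, loglik = loglik,
         origin = origin, expE = expE, included = type > 0L)
}

#' One M-step: parameter updates from expected sufficient statistics
#'
#' `p_k' = Sp[k] / (4 N[k])` (four parental allele slots per unit), clamped
#' to `[1e-6, 1 - 1e-6]`; `z' = Sz / sum(Sz)` when two-affected-sib units
#' exist, otherwise unchanged.
#'
#' @param stats List as returned by [emEStep()].
#' @param p,z Current parameters (carried through where no information is
#'   available).
#' @return `list(p, z)`.
#' @export
emMStep <- function(stats, p, z = c(0.25, 0.5, 0.25)) {
    pNew <- ifelse(stats$N > 0, stats$Sp / (4 * stats$N), p)
    if (any(stats$N == 0))
        warning("subpopulation(s) with zero expected membership; ",
                "frequency left unchanged")
    pNew <- pmin(pmax(pNew, .P_CLAMP[1L]), .P_CLAMP[2L])
    zNew <- if (!is.null(stats$Sz) && sum(stats$Sz) > 0)
        stats$Sz / sum(stats$Sz) else z
    list(p = pNew, z = zNew)
}

#' Run the per-marker EM to convergence
#'
#' Iterates E- and M-steps from a deterministic initialisation (per-cluster
#' sample allele frequencies; `z = (1/4, 1/2, 1/4)`) until the largest
#' absolute parameter change drops below `tol` or `maxIter` is reached.
#' The observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param units List of [FamilyUnit-class].
#' @param markerGenotypes Genotype vector for one marker.
#' @param priors Units x K origin prior matrix.
#' @param K Number of subpopulations.
#' @param labels Optional per-individual cluster labels used for the
#'   initial frequencies (defaults to all-1).
#' @param tol Convergence tolerance on the max absolute parameter change.
#' @param maxIter Maximum EM iterations (typically 20-40 are needed).
#' @return `list(model = list(p, z, nIterations, converged, loglik,
#'   loglikTrace), posteriors = list(origin, expE, included))`, or `NULL`
#'   when no family is includable at the marker.
#' @export
runEm <- function(units, markerGenotypes, priors, K, labels = NULL,
                  tol = 1e-6, maxIter = 50L) {
    if (is.null(labels)) labels <- rep(1L, length(markerGenotypes))
    md <- .markerData(units, markerGenotypes)
    p0 <- .emInit(markerGenotypes, labels, K)
    fit <- .emFit(md, seq_along(units), priors, p0 = p0, tol = tol,
                  maxIter = maxIter)
    if (is.null(fit)) return(NULL)
    list(model = fit[c("p", "z", "nIterations", "converged", "loglik",
                       "loglikTrace")],
         posteriors = fit[c("origin", "expE", "included")],
         markerData = md)
}
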