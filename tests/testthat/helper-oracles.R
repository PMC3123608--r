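# Independent oracles used across the suite.  These deliberately take the
# slow, exhaustive route (labelled enumeration, from-scratch objectives) and
# never share code with the package internals they check.

# --- labelled-gamete enumeration of sib-pair genotype distributions -------
# Enumerate the 16 labelled transmission outcomes of two meioses per parent;
# the IBD state is the number of parents whose labels coincide.  Returns
# the 3 x 3 conditional P(g1, g2 | m, IBD = j).
sibpairOracle <- function(m, j) {
    mt <- matingTypes()[m, ]
    fa <- c(rep(1L, mt[1L]), rep(0L, 2L - mt[1L]))
    mo <- c(rep(1L, mt[2L]), rep(0L, 2L - mt[2L]))
    joint <- array(0, c(3L, 3L, 3L))      # g1, g2, j
    for (f1 in 1:2) for (m1 in 1:2) for (f2 in 1:2) for (m2 in 1:2) {
        g1 <- fa[f1] + mo[m1]
        g2 <- fa[f2] + mo[m2]
        jj <- (f1 == f2) + (m1 == m2)
        joint[g1 + 1L, g2 + 1L, jj + 1L] <-
            joint[g1 + 1L, g2 + 1L, jj + 1L] + 1 / 16
    }
    joint[, , j + 1L] / sum(joint[, , j + 1L])
}

# --- exhaustive single-family posterior weights ---------------------------
# Direct loop over (k, m, j) with explicit ordered-parent bookkeeping:
# each ordered parental genotype pair gets prior hwe(gf) * hwe(gm), is
# screened against the observations, and contributes to its unordered
# mating type; sib-pair terms come from sibpairOracle.
familyWeightsOracle <- function(gf, gm, sibs, prior, p, z) {
    K <- length(p)
    mt <- matingTypes()
    w <- array(0, c(K, 6L, 3L))
    for (k in seq_len(K)) for (a in 0:2) for (b in 0:2) {
        if (!is.na(gf) && a != gf) next
        if (!is.na(gm) && b != gm) next
        m <- which(mt[, 1L] == min(a, b) & mt[, 2L] == max(a, b))
        base <- prior[k] * hweGenotypeProb(a, p[k]) * hweGenotypeProb(b, p[k])
        if (length(sibs) == 0L) {
            w[k, m, 1L] <- w[k, m, 1L] + base
        } else if (length(sibs) == 1L) {
            w[k, m, 1L] <- w[k, m, 1L] + base * offspringProb(sibs, m)
        } else {
            for (j in 0:2)
                w[k, m, j + 1L] <- w[k, m, j + 1L] + base * z[j + 1L] *
                    sibpairOracle(m, j)[sibs[1L] + 1L, sibs[2L] + 1L]
        }
    }
    w / sum(w)
}

# --- from-scratch Ward agglomeration --------------------------------------
# Greedy merging recomputing Ward's objective from first principles at every
# step: ESS(C) defined through squared pairwise dissimilarities,
# ESS(C) = sum_{i<j in C} d_ij^2 / |C|; merge cost = ESS gain.  Ties break
# towards the smallest (i, j) cluster-index pair.  Returns the partition at
# each K as a list of label vectors.
wardOracle <- function(d) {
    n <- nrow(d)
    ess <- function(members) {
        if (length(members) < 2L) return(0)
        pairs <- combn(members, 2L)
        sum(d[cbind(pairs[1L, ], pairs[2L, ])]^2) / length(members)
    }
    clusters <- as.list(seq_len(n))
    partitions <- vector("list", n)
    labelsOf <- function(cl) {
        lab <- integer(n)
        for (i in seq_along(cl)) lab[cl[[i]]] <- i
        lab
    }
    partitions[[n]] <- labelsOf(clusters)
    while (length(clusters) > 1L) {
        best <- Inf; bi <- bj <- 0L
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            cost <- ess(c(clusters[[i]], clusters[[j]])) -
                ess(clusters[[i]]) - ess(clusters[[j]])
            if (cost < best) { best <- cost; bi <- i; bj <- j }
        }
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
        partitions[[length(clusters)]] <- labelsOf(clusters)
    }
    partitions
}

# two label vectors describe the same partition?
samePartition <- function(a, b) {
    length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}

# --- TDT transmission counts ----------------------------------------------
# b = transmissions of the counted allele from heterozygous parents to
# affected offspring, c = non-transmissions; works on complete triads.
tdtCounts <- function(units, g) {
    g <- unname(g)
    b <- 0L; cc <- 0L
    for (u in units) {
        if (u@designTag != "triad") next
        gf <- g[u@father]; gm <- g[u@mother]; gc <- g[u@affectedSibs[1L]]
        # child = tF + tM; homozygous parents transmit deterministically,
        # so counted-allele transmissions from het parents are gc - forced
        fixed <- (gf == 2L) + (gm == 2L)   # forced counted-allele copies
        hets <- (gf == 1L) + (gm == 1L)
        tHet <- gc - fixed                 # counted alleles from het parents
        b <- b + tHet
        cc <- cc + (hets - tHet)
    }
    c(b = b, c = cc)
}

# --- moment estimator of the drift parameter from two population
# frequencies: between-population variance (p1-p2)^2 / 2 over pbar qbar
fstEstimate <- function(p1, p2) {
    pbar <- (p1 + p2) / 2
    num <- (p1 - p2)^2 / 2
    den <- pbar * (1 - pbar)
    mean(num[den > 0] / den[den > 0])
}

# genotype vector of a study column subset at one marker
markerVec <- function(study, m) genotypes(study)[m, ]
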