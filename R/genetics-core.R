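# Closed-form probability kernel for a biallelic marker: HWE genotype and
# mating-type probabilities, Mendelian transmission, and IBD-conditional
# affected-sib-pair genotype distributions.  Genotypes are coded 0/1/2 =
# copies of the counted allele.  Mating types are the 6 unordered parental
# genotype pairs, indexed 1..6 in the canonical order returned by
# matingTypes().

# transmission distribution: row g+1 gives P(transmit 0 copies), P(transmit 1)
.TAU <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))

#' Canonical mating types of a biallelic marker
#'
#' The six unordered parental genotype pairs, in the fixed order used by all
#' mating-type indices in this package.
#'
#' @return A 6 x 2 integer matrix; row `m` holds the (low, high) genotype
#'   pair of mating type `m`: (0,0), (0,1), (0,2), (1,1), (1,2), (2,2).
#' @examples
#' matingTypes()
#' @export
matingTypes <- function() {
    matrix(c(0L, 0L, 0L, 1L, 0L, 2L, 1L, 1L, 1L, 2L, 2L, 2L),
           ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("g1", "g2")))
}

.MT <- matrix(c(0L, 0L, 0L, 1L, 0L, 2L, 1L, 1L, 1L, 2L, 2L, 2L),
              ncol = 2L, byrow = TRUE)

# parental counted-allele copies a(m) and null-expected offspring count e(m)
.MT_A <- as.numeric(.MT[, 1L] + .MT[, 2L])
.MT_E <- .MT_A / 2

#' Map an unordered parental genotype pair to its mating-type index
#'
#' @param g1,g2 Parental genotype codes in \{0, 1, 2\} (order irrelevant).
#' @return Integer index in 1..6 into [matingTypes()].
#' @examples
#' matingTypeIndex(2, 0)  # -> 3, the (0,2) mating type
#' @export
matingTypeIndex <- function(g1, g2) {
    lo <- pmin(g1, g2)
    hi <- pmax(g1, g2)
    # (lo,hi) -> index: enumerate the 6 pairs
    idx <- integer(length(lo))
    key <- lo * 10L + hi
    map <- c(`0` = 1L, `1` = 2L, `2` = 3L, `11` = 4L, `12` = 5L, `22` = 6L)
    idx <- map[as.character(key)]
    if (anyNA(idx)) stop("invalid genotype codes for a mating type")
    unname(idx)
}

#' Hardy-Weinberg genotype probability
#'
#' @param g Genotype code(s) in \{0, 1, 2\}, copies of the counted allele.
#' @param p Counted-allele frequency in \[0, 1\].
#' @return P(g) under HWE: (1-p)^2, 2p(1-p), p^2 for g = 0, 1, 2.
#' @examples
#' hweGenotypeProb(0:2, 0.2)
#' @export
hweGenotypeProb <- function(g, p) {
    stopifnot(all(g %in% 0:2), all(p >= 0 & p <= 1))
    choose(2, g) * p^g * (1 - p)^(2 - g)
}

# unchecked fast path used inside the EM loops
.mtProbs <- function(p) {
    q <- 1 - p
    c(q^4, 4 * p * q^3, 2 * p^2 * q^2, 4 * p^2 * q^2, 4 * p^3 * q, p^4)
}

#' Mating-type probability under HWE random mating
#'
#' Probability of the unordered parental genotype pair `m` when both parents
#' are drawn from a subpopulation with counted-allele frequency `p`.
#' Heterogeneous pairs carry the factor 2 for their two ordered assignments.
#'
#' @param m Mating-type index (1..6, see [matingTypes()]); vectorised.
#' @param p Counted-allele frequency.
#' @return P(m); the six values sum to 1.
#' @examples
#' sum(matingTypeProb(1:6, 0.3))
#' @export
matingTypeProb <- function(m, p) {
    stopifnot(all(m %in% 1:6), length(p) == 1L, p >= 0, p <= 1)
    g1 <- .MT[m, 1L]
    g2 <- .MT[m, 2L]
    pr <- hweGenotypeProb(g1, p) * hweGenotypeProb(g2, p)
    pr * ifelse(g1 == g2, 1, 2)
}

# 3 x 6 Mendelian table: P(child g | mating type m), built by convolving the
# two parental transmission distributions.
.OFF <- local({
    off <- matrix(0, nrow = 3L, ncol = 6L)
    for (m in 1:6) {
        ta <- .TAU[.MT[m, 1L] + 1L, ]
        tb <- .TAU[.MT[m, 2L] + 1L, ]
        for (x in 0:1) for (y in 0:1)
            off[x + y + 1L, m] <- off[x + y + 1L, m] + ta[x + 1L] * tb[y + 1L]
    }
    off
})

#' Mendelian offspring genotype probability
#'
#' @param g Child genotype code(s) in \{0, 1, 2\}.
#' @param m Mating-type index (1..6).
#' @return P(g | m); sums to 1 over g for every m.
#' @examples
#' offspringProb(0:2, matingTypeIndex(1, 1))  # het x het -> 1/4, 1/2, 1/4
#' @export
offspringProb <- function(g, m) {
    stopifnot(all(g %in% 0:2), all(m %in% 1:6))
    .OFF[cbind(g + 1L, m)]
}

# P(g1, g2 | m, IBD = j) tables, dim 3 x 3 x 6, one per j = 0, 1, 2 —
# conditionals of the labelled-gamete model (IBD state = number of parental
# transmissions with coinciding labels):
#   j = 0: both parents transmit their two DISTINCT labelled alleles, one to
#          each sib (in either order);
#   j = 1: the shared parent (chosen uniformly) transmits one common allele
#          to both sibs, the other parent its two distinct alleles;
#   j = 2: sibs receive the identical labelled gamete pair.
# Mixing with z = (1/4, 1/2, 1/4) recovers the unconditional full-sib
# distribution, i.e. two independent Mendelian draws.
.SIB <- local({
    # labelled allele values of a parent with genotype g (het: counted
    # allele in slot 1)
    alleles <- function(g) switch(g + 1L, c(0L, 0L), c(1L, 0L), c(1L, 1L))
    # distribution over (t1, t2) value pairs when the parent's two distinct
    # labelled alleles go one to each sib, in either order
    distinctPair <- function(g) {
        a <- alleles(g)
        out <- matrix(0, 2L, 2L)  # rows t1+1, cols t2+1
        out[a[1L] + 1L, a[2L] + 1L] <- out[a[1L] + 1L, a[2L] + 1L] + 0.5
        out[a[2L] + 1L, a[1L] + 1L] <- out[a[2L] + 1L, a[1L] + 1L] + 0.5
        out
    }
    # distribution over (t, t) when one labelled allele goes to both sibs
    sharedPair <- function(g) {
        a <- alleles(g)
        out <- matrix(0, 2L, 2L)
        out[a[1L] + 1L, a[1L] + 1L] <- out[a[1L] + 1L, a[1L] + 1L] + 0.5
        out[a[2L] + 1L, a[2L] + 1L] <- out[a[2L] + 1L, a[2L] + 1L] + 0.5
        out
    }
    combine <- function(fPair, mPair) {
        s <- array(0, c(3L, 3L))
        for (tf1 in 0:1) for (tf2 in 0:1) for (tm1 in 0:1) for (tm2 in 0:1)
            s[tf1 + tm1 + 1L, tf2 + tm2 + 1L] <-
                s[tf1 + tm1 + 1L, tf2 + tm2 + 1L] +
                fPair[tf1 + 1L, tf2 + 1L] * mPair[tm1 + 1L, tm2 + 1L]
        s
    }
    s0 <- array(0, c(3L, 3L, 6L)); s1 <- array(0, c(3L, 3L, 6L))
    s2 <- array(0, c(3L, 3L, 6L))
    for (m in 1:6) {
        gf <- .MT[m, 1L]; gm <- .MT[m, 2L]
        s0[, , m] <- combine(distinctPair(gf), distinctPair(gm))
        s1[, , m] <- 0.5 * combine(sharedPair(gf), distinctPair(gm)) +
            0.5 * combine(distinctPair(gf), sharedPair(gm))
        s2[, , m] <- combine(sharedPair(gf), sharedPair(gm))
    }
    list(s0, s1, s2)
})

#' IBD-conditional genotype distribution of an affected sib pair
#'
#' Probability that two full siblings have genotypes `g1` and `g2` given the
#' parental mating type and the number `j` of alleles the pair shares
#' identical by descent.  These are the exact conditionals of the
#' labelled-gamete model: conditioning on `j = 0` at a parent means that
#' parent's two distinct labelled alleles went one to each sib, so sib
#' genotypes are anti-correlated rather than independent, and mixing the
#' three tables with `z = (1/4, 1/2, 1/4)` recovers the unconditional
#' full-sib distribution.
#'
#' @param g1,g2 Sib genotype codes in \{0, 1, 2\}.
#' @param m Mating-type index (1..6).
#' @param j IBD state in \{0, 1, 2\}.
#' @return P(g1, g2 | m, IBD = j); sums to 1 over the 9 genotype pairs.
#' @examples
#' sibpairProb(2, 1, matingTypeIndex(1, 1), 1)  # 1/4
#' sibpairProb(2, 2, matingTypeIndex(1, 1), 2)  # 1/4
#' @export
sibpairProb <- function(g1, g2, m, j) {
    stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2),
              all(m %in% 1:6), all(j %in% 0:2))
    n <- max(length(g1), length(g2), length(m), length(j))
    g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
    m <- rep_len(m, n); j <- rep_len(j, n)
    out <- numeric(n)
    for (jj in 0:2) {
        sel <- j == jj
        if (any(sel))
            out[sel] <- .SIB[[jj + 1L]][cbind(g1[sel] + 1L, g2[sel] + 1L, m[sel])]
    }
    out
}

#' Sib-pair genotype probability under an IBD-sharing mixture
#'
#' @param g1,g2 Sib genotype codes.
#' @param m Mating-type index (1..6).
#' @param z Numeric length-3 simplex (z0, z1, z2) of IBD-sharing
#'   probabilities for the pair.
#' @return sum_j z_j P(g1, g2 | m, IBD = j).
#' @examples
#' # the null sharing vector reproduces the unconditional full-sib distribution
#' sibpairProbMixture(1, 2, matingTypeIndex(1, 2), c(0.25, 0.5, 0.25))
#' @export
sibpairProbMixture <- function(g1, g2, m, z) {
    stopifnot(length(z) == 3L, all(z >= 0), abs(sum(z) - 1) < 1e-8)
    z[1L] * sibpairProb(g1, g2, m, 0L) +
        z[2L] * sibpairProb(g1, g2, m, 1L) +
        z[3L] * sibpairProb(g1, g2, m, 2L)
}

#' Null-expected counted-allele copies per offspring
#'
#' Expectation of an offspring's genotype under Mendelian transmission from
#' a mating type, i.e. half the parental counted-allele copies.
#'
#' @param m Mating-type index (1..6); vectorised.
#' @return e(m) = (g1 + g2) / 2.
#' @examples
#' expectedOffspringCount(1:6)
#' @export
expectedOffspringCount <- function(m) {
    stopifnot(all(m %in% 1:6))
    .MT_E[m]
}
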