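# Linkage-disequilibrium effective population size ------------------------
#
# Burrows composite disequilibrium between unlinked loci reflects drift in
# a finite population.  For every locus pair and allele pair we compute
#
#   Delta-hat = S/(S-1) * [ sum(x*y)/(2S) - 2*p*q ]
#   r2        = Delta-hat^2 / (p(1-p) q(1-q))
#
# with x, y allele dosages (0/1/2) over the S individuals typed at both
# loci.  The weighted mean r2 is compared with its pure-sampling
# expectation (Waples 2006):
#   S >= 30:  E[r2] = 1/S + 3.19/S^2
#   S <  30:  E[r2] = 0.0018 + 0.907/S + 4.44/S^2
# and the excess r2' = r2 - E[r2] is inverted to Ne under random mating:
#   S >= 30:  Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')
#   S <  30:  Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')
# Non-positive excess LD yields an infinite estimate (no drift signal).

# dosage matrix for one locus: individuals x retained alleles
dosage_matrix <- function(a1, a2, alleles) {
  m <- matrix(0L, length(a1), length(alleles))
  for (j in seq_along(alleles))
    m[, j] <- (a1 == alleles[j]) + (a2 == alleles[j])
  m[is.na(a1), ] <- NA_integer_
  colnames(m) <- alleles
  m
}

# mean r2 and harmonic-ish mean S over all comparisons, optionally
# excluding one locus (for the jackknife)
ld_mean_r2 <- function(dos, exclude = 0L) {
  loci <- setdiff(seq_along(dos), exclude)
  num <- 0; wsum <- 0; s_inv <- 0; ncomp <- 0
  for (ii in seq_along(loci)) {
    for (jj in seq_len(ii - 1L)) {
      l1 <- loci[ii]; l2 <- loci[jj]
      X <- dos[[l1]]; Y <- dos[[l2]]
      keep <- !is.na(X[, 1]) & !is.na(Y[, 1])
      S <- sum(keep)
      if (S < 10) next
      X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
      p <- colMeans(X) / 2; q <- colMeans(Y) / 2
      use_p <- p > 0 & p < 1; use_q <- q > 0 & q < 1
      if (!any(use_p) || !any(use_q)) next
      cross <- crossprod(X[, use_p, drop = FALSE],
                         Y[, use_q, drop = FALSE])     # sum x*y
      pu <- p[use_p]; qu <- q[use_q]
      delta <- (S / (S - 1)) * (cross / (2 * S) - 2 * outer(pu, qu))
      r2 <- delta^2 / outer(pu * (1 - pu), qu * (1 - qu))
      w <- S * length(r2)
      num <- num + S * sum(r2)
      wsum <- wsum + w
      s_inv <- s_inv + length(r2) / S
      ncomp <- ncomp + length(r2)
    }
  }
  if (ncomp == 0) return(NULL)
  list(r2 = num / wsum, S = ncomp / s_inv, ncomp = ncomp)
}

ld_expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

ld_ne_from_r2 <- function(r2, S) {
  r2p <- r2 - ld_expected_r2(S)
  if (is.na(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; b <- 1 / 9; cc <- 2.76 }
  else { a <- 0.308; b <- 0.308^2; cc <- 2.08 }
  disc <- b - cc * r2p
  if (disc < 0) disc <- 0
  ne <- (a + sqrt(disc)) / (2 * r2p)
  if (ne <= 0) Inf else ne
}

#' LD-based effective population size for one sample
#'
#' @param x a [microsat_dataset()] holding the individuals of one site (or
#'   any single sample).
#' @param pcrit alleles with sample frequency below this are excluded from
#'   the disequilibrium comparisons (default 0.05, the usual screening
#'   level); loci with fewer than two retained alleles are dropped, and at
#'   exactly two retained alleles only one is used (the two dosages are
#'   perfectly anticorrelated).
#' @param conf confidence level of the delete-one-locus jackknife interval.
#' @return list: `ne` (point estimate; `Inf` when the mean r2 does not
#'   exceed its sampling expectation), `ci` (jackknife interval on the
#'   same scale), `r2`, `expected_r2`, `S` (harmonic mean sample size),
#'   `n_comparisons`, `n_loci_used`. All-`NA` result with a `reason`
#'   attribute when fewer than two usable loci remain.
#' @export
ne_ld <- function(x, pcrit = 0.05, conf = 0.95) {
  none <- function(reason) {
    out <- list(ne = NA_real_, ci = c(NA_real_, NA_real_), r2 = NA_real_,
                expected_r2 = NA_real_, S = NA_real_, n_comparisons = 0L,
                n_loci_used = 0L)
    attr(out, "reason") <- reason
    out
  }
  dos <- list()
  for (l in seq_along(x$loci)) {
    a1 <- x$allele1[, l]; a2 <- x$allele2[, l]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    p <- table(c(a1[ok], a2[ok])) / (2 * sum(ok))
    keep <- names(p)[p >= pcrit]
    if (length(keep) < 2) next
    if (length(keep) == 2) keep <- keep[1]
    dos[[length(dos) + 1L]] <- dosage_matrix(a1, a2, as.integer(keep))
  }
  if (length(dos) < 2) return(none("fewer than 2 usable polymorphic loci"))
  full <- ld_mean_r2(dos)
  if (is.null(full)) return(none("no locus pair with enough joint data"))
  ne <- ld_ne_from_r2(full$r2, full$S)

  # delete-one-locus jackknife on mean r2, transformed to Ne bounds
  L <- length(dos)
  theta <- vapply(seq_len(L), function(l) {
    z <- ld_mean_r2(dos, exclude = l)
    if (is.null(z)) NA_real_ else z$r2
  }, numeric(1))
  theta <- theta[!is.na(theta)]
  if (length(theta) >= 2) {
    Lj <- length(theta)
    se <- sqrt((Lj - 1) / Lj * sum((theta - mean(theta))^2))
    zq <- qnorm(1 - (1 - conf) / 2)
    r2_lo <- full$r2 - zq * se
    r2_hi <- full$r2 + zq * se
    ci <- c(ld_ne_from_r2(r2_hi, full$S), ld_ne_from_r2(r2_lo, full$S))
  } else ci <- c(NA_real_, NA_real_)
  list(ne = ne, ci = ci, r2 = full$r2, expected_r2 = ld_expected_r2(full$S),
       S = full$S, n_comparisons = full$ncomp, n_loci_used = length(dos))
}
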