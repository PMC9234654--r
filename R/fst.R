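# Weir-Cockerham F_ST ------------------------------------------------------
#
# Multiallelic theta via the 1984 variance components a (among
# populations), b (among individuals within populations) and c (within
# individuals), summed over alleles and loci:
# theta = sum(a) / sum(a + b + c).

# a, b, c components for one locus across groups.
# a1, a2: allele vectors; g: group labels (factor-like).
wc_components_locus <- function(a1, a2, g) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; g <- g[keep]
  tab <- table(g)
  tab <- tab[tab >= 1]
  pops <- names(tab)[tab >= 2]          # need >= 2 genotypes per group
  if (length(pops) < 2) return(NULL)
  sel <- g %in% pops
  a1 <- a1[sel]; a2 <- a2[sel]; g <- factor(g[sel], levels = pops)
  r <- length(pops)
  n_i <- as.numeric(table(g))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL) # monomorphic across both groups
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    d <- (a1 == al) + (a2 == al)
    p_i <- tapply(d, g, mean) / 2
    h_i <- tapply(d == 1L, g, mean)     # heterozygous for this allele
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a_c <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_c <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    A <- A + a_c; B <- B + b_c; C <- C + c_c
  }
  c(a = A, b = B, c = C)
}

# summed components over loci for a dataset + grouping labels
wc_components <- function(x, g) {
  tot <- c(a = 0, b = 0, c = 0)
  used <- 0L
  for (l in seq_along(x$loci)) {
    z <- wc_components_locus(x$allele1[, l], x$allele2[, l], g)
    if (!is.null(z)) { tot <- tot + z; used <- used + 1L }
  }
  attr(tot, "n_loci_used") <- used
  tot
}

#' Weir-Cockerham theta between two groups
#'
#' @param x a [microsat_dataset()].
#' @param group_a,group_b group labels.
#' @param grouping `"site"` or `"river"` (or a per-individual label
#'   vector).
#' @return theta (can be slightly negative in the absence of
#'   differentiation), or `NA` when no locus is usable.
#' @export
wc_fst_pair <- function(x, group_a, group_b, grouping = "site") {
  g <- group_labels(x, grouping)
  sel <- g %in% c(group_a, group_b)
  comp <- wc_components(subset_dataset(x, individuals = sel), g[sel])
  if (attr(comp, "n_loci_used") == 0L) return(NA_real_)
  denom <- sum(comp)
  if (denom == 0) return(NA_real_)
  unname(comp["a"] / denom)
}

# Sufficient statistics for WC components: per locus, per group the
# genotype count n, allele frequencies P and per-allele heterozygote
# frequencies H.  Pairwise theta needs nothing else, so the all-pairs
# matrix never rescans individuals.
fst_suffstats <- function(x, g) {
  groups <- sort(unique(g))
  lapply(seq_along(x$loci), function(l) {
    a1 <- x$allele1[, l]; a2 <- x$allele2[, l]
    keep <- !is.na(a1)
    alleles <- sort(unique(c(a1[keep], a2[keep])))
    A <- length(alleles)
    S <- length(groups)
    n <- integer(S)
    P <- matrix(0, S, A, dimnames = list(groups, alleles))
    H <- matrix(0, S, A, dimnames = list(groups, alleles))
    for (s in seq_len(S)) {
      rows <- which(g == groups[s] & keep)
      n[s] <- length(rows)
      if (!n[s]) next
      for (a in seq_len(A)) {
        d <- (a1[rows] == alleles[a]) + (a2[rows] == alleles[a])
        P[s, a] <- sum(d) / (2 * n[s])
        H[s, a] <- sum(d == 1L) / n[s]
      }
    }
    list(n = setNames(n, groups), P = P, H = H)
  })
}

# WC a, b, c for one locus and one group pair from sufficient statistics
wc_pair_from_stats <- function(st, i, j) {
  n_i <- c(st$n[i], st$n[j])
  if (any(n_i < 2)) return(NULL)
  P <- st$P[c(i, j), , drop = FALSE]
  H <- st$H[c(i, j), , drop = FALSE]
  use <- colSums(P) > 0
  if (sum(use) < 2) return(NULL)       # monomorphic across the pair
  P <- P[, use, drop = FALSE]; H <- H[, use, drop = FALSE]
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * P) / (r * nbar)
  s2 <- colSums(n_i * (P - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * H) / (r * nbar)
  a_c <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b_c <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c_c <- hbar / 2
  c(a = sum(a_c), b = sum(b_c), c = sum(c_c))
}

#' All pairwise theta values for a grouping
#'
#' @param x a [microsat_dataset()].
#' @param grouping `"site"` or `"river"`; river grouping pools site
#'   samples.
#' @param min_n groups with fewer individuals are excluded with a warning.
#' @param exclude_loci locus names to drop (e.g. a null-allele-prone
#'   locus) before estimating differentiation.
#' @return list: `pairs` data.frame (group_a, group_b, theta) and `matrix`
#'   (a [distance_matrix()]-style symmetric matrix of theta, kind "fst").
#' @export
fst_matrix <- function(x, grouping = "site", min_n = 2,
                       exclude_loci = character(0)) {
  if (length(exclude_loci))
    x <- subset_dataset(x, loci = !(x$loci %in% exclude_loci))
  g <- group_labels(x, grouping)
  tab <- table(g)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("excluding group(s) with < ", min_n, " individuals: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- subset_dataset(x, individuals = keep)
    g <- g[keep]
  }
  groups <- sort(unique(g))
  stats <- fst_suffstats(x, g)
  prs <- t(combn(groups, 2))
  theta <- vapply(seq_len(nrow(prs)), function(k) {
    tot <- c(a = 0, b = 0, c = 0)
    used <- 0L
    for (st in stats) {
      z <- wc_pair_from_stats(st, prs[k, 1], prs[k, 2])
      if (!is.null(z)) { tot <- tot + z; used <- used + 1L }
    }
    if (used == 0L || sum(tot) == 0) NA_real_ else
      unname(tot["a"] / sum(tot))
  }, numeric(1))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (k in seq_len(nrow(prs))) {
    m[prs[k, 1], prs[k, 2]] <- theta[k]
    m[prs[k, 2], prs[k, 1]] <- theta[k]
  }
  list(pairs = data.frame(group_a = prs[, 1], group_b = prs[, 2],
                          theta = theta, stringsAsFactors = FALSE),
       matrix = m)
}

#' Permutation test of pairwise theta
#'
#' Multilocus genotypes (whole individuals, the exchangeable unit) are
#' permuted between the two groups; `p = (1 + #{theta_perm >= theta_obs})
#' / (1 + n_perm)`, so p is never exactly 0.  A mode permuting loci
#' instead of individuals is retained for comparability with analyses
#' phrased as "permutations of loci".
#'
#' @param x a [microsat_dataset()].
#' @param group_a,group_b group labels.
#' @param grouping `"site"`, `"river"`, or a label vector.
#' @param n_perm number of permutations (`< 1` returns `NA`).
#' @param seed optional integer seed for reproducibility.
#' @param unit `"individuals"` (default) or `"loci"`.
#' @return list: `theta`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(x, group_a, group_b, grouping = "site",
                                 n_perm = 10000, seed = NULL,
                                 unit = c("individuals", "loci")) {
  unit <- match.arg(unit)
  if (n_perm < 1) return(list(theta = NA_real_, p_value = NA_real_,
                              n_perm = 0L))
  if (!is.null(seed)) set.seed(seed)
  g <- group_labels(x, grouping)
  sel <- g %in% c(group_a, group_b)
  d <- subset_dataset(x, individuals = sel)
  gg <- g[sel]
  obs <- {
    comp <- wc_components(d, gg)
    sum_comp <- sum(comp)
    if (sum_comp == 0) NA_real_ else unname(comp["a"] / sum_comp)
  }
  if (is.na(obs)) return(list(theta = NA_real_, p_value = NA_real_,
                              n_perm = 0L))
  hits <- 0L
  for (r in seq_len(n_perm)) {
    if (unit == "individuals") {
      gp <- sample(gg)
      comp <- wc_components(d, gp)
    } else {
      # permute group labels independently within each locus
      tot <- c(a = 0, b = 0, c = 0)
      for (l in seq_along(d$loci)) {
        z <- wc_components_locus(d$allele1[, l], d$allele2[, l],
                                 sample(gg))
        if (!is.null(z)) tot <- tot + z
      }
      comp <- tot
    }
    s <- sum(comp)
    th <- if (s == 0) -Inf else comp["a"] / s
    if (th >= obs - 1e-15) hits <- hits + 1L
  }
  list(theta = obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}
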