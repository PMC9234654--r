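# Hierarchical AMOVA -------------------------------------------------------
#
# Excoffier-style analysis of molecular variance on an individual-level
# squared-distance matrix (number of allele differences summed over loci,
# rescaled for missing loci), with two nested levels above the individual:
# groups (e.g. rivers) and populations within groups (sites).

# individuals x individuals squared distance: allele differences per locus
# (0, 1, 2), averaged over loci scored in both individuals and scaled to
# the full locus count.
amova_distance <- function(x) {
  n <- length(x$ind_id)
  L <- length(x$loci)
  d <- matrix(0, n, n)
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- x$allele1[, l]; a2 <- x$allele2[, l]
    ok <- !is.na(a1)
    # per-pair allele difference via allele dosage vectors
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (!length(alleles)) next
    D <- dosage_matrix(a1, a2, alleles)
    D[!ok, ] <- 0L
    # number of shared allele copies between i and j = sum_a min(d_ia, d_ja)
    # difference = 2 - shared
    for (a in seq_along(alleles)) {
      da <- D[, a]
      d <- d + outer(da, da, pmin)
    }
    shared <- shared + outer(ok, ok, "&")
  }
  # d currently holds shared copies summed over scored loci
  diffs <- 2 * shared - d
  out <- matrix(NA_real_, n, n)
  pos <- shared > 0
  out[pos] <- diffs[pos] * (L / shared[pos])
  diag(out) <- 0
  out
}

amova_ss <- function(d2, pop, grp) {
  N <- nrow(d2)
  ss_within <- function(rows) {
    if (length(rows) < 2) return(0)
    sum(d2[rows, rows], na.rm = TRUE) / 2 / length(rows)
  }
  ss_t <- ss_within(seq_len(N))
  pops <- unique(pop); grps <- unique(grp)
  ss_wp <- sum(vapply(pops, function(p) ss_within(which(pop == p)),
                      numeric(1)))
  ss_wg <- sum(vapply(grps, function(g) ss_within(which(grp == g)),
                      numeric(1)))
  c(ag = ss_t - ss_wg, ap = ss_wg - ss_wp, wp = ss_wp)
}

amova_components <- function(d2, pop, grp) {
  N <- nrow(d2)
  pops <- unique(pop); grps <- unique(grp)
  P <- length(pops); G <- length(grps)
  ss <- amova_ss(d2, pop, grp)
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  ms <- ss / df
  n_p <- table(pop)
  n_g <- table(grp)
  pg <- tapply(pop, grp, function(z) unique(z))
  sum_np2_ng <- sum(vapply(grps, function(g) {
    rows <- pop[grp == g]
    sum(table(rows)^2) / sum(grp == g)
  }, numeric(1)))
  n1 <- (N - sum_np2_ng) / (P - G)
  n2 <- (sum_np2_ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  sig_c <- ms["wp"]
  sig_b <- (ms["ap"] - sig_c) / n1
  sig_a <- (ms["ag"] - sig_c - n2 * sig_b) / n3
  sig <- c(among_groups = unname(sig_a),
           among_pops_within_groups = unname(sig_b),
           within_pops = unname(sig_c))
  tot <- sum(sig)
  phi <- c(phi_ct = unname(sig_a) / tot,
           phi_sc = unname(sig_b) / (unname(sig_b) + unname(sig_c)),
           phi_st = (unname(sig_a) + unname(sig_b)) / tot)
  list(ss = ss, df = df, ms = ms, sigma = sig, phi = phi)
}

#' Hierarchical analysis of molecular variance
#'
#' Decomposes genotype variance into among-group, among-population-within-
#' group, and within-population components using squared allele-difference
#' distances, with permutation p-values per level:
#' \describe{
#'   \item{phi_st}{individuals permuted among all populations;}
#'   \item{phi_sc}{individuals permuted among populations within their
#'     group;}
#'   \item{phi_ct}{whole populations permuted among groups.}
#' }
#'
#' @param x a [microsat_dataset()].
#' @param pops population level: `"site"` (default).
#' @param groups grouping level: `"river"` (default) or `"catchment"`.
#' @param n_perm permutations per level (default 999); `0` skips testing.
#' @param seed optional seed.
#' @return object of class `amova_result`: `sigma` (variance components),
#'   `phi`, `p_values`, `ss`, `df`, `ms`, `n_perm`.
#' @export
amova <- function(x, pops = "site", groups = "river", n_perm = 999,
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- group_labels(x, pops)
  grp <- group_labels(x, groups)
  if (length(unique(grp)) < 2 || length(unique(pop)) <= length(unique(grp)))
    stop("degenerate hierarchy: need >= 2 groups and more populations ",
         "than groups")
  pop2grp <- tapply(grp, pop, function(z) unique(z)[1])
  d2 <- amova_distance(x)
  obs <- amova_components(d2, pop, grp)
  p <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (n_perm >= 1) {
    hits <- c(ct = 0L, sc = 0L, st = 0L)
    pops_u <- unique(pop)
    for (r in seq_len(n_perm)) {
      # phi_st: permute individuals everywhere
      z <- amova_components(d2, sample(pop), grp)$phi["phi_st"]
      if (!is.na(z) && z >= obs$phi["phi_st"] - 1e-15)
        hits["st"] <- hits["st"] + 1L
      # phi_sc: permute individuals within groups
      pp <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        pp[idx] <- sample(pop[idx])
      }
      z <- amova_components(d2, pp, grp)$phi["phi_sc"]
      if (!is.na(z) && z >= obs$phi["phi_sc"] - 1e-15)
        hits["sc"] <- hits["sc"] + 1L
      # phi_ct: permute whole populations among groups
      newg <- setNames(sample(unname(pop2grp)), names(pop2grp))
      z <- amova_components(d2, pop, unname(newg[pop]))$phi["phi_ct"]
      if (!is.na(z) && z >= obs$phi["phi_ct"] - 1e-15)
        hits["ct"] <- hits["ct"] + 1L
    }
    p <- c(phi_ct = (1 + hits[["ct"]]) / (1 + n_perm),
           phi_sc = (1 + hits[["sc"]]) / (1 + n_perm),
           phi_st = (1 + hits[["st"]]) / (1 + n_perm))
  }
  structure(list(sigma = obs$sigma, phi = obs$phi, p_values = p,
                 ss = obs$ss, df = obs$df, ms = obs$ms,
                 n_perm = as.integer(n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components:\n")
  print(round(x$sigma, 5))
  cat("Phi statistics:\n")
  print(round(x$phi, 4))
  if (!all(is.na(x$p_values))) {
    cat("p-values (", x$n_perm, " permutations):\n", sep = "")
    print(round(x$p_values, 4))
  }
  invisible(x)
}
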