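# Per-site diversity statistics ------------------------------------------

#' Quality-control filter on missingness
#'
#' Removes individuals whose fraction of missing locus calls exceeds
#' `max_missing`, then loci whose missingness across the retained
#' individuals exceeds `max_missing`.  Individuals are filtered first so
#' that a handful of failed samples cannot drag down otherwise good loci;
#' the order is configurable.
#'
#' @param x a [microsat_dataset()].
#' @param max_missing maximum tolerated missing fraction (default 0.20;
#'   strictly greater is removed).
#' @param order `"individuals_first"` or `"loci_first"`.
#' @return list: `dataset` (filtered), `removed_individuals`,
#'   `removed_loci`, `order`.
#' @export
qc_filter <- function(x, max_missing = 0.20,
                      order = c("individuals_first", "loci_first")) {
  order <- match.arg(order)
  drop_ind <- function(d) {
    fr <- rowMeans(is.na(d$allele1))
    which(fr > max_missing)
  }
  drop_loc <- function(d) {
    fr <- colMeans(is.na(d$allele1))
    which(fr > max_missing)
  }
  removed_individuals <- character(0); removed_loci <- character(0)
  d <- x
  steps <- if (order == "individuals_first") c("i", "l") else c("l", "i")
  for (st in steps) {
    if (st == "i") {
      bad <- drop_ind(d)
      removed_individuals <- d$ind_id[bad]
      if (length(bad) == length(d$ind_id))
        stop("QC removed all individuals")
      if (length(bad)) d <- subset_dataset(d, individuals = -bad)
    } else {
      bad <- drop_loc(d)
      removed_loci <- d$loci[bad]
      if (length(bad)) d <- subset_dataset(d, loci = -bad)
    }
  }
  list(dataset = d, removed_individuals = removed_individuals,
       removed_loci = removed_loci, order = order)
}

# Per-locus H_o / unbiased H_e for a set of rows (one group). Returns a
# data.frame with one row per locus: n (non-missing genotypes), ho, he.
het_components <- function(x, rows) {
  L <- length(x$loci)
  n <- ho <- he <- numeric(L)
  for (l in seq_len(L)) {
    a1 <- x$allele1[rows, l]; a2 <- x$allele2[rows, l]
    keep <- !is.na(a1)
    nl <- sum(keep)
    n[l] <- nl
    if (nl < 2) { ho[l] <- he[l] <- NA_real_; next }
    a1 <- a1[keep]; a2 <- a2[keep]
    hol <- mean(a1 != a2)
    p <- table(c(a1, a2)) / (2 * nl)
    # Nei (1987) unbiased gene diversity
    hel <- (nl / (nl - 1)) * (1 - sum(p^2) - hol / (2 * nl))
    ho[l] <- hol; he[l] <- hel
  }
  data.frame(locus = x$loci, n = n, ho = ho, he = he,
             stringsAsFactors = FALSE)
}

#' Heterozygosity and inbreeding statistics per group
#'
#' Observed heterozygosity H_o is the fraction of heterozygous genotypes;
#' expected heterozygosity H_e is Nei's unbiased gene diversity
#' `n/(n-1) * (1 - sum p^2 - H_o/(2n))`; F_IS = 1 - H_o/H_e.  The
#' group-level F_IS is computed from summed components,
#' `1 - sum(H_o)/sum(H_e)` over loci with H_e > 0, which is stabler than
#' averaging per-locus ratios when some loci are nearly monomorphic.
#' Monomorphic loci have H_e = 0 and undefined F_IS; they are excluded
#' from the group F_IS but included in mean H_o / H_e.
#'
#' @param x a [microsat_dataset()].
#' @param grouping `"site"`, `"river"`, or a per-individual label vector.
#' @return list: `per_locus` (data.frame group, locus, n, ho, he, fis) and
#'   `per_group` (data.frame group, n, mean_ho, mean_he, fis).
#' @export
het_stats <- function(x, grouping = "site") {
  g <- group_labels(x, grouping)
  groups <- sort(unique(g))
  pl <- list(); pg <- list()
  for (gr in groups) {
    hc <- het_components(x, which(g == gr))
    hc$fis <- ifelse(!is.na(hc$he) & hc$he > 0, 1 - hc$ho / hc$he, NA_real_)
    pl[[gr]] <- cbind(group = gr, hc, stringsAsFactors = FALSE)
    ok <- !is.na(hc$he)
    pos <- ok & hc$he > 0
    pg[[gr]] <- data.frame(
      group = gr, n = max(hc$n),
      mean_ho = mean(hc$ho[ok]), mean_he = mean(hc$he[ok]),
      fis = if (any(pos)) 1 - sum(hc$ho[pos]) / sum(hc$he[pos]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(per_locus = do.call(rbind, c(pl, list(make.row.names = FALSE))),
       per_group = do.call(rbind, c(pg, list(make.row.names = FALSE))))
}

# P(allele with N_i copies out of N is present in a subsample of g genes),
# exact hypergeometric, computed in log space.
prob_present <- function(Ni, N, g) {
  # 1 - C(N - Ni, g) / C(N, g)
  out <- rep(1, length(Ni))
  ok <- (N - Ni) >= g
  out[ok] <- 1 - exp(lchoose(N - Ni[ok], g) - lchoose(N, g))
  out
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by exact hypergeometric rarefaction:
#' `AR(g) = sum_i [1 - C(N - N_i, g) / C(N, g)]`.
#'
#' @param counts named integer vector of allele counts (gene copies) for
#'   one locus in one group.
#' @param g rarefaction size in gene copies; must not exceed `sum(counts)`.
#' @return expected allele count (>= 1 when data exist and g >= 1).
#' @export
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) stop("rarefaction size g = ", g, " exceeds available genes (",
                  N, ")")
  if (g < 1) stop("g must be >= 1")
  sum(prob_present(as.numeric(counts), N, g))
}

#' Rarefied allelic richness for every group and locus
#'
#' @param ac an [allele_counts()] list.
#' @param g rarefaction size in gene copies: a single number, or `NULL` to
#'   use, per locus, twice the smallest per-group count of complete
#'   genotypes (the usual rarefaction convention, so every group
#'   contributes).
#' @return list: `per_locus` matrix (loci x groups), `mean` named vector of
#'   per-group means over loci, `g_used` per-locus sizes.
#' @export
rarefied_allelic_richness <- function(ac, g = NULL) {
  groups <- attr(ac, "groups")
  L <- length(ac)
  gl <- numeric(L)
  m <- matrix(NA_real_, L, length(groups),
              dimnames = list(names(ac), groups))
  for (l in seq_len(L)) {
    Ns <- vapply(ac[[l]], sum, numeric(1))
    gl[l] <- if (is.null(g)) max(2, min(Ns)) else g
    if (any(Ns < gl[l]))
      stop("g = ", gl[l], " exceeds genes for group(s) ",
           paste(groups[Ns < gl[l]], collapse = ", "),
           " at locus ", names(ac)[l])
    for (j in seq_along(groups))
      m[l, j] <- rarefied_richness(ac[[l]][[j]], gl[l])
  }
  list(per_locus = m, mean = colMeans(m), g_used = gl)
}

#' Rarefied private-allele richness
#'
#' Expected number of alleles private to each group in subsamples of `g`
#' gene copies drawn independently from every group:
#' `PA_g(j) = sum_i P_g(i in j) * prod_{k != j} (1 - P_g(i in k))`.
#' Typically computed at river level (sites pooled) to measure
#' river-specific private alleles.
#'
#' @param ac an [allele_counts()] list (>= 2 groups).
#' @param g rarefaction size: single number or `NULL` (per-locus minimum
#'   rule, as in [rarefied_allelic_richness()]).
#' @return list: `per_locus` matrix (loci x groups), `mean`, `g_used`.
#' @export
rarefied_private_alleles <- function(ac, g = NULL) {
  groups <- attr(ac, "groups")
  if (length(groups) < 2) stop("private alleles need >= 2 groups")
  L <- length(ac)
  gl <- numeric(L)
  m <- matrix(0, L, length(groups), dimnames = list(names(ac), groups))
  for (l in seq_len(L)) {
    cl <- ac[[l]]
    Ns <- vapply(cl, sum, numeric(1))
    gl[l] <- if (is.null(g)) max(2, min(Ns)) else g
    if (any(Ns < gl[l]))
      stop("g = ", gl[l], " exceeds genes for group(s) ",
           paste(groups[Ns < gl[l]], collapse = ", "),
           " at locus ", names(ac)[l])
    alleles <- unique(unlist(lapply(cl, names)))
    # presence probability of each allele in each group's subsample
    pres <- vapply(seq_along(groups), function(j) {
      cnt <- cl[[j]][alleles]
      cnt[is.na(cnt)] <- 0
      prob_present(as.numeric(cnt), Ns[j], gl[l])
    }, numeric(length(alleles)))
    pres <- matrix(pres, nrow = length(alleles))
    for (j in seq_along(groups)) {
      others <- pres[, -j, drop = FALSE]
      m[l, j] <- sum(pres[, j] * apply(1 - others, 1, prod))
    }
  }
  list(per_locus = m, mean = colMeans(m), g_used = gl)
}

# log-probability of a genotype table conditional on allele counts
# (Levene 1949): log P = log(n!) + h log 2 + sum log(c_a!) - log((2n)!)
#                - sum log(n_ab!)
log_table_prob <- function(a1, a2) {
  n <- length(a1)
  h <- sum(a1 != a2)
  geno <- paste(pmin(a1, a2), pmax(a1, a2))
  nab <- table(geno)
  ca <- table(c(a1, a2))
  lgamma(n + 1) + h * log(2) + sum(lgamma(ca + 1)) -
    lgamma(2 * n + 1) - sum(lgamma(nab + 1))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Gene copies are pooled and randomly re-paired into genotypes `n_reps`
#' times (conditioning on the observed allele counts); the p-value is the
#' proportion of permuted tables with conditional probability less than or
#' equal to the observed one (observed table included, so p is never 0).
#'
#' @param a1,a2 allele vectors for one locus in one group (NA = missing).
#' @param n_reps number of Monte-Carlo replicates; `0` returns `NA`.
#' @param min_n minimum non-missing genotypes (default 5), else `NA`.
#' @return p-value in (0, 1], or `NA`.
#' @export
hwe_test <- function(a1, a2, n_reps = 1000, min_n = 5) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < min_n || n_reps < 1) return(NA_real_)
  if (length(unique(c(a1, a2))) < 2) return(NA_real_)  # monomorphic
  obs <- log_table_prob(a1, a2)
  pool <- c(a1, a2)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    perm <- sample(pool)
    p1 <- perm[seq_len(n)]; p2 <- perm[n + seq_len(n)]
    if (log_table_prob(p1, p2) <= obs + 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_reps + 1)
}

#' Null-allele frequency estimators from heterozygosity deficit
#'
#' Chakraborty's `r = (He - Ho) / (He + Ho)` and Brookfield's estimator 1
#' `r = (He - Ho) / (1 + He)`.  Raw values are returned (negative values
#' are not floored); estimates above 0.2 are conventionally treated as
#' evidence of a problematic locus.
#'
#' @param ho,he observed and expected heterozygosity (vectorised).
#' @return data.frame: chakraborty, brookfield, flagged (either estimator
#'   > 0.2). Rows with `he == 0` are `NA`.
#' @export
null_allele_freq <- function(ho, he) {
  chak <- ifelse(he > 0, (he - ho) / (he + ho), NA_real_)
  brook <- ifelse(he > 0, (he - ho) / (1 + he), NA_real_)
  data.frame(chakraborty = chak, brookfield = brook,
             flagged = !is.na(chak) & (chak > 0.2 | brook > 0.2))
}

#' Per-site diversity summary table
#'
#' Convenience wrapper assembling H_o, H_e, F_IS, rarefied allelic
#' richness, rarefied private-allele richness and LD-based effective
#' population size into one per-site table.
#'
#' @param x a [microsat_dataset()] (typically after [qc_filter()]).
#' @param g rarefaction size (see [rarefied_allelic_richness()]).
#' @param ne whether to compute the (comparatively slow) N_e estimate.
#' @param pcrit allele-frequency screening threshold for N_e.
#' @return data.frame keyed by site_id.
#' @export
site_diversity <- function(x, g = NULL, ne = TRUE, pcrit = 0.05) {
  hs <- het_stats(x, "site")
  ac <- allele_counts(x, "site")
  ar <- rarefied_allelic_richness(ac, g)
  pa <- if (length(attr(ac, "groups")) >= 2)
    rarefied_private_alleles(ac, g) else NULL
  out <- data.frame(site_id = hs$per_group$group,
                    n = hs$per_group$n,
                    mean_ho = hs$per_group$mean_ho,
                    mean_he = hs$per_group$mean_he,
                    fis = hs$per_group$fis,
                    allelic_richness = ar$mean[hs$per_group$group],
                    private_alleles =
                      if (is.null(pa)) NA_real_ else
                        pa$mean[hs$per_group$group],
                    stringsAsFactors = FALSE)
  if (ne) {
    nes <- lapply(out$site_id, function(s)
      ne_ld(subset_dataset(x, individuals = x$site == s), pcrit = pcrit))
    out$ne_hat <- vapply(nes, function(z) z$ne, numeric(1))
    out$ne_lo <- vapply(nes, function(z) z$ci[1], numeric(1))
    out$ne_hi <- vapply(nes, function(z) z$ci[2], numeric(1))
  }
  rownames(out) <- NULL
  out
}
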