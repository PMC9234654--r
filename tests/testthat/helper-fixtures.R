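# Shared fixtures and independent oracles ---------------------------------

# build a one-or-more-site dataset from genotype strings like "1/2"
# geno: list(site = list(c("1/1","1/2", ...) per locus?)) -- simpler:
# matrix interface: toy_dataset(site_of_ind, list_of_locus_vectors)
toy_dataset <- function(sites, loci_genos, loci = NULL) {
  n <- length(sites)
  L <- length(loci_genos)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    gs <- loci_genos[[l]]
    stopifnot(length(gs) == n)
    for (i in seq_len(n)) {
      if (is.na(gs[i])) next
      parts <- as.integer(strsplit(gs[i], "/", fixed = TRUE)[[1]])
      a1[i, l] <- parts[1]; a2[i, l] <- parts[2]
    }
  }
  usites <- unique(sites)
  ids <- paste0(sites, "_", stats::ave(seq_len(n), sites, FUN = seq_along))
  microsat_dataset(ids, sites,
                   if (is.null(loci)) paste0("L", seq_len(L)) else loci,
                   a1, a2,
                   setNames(usites, usites),
                   setNames(rep("C1", length(usites)), usites))
}

# random multi-population dataset (no missing data unless asked)
random_dataset <- function(seed, n_pops = 3, n_per_pop = 8, n_loci = 2,
                           n_alleles = 4, miss_rate = 0) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  sites <- rep(paste0("P", seq_len(n_pops)), each = n_per_pop)
  a1 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  a2 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  if (miss_rate > 0) {
    drop <- matrix(runif(n * n_loci) < miss_rate, n, n_loci)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  usites <- unique(sites)
  microsat_dataset(paste0(sites, "_", seq_len(n)), sites,
                   paste0("L", seq_len(n_loci)), a1, a2,
                   setNames(usites, usites),
                   setNames(rep("C1", length(usites)), usites))
}

# -- independent rarefaction oracle: enumerate every g-subset of the gene
#    copies and count distinct alleles (never touches the package's
#    hypergeometric closed form)
brute_force_ar <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# brute-force private alleles for two groups: enumerate subsample pairs
brute_force_pa <- function(counts1, counts2, g) {
  alleles <- union(names(counts1), names(counts2))
  genes1 <- rep(names(counts1), counts1)
  genes2 <- rep(names(counts2), counts2)
  s1 <- utils::combn(length(genes1), g)
  s2 <- utils::combn(length(genes2), g)
  pa1 <- 0
  for (i in seq_len(ncol(s1))) for (j in seq_len(ncol(s2))) {
    seen1 <- unique(genes1[s1[, i]])
    seen2 <- unique(genes2[s2[, j]])
    pa1 <- pa1 + length(setdiff(seen1, seen2))
  }
  pa1 / (ncol(s1) * ncol(s2))
}

# -- independently coded Weir-Cockerham component calculator (naive loops,
#    genotype-level input) used as the theta oracle
oracle_wc_theta <- function(x, g) {
  num <- 0; den <- 0
  for (l in seq_along(x$loci)) {
    a1 <- x$allele1[, l]; a2 <- x$allele2[, l]
    keep <- !is.na(a1)
    gg <- g[keep]; b1 <- a1[keep]; b2 <- a2[keep]
    pops <- names(which(table(gg) >= 2))
    if (length(pops) < 2) next
    inpop <- gg %in% pops
    gg <- gg[inpop]; b1 <- b1[inpop]; b2 <- b2[inpop]
    alleles <- unique(c(b1, b2))
    if (length(alleles) < 2) next
    r <- length(pops)
    ni <- sapply(pops, function(p) sum(gg == p))
    nbar <- sum(ni) / r
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      pi <- sapply(pops, function(p) {
        ix <- gg == p
        (sum(b1[ix] == al) + sum(b2[ix] == al)) / (2 * sum(ix))
      })
      hi <- sapply(pops, function(p) {
        ix <- gg == p
        sum((b1[ix] == al) != (b2[ix] == al)) / sum(ix)
      })
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# small study-bundle fixture without simulation
tiny_bundle_tables <- function() {
  md <- site_metadata(data.frame(
    site_id = c("S1", "S2"), river = c("R1", "R1"),
    catchment = c("C1", "C1"), distance_from_source = c(1, 5),
    wwtp_upstream = c(FALSE, TRUE), conductivity = c(300, 500),
    ph = c(7.8, 7.9), oxygen_saturation = c(99, 85),
    abundance = c(40, 25)))
  tis <- concentration_table(
    matrix(c(1, 2.5, 0, 4), 2, 2,
           dimnames = list(c("S1", "S2"), c("cmpA", "cmpB"))), "tissue")
  cp <- compound_properties(data.frame(
    compound = c("cmpA", "cmpB"),
    application_class = c("pesticide", "pharmaceutical"),
    log_dow = c(1, 2)))
  lc <- lc50_table(data.frame(
    compound = c("cmpA", "cmpA", "cmpB"),
    species = c("Gammarus pulex", "Gammarus pulex", "Daphnia magna"),
    duration_h = c(24, 48, 48), lc50 = c(10, 20, 100)))
  dm <- distance_matrix(matrix(c(0, 4, 4, 0), 2, 2,
                               dimnames = list(c("S1", "S2"),
                                               c("S1", "S2"))))
  list(metadata = md, tissue = tis, compounds = cp, lc50 = lc,
       distances = dm)
}
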