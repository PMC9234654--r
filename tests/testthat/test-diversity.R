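# Per-site diversity statistics

test_that("QC removes individuals then loci above the missingness
           threshold", {
  # 16 loci; ind 1 misses 4 (25% -> removed), ind 2 misses 3 (18.75% ->
  # retained)
  genos <- lapply(1:16, function(l) {
    g <- rep("1/2", 4)
    if (l <= 4) g[1] <- NA
    if (l <= 3) g[2] <- NA
    g
  })
  d <- toy_dataset(rep("S1", 4), genos)
  qc <- qc_filter(d, max_missing = 0.20)
  expect_equal(qc$removed_individuals, "S1_1")
  expect_equal(n_individuals(qc$dataset), 3)
  # the cascade then re-evaluates loci on the 3 retained individuals:
  # loci 1-3 are each missing in 1/3 of them (> 20%), locus 4 only in
  # the removed individual
  expect_equal(qc$removed_loci, c("L1", "L2", "L3"))
  # a locus missing in 2 of 6 individuals (33%) is dropped while every
  # individual stays below the threshold (1 of 6 loci missing each)
  genos2 <- c(list(c(NA, NA, rep("1/2", 4))),
              replicate(5, rep("1/1", 6), simplify = FALSE))
  d2 <- toy_dataset(rep("S1", 6), genos2)
  qc2 <- qc_filter(d2, max_missing = 0.20)
  expect_length(qc2$removed_individuals, 0)
  expect_equal(qc2$removed_loci, "L1")
  all_bad <- toy_dataset(rep("S1", 2), list(c(NA, NA), c(NA, NA)))
  expect_error(qc_filter(all_bad), "all individuals")
})

test_that("heterozygosity follows the unbiased estimator", {
  d <- toy_dataset(rep("S1", 4), list(c("1/1", "1/2", "2/2", "1/2")))
  hs <- het_stats(d, "site")
  pg <- hs$per_group
  expect_equal(pg$mean_ho, 0.5)
  expect_equal(pg$mean_he, (4 / 3) * (1 - 0.5 - 0.5 / 8))
  expect_equal(pg$fis, 1 - 0.5 / pg$mean_he)
  # all heterozygous -> F_IS < 0
  d2 <- toy_dataset(rep("S1", 5), list(rep("1/2", 5)))
  pg2 <- het_stats(d2, "site")$per_group
  expect_equal(pg2$mean_ho, 1)
  expect_lt(pg2$fis, 0)
  # monomorphic locus
  d3 <- toy_dataset(rep("S1", 5), list(rep("3/3", 5)))
  pl3 <- het_stats(d3, "site")$per_locus
  expect_equal(pl3$ho, 0)
  expect_equal(pl3$he, 0)
  expect_true(is.na(pl3$fis))
})

test_that("unbiased H_e converges to the plug-in value at large n", {
  set.seed(31)
  n <- 1e4
  p <- c(0.4, 0.3, 0.2, 0.1)
  a1 <- sample.int(4, n, TRUE, p); a2 <- sample.int(4, n, TRUE, p)
  d <- toy_dataset(rep("S1", n),
                   list(paste0(pmin(a1, a2), "/", pmax(a1, a2))))
  he <- het_stats(d, "site")$per_group$mean_he
  phat <- table(c(a1, a2)) / (2 * n)
  expect_lt(abs(he - (1 - sum(phat^2))), 1e-3)
})

test_that("closed-form rarefaction equals enumeration and obeys bounds", {
  expect_equal(rarefied_richness(c(A = 2, B = 2), 2), 5 / 3)
  expect_equal(brute_force_ar(c(2, 2), 2), 5 / 3)
  set.seed(17)
  for (k in 1:10) {
    counts <- as.vector(table(sample.int(4, sample(4:12, 1), TRUE)))
    N <- sum(counts)
    g <- sample(seq_len(N), 1)
    expect_equal(rarefied_richness(counts, g), brute_force_ar(counts, g),
                 tolerance = 1e-12)
  }
  expect_equal(rarefied_richness(c(X = 9), 3), 1)      # monomorphic
  expect_equal(rarefied_richness(c(2, 3, 4), 9), 3)    # g = N identity
  ar_g <- vapply(1:9, function(g) rarefied_richness(c(2, 3, 4), g),
                 numeric(1))
  expect_true(all(diff(ar_g) >= 0))                    # monotone in g
  expect_true(all(ar_g <= 3))
  expect_error(rarefied_richness(c(2, 2), 5), "exceeds")
})

test_that("private-allele rarefaction matches enumeration and AR bound", {
  ac <- structure(list(L1 = list(P1 = c(A = 2, B = 2), P2 = c(A = 4))),
                  groups = c("P1", "P2"))
  names(ac) <- "L1"
  pa <- rarefied_private_alleles(ac, g = 2)
  expect_equal(pa$per_locus["L1", "P1"], 5 / 6)
  expect_equal(brute_force_pa(c(A = 2, B = 2), c(A = 4), 2), 5 / 6)
  # allele absent from focal group contributes nothing; symmetry when
  # counts coincide
  ac2 <- structure(list(L1 = list(P1 = c(A = 3, B = 3),
                                  P2 = c(A = 3, B = 3))),
                   groups = c("P1", "P2"))
  pa2 <- rarefied_private_alleles(ac2, g = 4)
  expect_equal(pa2$per_locus["L1", "P1"], pa2$per_locus["L1", "P2"])
  set.seed(23)
  for (k in 1:5) {
    c1 <- table(sample(LETTERS[1:3], sample(4:8, 1), TRUE))
    c2 <- table(sample(LETTERS[2:4], sample(4:8, 1), TRUE))
    g <- 3
    acr <- structure(list(L = list(P1 = c(c1), P2 = c(c2))),
                     groups = c("P1", "P2"))
    pa_k <- rarefied_private_alleles(acr, g)$per_locus[1, ]
    expect_equal(unname(pa_k["P1"]), brute_force_pa(c(c1), c(c2), g),
                 tolerance = 1e-12)
    ar_k <- rarefied_allelic_richness(acr, g)$per_locus[1, ]
    expect_true(all(pa_k <= ar_k + 1e-12))
  }
})

test_that("Monte-Carlo HWE test is calibrated and directional", {
  set.seed(41)
  # under random mating p-values should not pile up near 0
  ps <- replicate(60, {
    a1 <- sample.int(3, 40, TRUE); a2 <- sample.int(3, 40, TRUE)
    hwe_test(a1, a2, n_reps = 200)
  })
  expect_gt(mean(ps > 0.05), 0.8)
  # a sample of only homozygotes at a common 2-allele locus is extreme
  a <- rep(c(1L, 2L), 25)
  expect_lt(hwe_test(a, a, n_reps = 1000), 0.01)
  expect_true(is.na(hwe_test(a, a, n_reps = 0)))
  expect_true(is.na(hwe_test(1:2, 1:2, n_reps = 100)))   # n < 5
})

test_that("null-allele estimators reproduce hand arithmetic", {
  r <- null_allele_freq(0.5, 0.5833333)
  expect_equal(r$chakraborty, (0.5833333 - 0.5) / (0.5833333 + 0.5),
               tolerance = 1e-6)
  expect_equal(r$brookfield, (0.5833333 - 0.5) / 1.5833333,
               tolerance = 1e-6)
  expect_equal(null_allele_freq(0.4, 0.4)$chakraborty, 0)
  expect_equal(null_allele_freq(0, 0.5)$chakraborty, 1)
  expect_true(is.na(null_allele_freq(0, 0)$chakraborty))
  expect_true(null_allele_freq(0.1, 0.6)$flagged)
})

test_that("site_diversity assembles a coherent per-site table", {
  d <- random_dataset(5, n_pops = 3, n_per_pop = 10, n_loci = 5,
                      n_alleles = 5)
  tab <- site_diversity(d, ne = FALSE)
  expect_equal(tab$site_id, c("P1", "P2", "P3"))
  expect_true(all(tab$mean_ho >= 0 & tab$mean_ho <= 1))
  expect_true(all(tab$mean_he >= 0 & tab$mean_he <= 1))
  expect_true(all(tab$allelic_richness >= 1))
  expect_true(all(tab$private_alleles <= tab$allelic_richness))
})
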