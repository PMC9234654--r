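# Synthetic study generator
#
# Several directional checks run on deliberately small configurations
# (fewer loci / shorter histories than the default) so the whole file
# stays fast; the full-scale default configuration is exercised by the
# end-to-end acceptance tests.

small_cfg <- function(...) {
  sim_config(sites_per_river = c(3, 3), n_catchments = 1,
             rivers_per_catchment = 2, n_loci = 6,
             catchment_divergence = 50, river_divergence = 40,
             generations = 60, ind_per_site = c(12, 16), ...)
}

test_that("the default configuration echoes the survey design", {
  pol <- simulate_pollution(sim_config(), seed = 3)
  expect_equal(nrow(pol$metadata), 34)
  expect_equal(length(unique(pol$metadata$river)), 6)
  expect_equal(length(unique(pol$metadata$catchment)), 3)
  expect_true(all(pol$pollution >= 0 & pol$pollution <= 1))
  expect_s3_class(pol$distances, "distance_matrix")
  gen <- simulate_genotypes(sim_config(), pol$pollution, pol$metadata,
                            seed = 4)
  expect_equal(length(gen$dataset$loci), 16)
  ns <- table(gen$dataset$site)
  expect_true(all(ns >= 10 & ns <= 30))
  expect_equal(sort(names(ns)), sort(pol$metadata$site_id))
})

test_that("identical seeds give identical bundles", {
  a <- simulate_pollution(sim_config(), seed = 11)
  b <- simulate_pollution(sim_config(), seed = 11)
  expect_identical(a$tissue$values, b$tissue$values)
  expect_identical(a$metadata, b$metadata)
  ga <- simulate_genotypes(small_cfg(), a$pollution[1:6],
                           a$metadata[1:6, ], seed = 12)
  gb <- simulate_genotypes(small_cfg(), a$pollution[1:6],
                           a$metadata[1:6, ], seed = 12)
  expect_identical(ga$dataset$allele1, gb$dataset$allele1)
})

test_that("pollution jumps downstream of a WWTP", {
  pol <- simulate_pollution(sim_config(), seed = 13)
  md <- pol$metadata
  for (r in unique(md$river)) {
    rows <- md[md$river == r, ]
    first_wwtp <- which(rows$wwtp_upstream)[1]
    expect_gt(pol$pollution[rows$site_id[first_wwtp]],
              pol$pollution[rows$site_id[first_wwtp - 1]])
  }
})

test_that("concentrations follow the stated lognormal around the
           pollution-scaled mean", {
  cfgs <- sim_config()
  logs <- numeric(0)
  for (s in 1:25) {
    pol <- simulate_pollution(cfgs, seed = 3000 + s)
    v <- pol$tissue$values[, "benzotriazole"]
    mu <- 2000 * 10^(2.5 * (pol$pollution - 1))
    det <- v > 0
    logs <- c(logs, log(v[det]) - log(mu[det]))
  }
  expect_lt(abs(mean(logs)), 0.1)
  expect_lt(abs(sd(logs) - 0.5), 0.05)
})

test_that("LC50 coverage exercises every selection branch", {
  pol <- simulate_pollution(sim_config(), seed = 15)
  lc <- pol$lc50
  species <- vapply(pol$compounds$compound, function(cm) {
    v <- select_lc50(cm, lc)
    if (is.na(v)) "none" else if (
      length(lc$lc50[lc$compound == cm &
                       lc$species == "Gammarus pulex" &
                       lc$duration_h %in% c(24, 48)])) "target"
    else "fallback"
  }, character(1))
  expect_true(all(c("target", "fallback", "none") %in% species))
})

test_that("strong mixing approaches panmixia within a river", {
  cfg <- sim_config(n_catchments = 1, rivers_per_catchment = 1,
                    sites_per_river = 4, n_loci = 16,
                    catchment_divergence = 30, river_divergence = 30,
                    generations = 120, m = 0.5, gamma = 0, wahlund_w = 0,
                    ind_per_site = c(30, 30), ne_base = 400)
  pol <- simulate_pollution(cfg, seed = 17)
  gen <- simulate_genotypes(cfg, pol$pollution, pol$metadata, seed = 18)
  fm <- fst_matrix(gen$dataset, "site")
  # theta ~ 0 up to 16-locus estimation noise
  expect_lt(mean(abs(fm$pairs$theta)), 0.01)
  expect_lt(max(abs(fm$pairs$theta)), 0.02)
})

test_that("longer isolation increases between-river differentiation", {
  theta_at <- function(gens, seed) {
    cfg <- sim_config(n_catchments = 1, rivers_per_catchment = 2,
                      sites_per_river = c(2, 2), n_loci = 8,
                      catchment_divergence = 20, river_divergence = 10,
                      generations = gens, m = 0, gamma = 0,
                      wahlund_w = 0, wahlund_split = 0,
                      ind_per_site = c(25, 25), ne_base = 80)
    pol <- simulate_pollution(cfg, seed = seed)
    gen <- simulate_genotypes(cfg, pol$pollution, pol$metadata,
                              seed = seed + 1)
    fst_matrix(gen$dataset, "river")$pairs$theta
  }
  short <- mean(sapply(1:4, function(s) theta_at(10, 100 + s)))
  long <- mean(sapply(1:4, function(s) theta_at(250, 200 + s)))
  expect_gt(long, short)
})

test_that("pollution-scaled drift erodes allelic richness", {
  # reduced replicate count at reduced scale: assert the mean rank
  # correlation is significantly negative rather than counting signs
  # (the full-scale sign-frequency check lives in the acceptance suite)
  set.seed(61)
  rhos <- replicate(12, {
    cfg <- small_cfg(gamma = 1.2, m = 0.01)
    seed <- sample.int(1e6, 1)
    pol <- simulate_pollution(cfg, seed = seed)
    gen <- simulate_genotypes(cfg, pol$pollution, pol$metadata,
                              seed = seed + 1)
    ar <- rarefied_allelic_richness(allele_counts(gen$dataset, "site"))
    cor(ar$mean[gen$truth$site_id], gen$truth$pollution,
        method = "spearman")
  })
  upper <- mean(rhos) + qt(0.95, 11) * sd(rhos) / sqrt(12)
  expect_lt(upper, 0)
})

test_that("without pollution effects there is no diversity trend", {
  set.seed(71)
  slopes <- replicate(12, {
    cfg <- small_cfg(gamma = 0, wahlund_w = 0)
    seed <- sample.int(1e6, 1)
    pol <- simulate_pollution(cfg, seed = seed)
    gen <- simulate_genotypes(cfg, pol$pollution, pol$metadata,
                              seed = seed + 1)
    ar <- rarefied_allelic_richness(allele_counts(gen$dataset, "site"))
    unname(coef(lm(ar$mean[gen$truth$site_id] ~ gen$truth$pollution))[2])
  })
  ci <- mean(slopes) + c(-1, 1) * qt(0.975, 11) * sd(slopes) / sqrt(12)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("the Wahlund mixture inflates F_IS (paired replicates)", {
  diffs <- replicate(8, {
    seed <- sample.int(1e6, 1)
    cfg_w <- small_cfg(wahlund_w = 0.3, wahlund_threshold = 0)
    cfg_0 <- small_cfg(wahlund_w = 0, wahlund_threshold = 0)
    pol <- simulate_pollution(cfg_w, seed = seed)
    gw <- simulate_genotypes(cfg_w, pol$pollution, pol$metadata,
                             seed = seed + 1)
    g0 <- simulate_genotypes(cfg_0, pol$pollution, pol$metadata,
                             seed = seed + 1)
    mean(het_stats(gw$dataset, "site")$per_group$fis) -
      mean(het_stats(g0$dataset, "site")$per_group$fis)
  })
  expect_gt(mean(diffs > 0), 0.7)
  expect_gt(mean(diffs), 0)
})

test_that("extreme pollution sensitivity errors out rather than
           simulating a vanishing deme", {
  cfg <- small_cfg(gamma = 12, ne_base = 20)
  pol <- simulate_pollution(cfg, seed = 19)
  expect_error(simulate_genotypes(cfg, pol$pollution, pol$metadata,
                                  seed = 20), "too extreme")
})

test_that("emitted files re-parse to the in-memory objects", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  generate_study(cfg, seed = 23, out_dir = dir)
  sim <- simulate_study(cfg, seed = 23)
  ds <- read_genepop(file.path(dir, "genotypes.gen"))
  expect_equal(ds$allele1, sim$dataset$allele1)
  expect_equal(ds$site, sim$dataset$site)
  b <- read_study_tables(metadata = file.path(dir, "metadata.csv"),
                         tissue = file.path(dir, "tissue.csv"),
                         water = file.path(dir, "water.csv"),
                         compounds = file.path(dir, "compounds.csv"),
                         lc50 = file.path(dir, "lc50.csv"),
                         distances = file.path(dir, "distances.csv"))
  expect_equal(b$tissue$values, sim$bundle$tissue$values,
               tolerance = 1e-6)
  expect_equal(b$metadata$site_id, sim$bundle$metadata$site_id)
  expect_equal(b$distances$values, sim$bundle$distances$values,
               tolerance = 1e-6)
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 23)
  expect_equal(manifest$n_loci, 6)
})
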