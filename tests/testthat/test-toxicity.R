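# Toxic-unit scoring

test_that("LC50 aggregation pools 24/48 h records with species fallback", {
  lc <- lc50_table(data.frame(
    compound = c("a", "a", "a", "b", "c", "c"),
    species = c("Gammarus pulex", "Gammarus pulex", "Daphnia magna",
                "Daphnia magna", "Gammarus pulex", "Gammarus pulex"),
    duration_h = c(24, 48, 48, 48, 96, 72),
    lc50 = c(10, 20, 999, 100, 5, 7)))
  expect_equal(select_lc50("a", lc), 15)       # target mean, no fallback mix
  expect_equal(select_lc50("b", lc), 100)      # fallback only
  expect_true(is.na(select_lc50("c", lc)))     # only non-24/48 h records
  expect_true(is.na(select_lc50("zzz", lc)))   # absent entirely
})

test_that("equilibrium partitioning arithmetic and properties hold", {
  expect_equal(freely_dissolved(0, 0.0134, 2), 0)
  # C/(f_lipid * 10^logD): 134/(0.0134*1000) = 10 ug/L under the
  # ng/g-wet == ug/L unit bridge
  expect_equal(freely_dissolved(134, 0.0134, 3), 10)
  x <- freely_dissolved(7, 0.0134, 1.3)
  expect_equal(freely_dissolved(14, 0.0134, 1.3), 2 * x)  # linearity
  expect_gt(freely_dissolved(5, 0.0134, 1), freely_dissolved(5, 0.0134, 2))
  expect_error(freely_dissolved(1, 0, 1), "positive")
})

test_that("toxic_units reproduces hand arithmetic and handles degeneracy", {
  cfg <- toxicity_config()
  # choose c_tissue so cfd = 0.5 at log_dow = 0: c = 0.5 * 0.0134
  tis <- concentration_table(
    matrix(c(0.5 * 0.0134, 0), 2, 1,
           dimnames = list(c("S1", "S2"), "a")), "tissue")
  cp <- compound_properties(data.frame(compound = "a",
                                       application_class = "pesticide",
                                       log_dow = 0))
  lc <- lc50_table(data.frame(compound = "a", species = "Gammarus pulex",
                              duration_h = 48, lc50 = 50))
  tu <- toxic_units(tis, cp, lc, cfg)
  s1 <- tu$per_site[tu$per_site$site_id == "S1", ]
  expect_equal(s1$sum_tu, 0.01)
  expect_equal(s1$log10_sum_tu, -2)
  s2 <- tu$per_site[tu$per_site$site_id == "S2", ]
  expect_equal(s2$sum_tu, 0)                 # nothing detected
  expect_true(is.na(s2$log10_sum_tu))
})

test_that("class shares are symmetric and sum to one; skipped compounds
           are reported", {
  tis <- concentration_table(
    matrix(c(1, 2, 5), 1, 3,
           dimnames = list("S1", c("a", "b", "c"))), "tissue")
  cp <- compound_properties(data.frame(
    compound = c("a", "b", "c"),
    application_class = c("pesticide", "pharmaceutical", "industrial"),
    log_dow = c(1, 1, 1)))
  lc <- lc50_table(data.frame(compound = c("a", "b"),
                              species = "Gammarus pulex",
                              duration_h = 48, lc50 = c(10, 20)))
  tu <- toxic_units(tis, cp, lc)
  ps <- tu$per_site
  # b has double the tissue burden but double the LC50 -> equal TU
  expect_equal(ps$share_pesticide, ps$share_pharmaceutical)
  shares <- ps[, grepl("^share_", names(ps))]
  expect_equal(sum(shares, na.rm = TRUE), 1)
  expect_equal(tu$compounds_skipped, "c")    # detected but no LC50
})

test_that("summed TU scales as 1/c when every LC50 is scaled by c and is
           order-invariant", {
  set.seed(7)
  cmp <- paste0("c", 1:6)
  tis_m <- matrix(runif(18, 0, 50), 3, 6,
                  dimnames = list(paste0("S", 1:3), cmp))
  cp <- compound_properties(data.frame(
    compound = cmp,
    application_class = sample(c("pesticide", "biocide"), 6, TRUE),
    log_dow = runif(6, -1, 3)))
  lc <- lc50_table(data.frame(compound = cmp, species = "Gammarus pulex",
                              duration_h = 48, lc50 = runif(6, 5, 500)))
  base <- toxic_units(concentration_table(tis_m, "tissue"), cp, lc)
  lc3 <- lc; lc3$lc50 <- lc3$lc50 * 3
  scaled <- toxic_units(concentration_table(tis_m, "tissue"), cp, lc3)
  expect_equal(scaled$per_site$sum_tu, base$per_site$sum_tu / 3)
  perm <- sample(6)
  reord <- toxic_units(concentration_table(tis_m[, perm], "tissue"),
                       cp, lc)
  expect_equal(reord$per_site$sum_tu, base$per_site$sum_tu)
})

test_that("threshold classification is strict at both boundaries", {
  expect_equal(classify_toxicity(c(0.02, 0.005, 0, 0.01, 0.001, 0.0101)),
               c("acute", "chronic", "below", "chronic", "below", "acute"))
  expect_true(is.na(classify_toxicity(NA_real_)))
})

test_that("total_aom sums compounds with a log10 companion", {
  tis <- concentration_table(
    matrix(c(1, 0, 2.5, 0, 40, 60), 2, 3,
           dimnames = list(c("S1", "S2"), c("a", "b", "c"))), "tissue")
  tot <- total_aom(tis)
  expect_equal(tot$total, c(43.5, 60))
  tis0 <- concentration_table(matrix(c(100, 0), 2, 1,
                                     dimnames = list(c("S1", "S2"), "a")),
                              "tissue")
  tot0 <- total_aom(tis0)
  expect_equal(tot0$log10_total, c(2, NA))
  # independent spreadsheet-style summation over a simulated table
  pol <- simulate_pollution(sim_config(), seed = 21)
  tot_pkg <- total_aom(pol$tissue)
  by_hand <- apply(pol$tissue$values, 1, function(r) sum(r))
  expect_equal(setNames(tot_pkg$total, tot_pkg$site_id), by_hand)
})
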