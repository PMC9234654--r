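# Synthetic study generator ----------------------------------------------
#
# Emulates a regional river survey: rivers nested in catchments, sites
# ordered downstream, pollution rising below wastewater treatment plants
# (WWTP), and genotypes produced by a forward Wright-Fisher stepping-stone
# model in which local drift intensifies with pollution
# (Ne(site) = ne_base * exp(-gamma * pollution)).  Heterozygote deficits at
# polluted sites are induced by a Wahlund mixture: a hidden, unconnected
# deme contributes a fraction w of the sampled individuals.

#' Simulation configuration
#'
#' Defaults encode the emulated survey design: 3 catchments x 2 rivers,
#' 34 sites in total, 16 loci, 20-30 genotyped individuals per site, and a
#' pollution effect on local effective size.  Migration and divergence
#' times are set so that between-river differentiation is strong and
#' within-river differentiation is weak but non-zero, the regime the
#' survey design implies.
#'
#' @param n_catchments number of catchments.
#' @param rivers_per_catchment rivers per catchment.
#' @param sites_per_river integer vector recycled over rivers (4-7 each;
#'   defaults sum to 34).
#' @param ind_per_site length-2 range; per-site sample sizes are drawn
#'   uniformly from it.
#' @param n_loci number of microsatellite loci.
#' @param founder_alleles distinct alleles per locus at founding.
#' @param ne_founder effective size of founder pools during divergence.
#' @param catchment_divergence,river_divergence drift generations
#'   separating catchment pools and rivers within a catchment.
#' @param generations stepping-stone generations at the site level.
#' @param m per-generation migration rate between adjacent sites.
#' @param ne_base baseline site effective size at zero pollution.
#' @param gamma pollution sensitivity of local size:
#'   `Ne = ne_base * exp(-gamma * pollution)` with pollution in `[0, 1]`.
#' @param wahlund_w mixture fraction from the hidden deme at polluted
#'   sites (pollution > `wahlund_threshold`); 0 disables.
#' @param wahlund_threshold pollution score above which a site carries
#'   internal substructure.
#' @param wahlund_split generations before sampling at which the hidden
#'   deme splits off its site deme.  A recent split diverges allele
#'   frequencies enough to depress heterozygosity in the mixed sample
#'   while importing essentially no novel alleles, matching the observed
#'   pattern of jointly reduced richness and elevated inbreeding at
#'   polluted sites.
#' @param mu stepwise mutation rate per gene copy per generation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_catchments = 3, rivers_per_catchment = 2,
                       sites_per_river = c(5, 6, 6, 5, 6, 6),
                       ind_per_site = c(20, 30),
                       n_loci = 16, founder_alleles = 8,
                       ne_founder = 500,
                       catchment_divergence = 300, river_divergence = 100,
                       generations = 150, m = 0.03,
                       ne_base = 150, gamma = 1.2,
                       wahlund_w = 0.2, wahlund_threshold = 0.6,
                       wahlund_split = 40, mu = 5e-4) {
  n_rivers <- n_catchments * rivers_per_catchment
  sites_per_river <- rep(sites_per_river, length.out = n_rivers)
  stopifnot(all(sites_per_river >= 2),
            m >= 0, m <= 1, mu >= 0, mu <= 1,
            wahlund_w >= 0, wahlund_w < 1,
            wahlund_split >= 0, wahlund_split <= generations,
            ne_base >= 2, ne_founder >= 2, founder_alleles >= 2)
  structure(list(n_catchments = n_catchments,
                 rivers_per_catchment = rivers_per_catchment,
                 sites_per_river = sites_per_river,
                 ind_per_site = ind_per_site, n_loci = n_loci,
                 founder_alleles = founder_alleles,
                 ne_founder = ne_founder,
                 catchment_divergence = catchment_divergence,
                 river_divergence = river_divergence,
                 generations = generations, m = m, ne_base = ne_base,
                 gamma = gamma, wahlund_w = wahlund_w,
                 wahlund_threshold = wahlund_threshold,
                 wahlund_split = wahlund_split, mu = mu),
            class = "sim_config")
}

# -- compound catalogue ---------------------------------------------------
# A fixed, synthetic catalogue shaped like the mixtures reported from
# central-European rivers: insecticides dominate toxicity (low LC50),
# industrial chemicals and pharmaceuticals dominate mass.  LC50 coverage
# deliberately includes target-species records, fallback-only records and
# compounds with no records at all.
sim_compound_catalogue <- function() {
  cmp <- data.frame(
    compound = c("acetamiprid", "imidacloprid", "thiacloprid",
                 "clothianidin", "pendimethalin", "metazachlor",
                 "acetaminophen", "citalopram", "diclofenac",
                 "carbamazepine", "benzotriazole", "melamine",
                 "tripropylphosphate", "acesulfame", "cyclamate",
                 "benzalkonium", "decylsulfate", "guanylurea"),
    application_class = c(rep("pesticide", 6),
                          rep("pharmaceutical", 4),
                          rep("industrial", 3),
                          rep("food ingredient", 2),
                          "biocide", "surfactant",
                          "transformation product"),
    log_dow = c(0.80, 0.57, 1.26, 0.91, 5.18, 2.13,
                0.46, 1.39, 1.10, 2.45, 1.44, -1.37,
                1.87, -1.33, -1.61, 2.93, 1.60, -1.56),
    # lognormal mean tissue burden (ng/g wet) at full pollution; the
    # hydrophilic insecticides carry the toxicity, bulk industrial /
    # household chemicals carry the mass (most have no usable LC50)
    tissue_scale = c(0.6, 0.3, 0.3, 0.3, 800, 150,
                     0.15, 0.8, 8, 20, 2000, 1500,
                     400, 300, 200, 20, 10, 200),
    # lognormal mean water concentration (ug/L) at full pollution
    water_scale = c(0.08, 0.06, 0.03, 0.02, 0.05, 0.4,
                    1.5, 0.3, 0.8, 0.6, 6, 3,
                    0.5, 4, 2, 0.3, 0.6, 2),
    stringsAsFactors = FALSE)
  lc <- rbind(
    # target-species 24/48 h records: insecticides acutely toxic
    data.frame(compound = c("acetamiprid", "acetamiprid", "imidacloprid",
                            "thiacloprid", "clothianidin",
                            "acetaminophen", "citalopram",
                            "pendimethalin", "metazachlor"),
               species = "Gammarus pulex",
               duration_h = c(24, 48, 48, 48, 48, 48, 24, 48, 48),
               lc50 = c(60, 40, 120, 90, 150, 800, 1200, 900, 6000),
               stringsAsFactors = FALSE),
    # fallback-only records
    data.frame(compound = c("diclofenac", "carbamazepine", "benzalkonium",
                            "decylsulfate"),
               species = "Daphnia magna",
               duration_h = c(48, 48, 48, 24),
               lc50 = c(22000, 13000, 300, 5000),
               stringsAsFactors = FALSE),
    # a 96 h record that must be ignored by the 24/48 h rule
    data.frame(compound = "benzotriazole", species = "Gammarus pulex",
               duration_h = 96, lc50 = 10000, stringsAsFactors = FALSE))
  list(compounds = compound_properties(
         cmp[, c("compound", "application_class", "log_dow")]),
       scales = cmp[, c("compound", "tissue_scale", "water_scale")],
       lc50 = lc50_table(lc))
}

#' Simulate site layout, pollution and chemistry tables
#'
#' Sites are laid out downstream along each river; a WWTP is placed after
#' the first one or two sites (those upstream form the reference set) and
#' a second one further down on longer rivers.  The latent pollution score
#' rises gently with distance (diffuse run-off) and jumps below each WWTP,
#' and drives lognormal compound concentrations, conductivity, oxygen
#' deficit and amphipod abundance.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory: a bundle is its seed).
#' @return list: `metadata` ([site_metadata()]), `tissue`, `water`
#'   ([concentration_table()]s), `compounds`, `lc50`, `distances`
#'   (waterway [distance_matrix()]), `pollution` (named per-site latent
#'   score in `[0, 1]`).
#' @export
simulate_pollution <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n_rivers <- config$n_catchments * config$rivers_per_catchment
  river_names <- paste0("R", seq_len(n_rivers))
  catchments <- paste0("C", rep(seq_len(config$n_catchments),
                                each = config$rivers_per_catchment))
  md <- list(); pollution <- numeric(0)
  for (r in seq_len(n_rivers)) {
    K <- config$sites_per_river[r]
    sid <- paste0(river_names[r], "S", seq_len(K))
    dist_km <- cumsum(runif(K, 1.5, 4))
    n_ref <- sample(1:2, 1)                   # sites upstream of first WWTP
    wwtp_after <- n_ref
    wwtp2 <- if (K >= 6) wwtp_after + 2 else NA
    wwtp_up <- seq_len(K) > wwtp_after
    base <- 0.08 + 0.25 * (seq_len(K) - 1) / max(1, K - 1)
    jump <- 0.35 * wwtp_up
    if (!is.na(wwtp2)) jump <- jump + 0.2 * (seq_len(K) > wwtp2)
    score <- pmin(1, pmax(0, base + jump + rnorm(K, 0, 0.04)))
    pollution <- c(pollution, setNames(score, sid))
    md[[r]] <- data.frame(
      site_id = sid, river = river_names[r], catchment = catchments[r],
      distance_from_source = round(dist_km, 2),
      wwtp_upstream = wwtp_up,
      conductivity = round(300 + 600 * score + rnorm(K, 0, 40)),
      ph = round(rnorm(K, 7.8, 0.15), 2),
      oxygen_saturation = round(pmin(110, 100 - 25 * score +
                                       rnorm(K, 0, 5)), 1),
      abundance = NA_real_,
      stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, md)
  # abundance: unimodal in pollution (nutrients help until toxicity bites)
  md$abundance <- round(exp(3.2 + 1.2 * pollution - 2.2 * pollution^2 +
                              rnorm(nrow(md), 0, 0.35)))

  cat_tabs <- sim_compound_catalogue()
  cmp <- cat_tabs$compounds; sc <- cat_tabs$scales
  n_sites <- nrow(md)
  # concentrations scale as 10^(2.5 * (pollution - 1)): ~300-fold between
  # pristine and maximally polluted sites, so summed toxic units span the
  # below-chronic to acute range and log totals are ~linear in pollution
  draw_conc <- function(scale_col, detect_base) {
    v <- matrix(0, n_sites, nrow(cmp),
                dimnames = list(md$site_id, cmp$compound))
    for (j in seq_len(nrow(cmp))) {
      mean_j <- sc[[scale_col]][j] * 10^(2.5 * (pollution - 1))
      p_det <- pmin(0.98, detect_base + 0.55 * pollution)
      det <- runif(n_sites) < p_det
      v[det, j] <- rlnorm(sum(det), log(mean_j[det]), 0.5)
    }
    v
  }
  tissue <- concentration_table(draw_conc("tissue_scale", 0.40), "tissue")
  water <- concentration_table(draw_conc("water_scale", 0.45), "water")

  distances <- sim_waterway_distances(md)
  list(metadata = site_metadata(md), tissue = tissue, water = water,
       compounds = cmp, lc50 = cat_tabs$lc50, distances = distances,
       pollution = pollution)
}

# waterway distances: |cumulative km| within a river; rivers of one
# catchment join at a confluence below their last sites; catchments are
# connected only through a long main stem.
sim_waterway_distances <- function(md) {
  n <- nrow(md)
  to_conf <- numeric(n)     # site -> own-river confluence distance
  for (r in unique(md$river)) {
    rows <- which(md$river == r)
    river_len <- max(md$distance_from_source[rows]) + runif(1, 5, 20)
    to_conf[rows] <- river_len - md$distance_from_source[rows]
  }
  m <- matrix(0, n, n, dimnames = list(md$site_id, md$site_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (md$river[i] == md$river[j]) {
      m[i, j] <- abs(md$distance_from_source[i] -
                       md$distance_from_source[j])
    } else if (md$catchment[i] == md$catchment[j]) {
      m[i, j] <- to_conf[i] + to_conf[j]
    } else {
      m[i, j] <- to_conf[i] + to_conf[j] + 150
    }
  }
  m <- (m + t(m)) / 2
  distance_matrix(m, "waterway")
}

# -- allele-frequency forward machinery -----------------------------------

# one generation of drift (+ stepwise mutation) for a frequency vector
drift_step <- function(p, ne2, mu) {
  cnt <- drop(rmultinom(1, ne2, p))
  if (mu > 0) {
    nm <- rbinom(1, ne2, mu)
    if (nm > 0) {
      C <- length(cnt)
      for (k in seq_len(nm)) {
        from <- sample.int(C, 1, prob = cnt)
        to <- from + sample(c(-1L, 1L), 1)
        if (to < 1L) to <- 2L
        if (to > C) to <- C - 1L
        cnt[from] <- cnt[from] - 1L
        cnt[to] <- cnt[to] + 1L
      }
    }
  }
  cnt / ne2
}

drift_gens <- function(p, ne, gens, mu) {
  ne2 <- 2 * round(ne)
  for (g in seq_len(gens)) p <- drift_step(p, ne2, mu)
  p
}

#' Simulate genotypes over the site network
#'
#' Founder allele frequencies per catchment come from a symmetric
#' Dirichlet; catchment pools and then river pools drift apart for the
#' configured divergence times; finally each river runs a stepping-stone
#' chain of site demes for `generations` generations with adjacent-site
#' migration `m` and site-specific `Ne = ne_base * exp(-gamma *
#' pollution)`.  Sites above the Wahlund threshold carry a hidden deme
#' (same Ne, no migration, split at river founding) contributing a
#' fraction `wahlund_w` of sampled individuals, which inflates F_IS.
#' Individuals are drawn in Hardy-Weinberg proportions within each
#' (sub)deme.
#'
#' @param config a [sim_config()].
#' @param pollution named per-site pollution scores (from
#'   [simulate_pollution()]).
#' @param metadata the matching [site_metadata()] table.
#' @param seed integer seed.
#' @return list: `dataset` (a [microsat_dataset()]) and `truth`
#'   (data.frame site_id, pollution, ne_realized, wahlund_w, plus
#'   attribute `params` with the generating values).
#' @export
simulate_genotypes <- function(config = sim_config(), pollution, metadata,
                               seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  A <- config$founder_alleles
  C <- A + 8L                      # code space with mutation head-room
  start <- 4L
  codes <- 100L + seq_len(C)       # microsatellite-style 3-digit codes
  L <- config$n_loci
  rivers <- unique(metadata$river)
  ne_site <- setNames(
    round(config$ne_base * exp(-config$gamma * pollution)),
    names(pollution))
  if (any(ne_site < 2))
    stop("Ne(site) < 2 at ", paste(names(ne_site)[ne_site < 2],
                                   collapse = ", "),
         ": pollution too extreme for this configuration")
  wahlund <- pollution > config$wahlund_threshold & config$wahlund_w > 0

  # founder frequencies per catchment per locus
  catchment_of <- tapply(metadata$catchment, metadata$river,
                         function(z) z[1])
  cat_names <- unique(metadata$catchment)
  cat_freq <- lapply(cat_names, function(cn) {
    lapply(seq_len(L), function(l) {
      p <- rep(0, C)
      p[start:(start + A - 1L)] <- rgamma(A, shape = 1)  # Dirichlet(1)
      p <- p / sum(p)
      drift_gens(p, config$ne_founder, config$catchment_divergence,
                 config$mu)
    })
  })
  names(cat_freq) <- cat_names

  n_range <- config$ind_per_site
  all_id <- character(0); all_site <- character(0)
  a1 <- NULL; a2 <- NULL
  truth_rows <- list()
  for (rv in rivers) {
    rows <- which(metadata$river == rv)
    sids <- metadata$site_id[rows]
    K <- length(sids)
    ne_r <- ne_site[sids]
    base <- cat_freq[[catchment_of[[rv]]]]
    # river pool drifts off the catchment pool
    river_freq <- lapply(base, function(p)
      drift_gens(p, config$ne_founder, config$river_divergence, config$mu))
    # site demes: K x C per locus; hidden Wahlund demes split off late
    # and then drift unconnected
    site_freq <- lapply(river_freq, function(p)
      matrix(rep(p, each = K), nrow = K))
    hidden_freq <- lapply(river_freq, function(p)
      matrix(rep(p, each = K), nrow = K))
    split_gen <- config$generations - config$wahlund_split
    for (gen in seq_len(config$generations)) {
      for (l in seq_len(L)) {
        P <- site_freq[[l]]
        if (config$m > 0 && K > 1) {
          up <- P[c(1, seq_len(K - 1)), , drop = FALSE]
          dn <- P[c(seq_len(K)[-1], K), , drop = FALSE]
          P <- (1 - config$m) * P + (config$m / 2) * (up + dn)
          P <- P / rowSums(P)
        }
        for (s in seq_len(K)) {
          site_freq[[l]][s, ] <- drift_step(P[s, ], 2 * ne_r[s], config$mu)
          if (wahlund[sids[s]] && gen > split_gen)
            hidden_freq[[l]][s, ] <-
              drift_step(hidden_freq[[l]][s, ], 2 * ne_r[s], config$mu)
        }
        if (gen == split_gen)
          hidden_freq[[l]] <- site_freq[[l]]
      }
    }
    # sample individuals
    for (s in seq_len(K)) {
      n_choices <- seq(n_range[1], n_range[2])
      n_i <- n_choices[sample.int(length(n_choices), 1)]
      w <- if (wahlund[sids[s]]) config$wahlund_w else 0
      from_hidden <- runif(n_i) < w
      g1 <- matrix(0L, n_i, L); g2 <- matrix(0L, n_i, L)
      for (l in seq_len(L)) {
        pm <- site_freq[[l]][s, ]; ph <- hidden_freq[[l]][s, ]
        for (i in seq_len(n_i)) {
          p <- if (from_hidden[i]) ph else pm
          g1[i, l] <- codes[sample.int(C, 1, prob = p)]
          g2[i, l] <- codes[sample.int(C, 1, prob = p)]
        }
      }
      ids <- paste0(sids[s], "_", seq_len(n_i))
      all_id <- c(all_id, ids)
      all_site <- c(all_site, rep(sids[s], n_i))
      a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
      truth_rows[[sids[s]]] <- data.frame(
        site_id = sids[s], pollution = unname(pollution[sids[s]]),
        ne_realized = unname(ne_r[s]),
        wahlund_w = w, n_sampled = n_i, stringsAsFactors = FALSE)
    }
  }
  site_to_river <- setNames(metadata$river, metadata$site_id)
  river_to_catchment <- setNames(metadata$catchment, metadata$river)
  river_to_catchment <- river_to_catchment[!duplicated(names(river_to_catchment))]
  ds <- microsat_dataset(all_id, all_site,
                         paste0("loc", seq_len(L)), a1, a2,
                         site_to_river, river_to_catchment)
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  truth <- truth[match(metadata$site_id, truth$site_id), ]
  rownames(truth) <- NULL
  attr(truth, "params") <- config
  list(dataset = ds, truth = truth)
}

#' Simulate a complete in-memory study bundle
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `bundle` (a validated `study_bundle`), `dataset`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  pol <- simulate_pollution(config, seed)
  gen <- simulate_genotypes(config, pol$pollution, pol$metadata,
                            seed + 1000L)
  pol$metadata$abundance <- pol$metadata$abundance  # already drawn
  bundle <- validate_study_bundle(pol$metadata, pol$tissue, pol$water,
                                  pol$compounds, pol$lc50, pol$distances)
  list(bundle = bundle, dataset = gen$dataset, truth = gen$truth)
}

#' Write a complete synthetic study to disk
#'
#' Emits GenePop genotypes, all delimited tables, the waterway distance
#' matrix, the ground-truth table, and a YAML manifest; the directory is
#' directly consumable by [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
generate_study <- function(config = sim_config(), seed, out_dir) {
  sim <- simulate_study(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  paths <- c(genotypes = fp("genotypes.gen"), metadata = fp("metadata.csv"),
             tissue = fp("tissue.csv"), water = fp("water.csv"),
             compounds = fp("compounds.csv"), lc50 = fp("lc50.csv"),
             distances = fp("distances.csv"), truth = fp("truth.csv"),
             manifest = fp("manifest.yaml"))
  write_genepop(sim$dataset, paths["genotypes"],
                title = paste0("synthetic study bundle (seed ", seed, ")"))
  write.csv(sim$bundle$metadata, paths["metadata"], row.names = FALSE,
            quote = FALSE)
  wtab <- function(ct, path) {
    df <- data.frame(site_id = rownames(ct$values), ct$values,
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  wtab(sim$bundle$tissue, paths["tissue"])
  wtab(sim$bundle$water, paths["water"])
  write.csv(as.data.frame(sim$bundle$compounds), paths["compounds"],
            row.names = FALSE)
  write.csv(as.data.frame(sim$bundle$lc50), paths["lc50"],
            row.names = FALSE)
  write_distance_matrix(sim$bundle$distances, paths["distances"])
  write.csv(sim$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    generator = "gammapop::generate_study",
    version = as.character(packageVersion("gammapop")),
    seed = seed,
    n_sites = nrow(sim$bundle$metadata),
    n_individuals = length(sim$dataset$ind_id),
    n_loci = length(sim$dataset$loci),
    files = as.list(basename(paths[names(paths) != "manifest"]))),
    paths["manifest"])
  invisible(paths)
}

#' Individual-based Wright-Fisher population (single deme)
#'
#' Forward simulation of a closed, randomly mating diploid population of
#' constant size, used as the ground-truth generator for the
#' linkage-disequilibrium effective-size estimator: after a burn-in the
#' background LD among unlinked loci reflects `ne` alone.
#'
#' @param ne diploid population size (= effective size here).
#' @param n_loci unlinked loci.
#' @param founder_alleles alleles per locus in generation 0 (frequencies
#'   from a symmetric Dirichlet(1)).
#' @param generations generations of random mating.
#' @param sample_size individuals sampled (without replacement) at the
#'   end; default all.
#' @param seed optional seed.
#' @return a [microsat_dataset()] with one site `"WF"`.
#' @export
simulate_wright_fisher <- function(ne, n_loci = 16, founder_alleles = 8,
                                   generations = 30, sample_size = ne,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sample_size <= ne)
  codes <- 100L + seq_len(founder_alleles)
  # genotypes: ne x n_loci x 2
  g1 <- matrix(0L, ne, n_loci); g2 <- matrix(0L, ne, n_loci)
  for (l in seq_len(n_loci)) {
    p <- rgamma(founder_alleles, 1); p <- p / sum(p)
    g1[, l] <- sample(codes, ne, TRUE, prob = p)
    g2[, l] <- sample(codes, ne, TRUE, prob = p)
  }
  for (gen in seq_len(generations)) {
    mothers <- sample.int(ne, ne, TRUE)
    fathers <- sample.int(ne, ne, TRUE)
    pick1 <- matrix(runif(ne * n_loci) < 0.5, ne, n_loci)
    pick2 <- matrix(runif(ne * n_loci) < 0.5, ne, n_loci)
    n1 <- ifelse(pick1, g1[cbind(rep(mothers, n_loci),
                                 rep(seq_len(n_loci), each = ne))],
                 g2[cbind(rep(mothers, n_loci),
                          rep(seq_len(n_loci), each = ne))])
    n2 <- ifelse(pick2, g1[cbind(rep(fathers, n_loci),
                                 rep(seq_len(n_loci), each = ne))],
                 g2[cbind(rep(fathers, n_loci),
                          rep(seq_len(n_loci), each = ne))])
    g1 <- matrix(n1, ne, n_loci)
    g2 <- matrix(n2, ne, n_loci)
  }
  idx <- sample.int(ne, sample_size)
  ids <- paste0("WF_", seq_len(sample_size))
  microsat_dataset(ids, rep("WF", sample_size),
                   paste0("loc", seq_len(n_loci)),
                   g1[idx, , drop = FALSE], g2[idx, , drop = FALSE],
                   c(WF = "WF"), c(WF = "C1"))
}
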