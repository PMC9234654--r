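# Pipeline orchestration ---------------------------------------------------
#
# A run is fully described by a configuration (YAML file or list): input
# paths, permutation counts, rarefaction policy, locus exclusions, random
# seed, output directory.  Stages run in order toxicity -> diversity ->
# structure -> association; every stage failure is re-raised with the
# stage name, and a sidecar metadata file records versions, the seed and
# all resolved parameters so a run can be audited and reproduced.

#' Default pipeline configuration
#'
#' @param input_dir directory holding a study bundle as written by
#'   [generate_study()] (file names can be overridden individually).
#' @param out_dir output directory.
#' @param seed integer seed governing every stochastic stage.
#' @param permutations permutation count for F_ST, Mantel and AMOVA tests
#'   (0 reports p-values as `NA`).
#' @param rarefaction_size gene copies for rarefaction (`NULL` = per-locus
#'   minimum rule).
#' @param allele_digits GenePop allele width.
#' @param exclude_loci loci excluded from the structure analyses (e.g. a
#'   locus with consistent null-allele signal); diversity statistics keep
#'   all loci.
#' @param max_missing QC missingness threshold.
#' @param ne_estimates compute LD-based N_e per site (slowest stage
#'   component).
#' @return named list, the pipeline configuration.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1,
                            permutations = 999, rarefaction_size = NULL,
                            allele_digits = 3,
                            exclude_loci = character(0),
                            max_missing = 0.20, ne_estimates = FALSE) {
  files <- list(genotypes = file.path(input_dir, "genotypes.gen"),
                metadata = file.path(input_dir, "metadata.csv"),
                tissue = file.path(input_dir, "tissue.csv"),
                water = file.path(input_dir, "water.csv"),
                compounds = file.path(input_dir, "compounds.csv"),
                lc50 = file.path(input_dir, "lc50.csv"),
                distances = file.path(input_dir, "distances.csv"))
  list(files = files, out_dir = out_dir, seed = seed,
       permutations = permutations, rarefaction_size = rarefaction_size,
       allele_digits = allele_digits, exclude_loci = exclude_loci,
       max_missing = max_missing, ne_estimates = ne_estimates)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(input_dir = cfg$input_dir %||% ".",
                          out_dir = cfg$out_dir %||% "gammapop-out",
                          seed = cfg$seed %||% 1)
  for (nm in setdiff(names(cfg), c("input_dir", "files")))
    base[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$files))
    for (nm in names(cfg$files)) base$files[[nm]] <- cfg$files[[nm]]
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes toxicity scoring, per-site diversity, differentiation and
#' spatial association, and the diversity-versus-pollution models on a
#' study bundle, writing delimited tables plus a YAML run-metadata
#' sidecar.  Reruns with identical config and inputs are bit-identical.
#'
#' @param config a [pipeline_config()] list or path to a YAML file.
#' @return (invisibly) a list with all stage results (`tu`, `diversity`,
#'   `fst_site`, `fst_river`, `mantel`, `partial_mantel`, `amova`,
#'   `models`, `sem`) plus `tables` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  nperm <- config$permutations

  bundle <- stage("input", {
    read_study_tables(metadata = config$files$metadata,
                      tissue = config$files$tissue,
                      water = config$files$water,
                      compounds = config$files$compounds,
                      lc50 = config$files$lc50,
                      distances = config$files$distances)
  })
  raw <- stage("input", read_genepop(config$files$genotypes,
                                     config$allele_digits,
    setNames(bundle$metadata$river, bundle$metadata$site_id),
    setNames(bundle$metadata$catchment,
             bundle$metadata$river)[!duplicated(bundle$metadata$river)]))

  # -- toxicity ----------------------------------------------------------
  tu <- stage("toxicity", toxic_units(bundle$tissue, bundle$compounds,
                                      bundle$lc50))
  tu$per_site$class <- classify_toxicity(tu$per_site$sum_tu)
  totals <- stage("toxicity", total_aom(bundle$tissue))

  # -- diversity ---------------------------------------------------------
  qc <- stage("diversity", qc_filter(raw, config$max_missing))
  div <- stage("diversity",
               site_diversity(qc$dataset, g = config$rarefaction_size,
                              ne = config$ne_estimates))
  # -- structure ---------------------------------------------------------
  struct_ds <- qc$dataset
  fst_site <- stage("structure",
                    fst_matrix(struct_ds, "site",
                               exclude_loci = config$exclude_loci))
  fst_river <- stage("structure",
                     fst_matrix(struct_ds, "river",
                                exclude_loci = config$exclude_loci))
  sites_used <- rownames(fst_site$matrix)
  wdist <- bundle$distances$values[sites_used, sites_used]
  mant <- stage("structure",
                mantel(fst_site$matrix, wdist, n_perm = nperm))
  tot_named <- setNames(totals$total, totals$site_id)
  aom_d <- stage("structure",
                 suppressWarnings(
                   aom_distance_matrix(tot_named[sites_used], "log10")))
  common <- intersect(sites_used, aom_d$sites)
  pmant <- stage("structure",
                 partial_mantel(fst_site$matrix[common, common],
                                aom_d$values[common, common],
                                wdist[common, common], n_perm = nperm))
  amv <- stage("structure", amova(struct_ds, n_perm = min(nperm, 999)))

  # -- association -------------------------------------------------------
  site_table <- stage("association", {
    st <- merge(bundle$metadata, div, by = "site_id")
    st <- merge(st, totals, by = "site_id", all.x = TRUE)
    st <- merge(st, tu$per_site[, c("site_id", "sum_tu", "log10_sum_tu")],
                by = "site_id", all.x = TRUE)
    # sites lacking tissue chemistry are excluded from the models
    st[!(st$site_id %in% bundle$sites_without_tissue), ]
  })
  models <- stage("association", {
    resp <- c(ar = "allelic_richness", fis = "fis", abundance = "abundance")
    lapply(resp, function(rv) {
      f <- stats::as.formula(paste(
        rv, "~ distance_from_source + wwtp_upstream + log10_total +",
        "log10_sum_tu + conductivity + ph + oxygen_saturation"))
      dredge_lmm(f, site_table, "river", delta_max = 5, force = TRUE)
    })
  })
  sem <- stage("association", {
    d <- data.frame(ar = site_table$allelic_richness,
                    tot = site_table$log10_total,
                    dist = site_table$distance_from_source,
                    tu = site_table$log10_sum_tu,
                    abun = log10(site_table$abundance + 1))
    fit_path_model(list(tu ~ tot, abun ~ tot,
                        ar ~ tot + tu + abun + dist), d)
  })

  # -- outputs -----------------------------------------------------------
  outp <- function(x) file.path(config$out_dir, x)
  tables <- c(tu_per_site = outp("tu_per_site.csv"),
              tu_per_compound = outp("tu_per_compound.csv"),
              diversity = outp("diversity.csv"),
              site_table = outp("site_table.csv"),
              fst_site = outp("fst_site_pairs.csv"),
              fst_river = outp("fst_river_pairs.csv"),
              association = outp("association_tests.csv"),
              sem_paths = outp("sem_paths.csv"),
              run_metadata = outp("run_metadata.yaml"))
  wcsv <- function(df, p) write.csv(df, p, row.names = FALSE)
  wcsv(tu$per_site, tables["tu_per_site"])
  wcsv(tu$per_compound, tables["tu_per_compound"])
  wcsv(div, tables["diversity"])
  wcsv(site_table, tables["site_table"])
  wcsv(fst_site$pairs, tables["fst_site"])
  wcsv(fst_river$pairs, tables["fst_river"])
  assoc <- data.frame(
    test = c("mantel_fst_waterway", "partial_mantel_fst_aom",
             "amova_phi_ct", "amova_phi_sc", "amova_phi_st"),
    statistic = c(mant$r, pmant$r, amv$phi),
    p_value = c(mant$p_value, pmant$p_value, amv$p_values))
  wcsv(assoc, tables["association"])
  wcsv(sem$paths, tables["sem_paths"])
  yaml::write_yaml(list(
    package = "gammapop",
    version = as.character(packageVersion("gammapop")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    permutations = nperm,
    rarefaction_size = config$rarefaction_size %||% "per-locus minimum",
    allele_digits = config$allele_digits,
    exclude_loci = as.list(config$exclude_loci),
    max_missing = config$max_missing,
    qc_removed_individuals = as.list(qc$removed_individuals),
    qc_removed_loci = as.list(qc$removed_loci),
    sites_without_tissue = as.list(bundle$sites_without_tissue)),
    tables["run_metadata"])

  invisible(list(tu = tu, totals = totals, diversity = div,
                 fst_site = fst_site, fst_river = fst_river,
                 mantel = mant, partial_mantel = pmant, amova = amv,
                 models = models, sem = sem, site_table = site_table,
                 qc = qc, tables = tables))
}
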