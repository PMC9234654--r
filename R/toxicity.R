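# Toxic-unit scoring from tissue chemistry --------------------------------
#
# Measured internal (tissue) concentrations are converted to an estimated
# freely dissolved water concentration by equilibrium partitioning:
#
#   C_fd = C_tissue / (f_lipid * D_ow)
#
# where f_lipid is the lipid fraction of wet body weight and D_ow the
# pH-dependent octanol-water distribution coefficient (a proxy for the
# lipid-water partition coefficient).  With tissue in ng/g wet weight and
# assuming unit density (1 g tissue ~ 1 mL), ng/g maps 1:1 onto ug/L, so
# C_fd is in ug/L, the unit of the LC50 records.  TU_i = C_fd,i / LC50_i,
# and concentration addition sums TUs over compounds within a site.

#' Toxicity-scoring configuration
#'
#' @param f_lipid lipid fraction of wet body weight; the default 0.0134
#'   (1.34 percent) is the value predicted for *Gammarus pulex*.
#' @param acute_threshold summed-TU level above which acute effects on
#'   crustaceans are expected (default 0.01).
#' @param chronic_threshold level above which chronic adverse effects are
#'   expected (default 0.001).
#' @return list of class `toxicity_config`.
#' @export
toxicity_config <- function(f_lipid = 0.0134, acute_threshold = 0.01,
                            chronic_threshold = 0.001) {
  if (f_lipid <= 0 || f_lipid >= 1) stop("f_lipid must be in (0, 1)")
  if (chronic_threshold >= acute_threshold)
    stop("chronic_threshold must be below acute_threshold")
  structure(list(f_lipid = f_lipid, acute_threshold = acute_threshold,
                 chronic_threshold = chronic_threshold),
            class = "toxicity_config")
}

#' Aggregate LC50 records for one compound
#'
#' Takes the arithmetic mean of all 24 h and 48 h records for the target
#' species; if the target species has none, falls back to the mean of the
#' fallback species' 24/48 h records; if neither has records the compound
#' has no usable LC50 and `NA` is returned (absence is a value, not an
#' error — the compound is simply excluded from TU summation).
#'
#' @param compound compound name.
#' @param lc50 an [lc50_table()].
#' @param target_species,fallback_species species names.
#' @return mean LC50 in ug/L, or `NA_real_`.
#' @export
select_lc50 <- function(compound, lc50,
                        target_species = "Gammarus pulex",
                        fallback_species = "Daphnia magna") {
  el <- lc50$duration_h %in% c(24, 48) & lc50$compound == compound
  tgt <- lc50$lc50[el & lc50$species == target_species]
  if (length(tgt)) return(mean(tgt))
  fb <- lc50$lc50[el & lc50$species == fallback_species]
  if (length(fb)) return(mean(fb))
  NA_real_
}

#' Freely dissolved concentration from tissue burden
#'
#' @param c_tissue tissue concentration, ng/g wet weight (vectorised).
#' @param f_lipid lipid fraction of wet body weight.
#' @param log_dow log10 D_ow (vectorised, recycled against `c_tissue`).
#' @return estimated freely dissolved concentration, ug/L.
#' @export
freely_dissolved <- function(c_tissue, f_lipid, log_dow) {
  if (f_lipid <= 0) stop("f_lipid must be positive")
  if (any(c_tissue < 0)) stop("tissue concentrations must be >= 0")
  c_tissue / (f_lipid * 10^log_dow)
}

#' Per-site toxic units from a tissue concentration table
#'
#' @param tissue a tissue [concentration_table()].
#' @param compounds a [compound_properties()] table covering all tissue
#'   compounds.
#' @param lc50 an [lc50_table()].
#' @param config a [toxicity_config()].
#' @param target_species,fallback_species passed to [select_lc50()].
#' @return object of class `tu_result`: list with
#'   \describe{
#'     \item{per_compound}{data.frame site_id, compound, application_class,
#'       c_tissue, cfd, lc50, tu (rows only for detected compounds with a
#'       usable LC50).}
#'     \item{per_site}{data.frame site_id, sum_tu, log10_sum_tu (NA when
#'       sum_tu is 0), and one `share_<class>` column per application class
#'       present (shares of sum_tu; they sum to 1 where sum_tu > 0).}
#'     \item{compounds_skipped}{compounds detected somewhere but lacking
#'       any usable LC50.}
#'   }
#' @export
toxic_units <- function(tissue, compounds, lc50, config = toxicity_config(),
                        target_species = "Gammarus pulex",
                        fallback_species = "Daphnia magna") {
  stopifnot(inherits(tissue, "concentration_table"),
            tissue$matrix_kind == "tissue")
  v <- tissue$values
  cmp <- colnames(v)
  props <- compounds[match(cmp, compounds$compound), ]
  if (anyNA(props$compound))
    stop("missing property records for: ",
         paste(cmp[is.na(props$compound)], collapse = ", "))
  lc <- vapply(cmp, select_lc50, numeric(1), lc50 = lc50,
               target_species = target_species,
               fallback_species = fallback_species)
  detected_any <- colSums(v > 0) > 0
  skipped <- cmp[is.na(lc) & detected_any]

  rows <- list()
  classes <- sort(unique(props$application_class))
  ps <- data.frame(site_id = rownames(v), sum_tu = 0,
                   log10_sum_tu = NA_real_, stringsAsFactors = FALSE)
  shares <- matrix(NA_real_, nrow(v), length(classes),
                   dimnames = list(NULL, paste0("share_", classes)))
  for (s in seq_len(nrow(v))) {
    use <- which(v[s, ] > 0 & !is.na(lc))
    if (length(use)) {
      cfd <- freely_dissolved(v[s, use], config$f_lipid,
                              props$log_dow[use])
      tu <- cfd / lc[use]
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = rownames(v)[s], compound = cmp[use],
        application_class = props$application_class[use],
        c_tissue = unname(v[s, use]), cfd = unname(cfd),
        lc50 = unname(lc[use]), tu = unname(tu),
        stringsAsFactors = FALSE)
      st <- sum(tu)
      ps$sum_tu[s] <- st
      if (st > 0) {
        ps$log10_sum_tu[s] <- log10(st)
        cl_tu <- tapply(tu, factor(props$application_class[use],
                                   levels = classes), sum)
        cl_tu[is.na(cl_tu)] <- 0
        shares[s, ] <- cl_tu / st
      }
    }
  }
  per_compound <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(0), compound = character(0),
               application_class = character(0), c_tissue = numeric(0),
               cfd = numeric(0), lc50 = numeric(0), tu = numeric(0))
  structure(list(per_compound = per_compound,
                 per_site = cbind(ps, as.data.frame(shares)),
                 compounds_skipped = skipped,
                 config = config),
            class = "tu_result")
}

#' @export
print.tu_result <- function(x, ...) {
  cat("tu_result:", nrow(x$per_site), "sites;",
      length(x$compounds_skipped), "compounds without LC50\n")
  invisible(x)
}

#' Classify toxic-unit levels against effect thresholds
#'
#' Comparisons are strict (`>`): a value exactly at a threshold is
#' classified in the band below it, mirroring the language "exceeded".
#'
#' @param tu numeric vector of toxic units (per compound or summed per
#'   site).
#' @param config a [toxicity_config()].
#' @return character vector: `"acute"`, `"chronic"` or `"below"`.
#' @export
classify_toxicity <- function(tu, config = toxicity_config()) {
  out <- rep("below", length(tu))
  out[tu > config$chronic_threshold] <- "chronic"
  out[tu > config$acute_threshold] <- "acute"
  out[is.na(tu)] <- NA_character_
  out
}

#' Per-site total micropollutant concentration
#'
#' Sums all compounds per site and attaches the log10 companion used by the
#' downstream models (totals span orders of magnitude, and values near zero
#' would otherwise dominate leverage). A site with total 0 gets `NA` for
#' the log.
#'
#' @param conc a [concentration_table()].
#' @return data.frame: site_id, total, log10_total.
#' @export
total_aom <- function(conc) {
  stopifnot(inherits(conc, "concentration_table"))
  tot <- rowSums(conc$values)
  data.frame(site_id = rownames(conc$values), total = unname(tot),
             log10_total = ifelse(tot > 0, log10(tot), NA_real_),
             stringsAsFactors = FALSE)
}
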