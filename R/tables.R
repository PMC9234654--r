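# Study tables: metadata, concentrations, compound properties, LC50,
# distance matrices --------------------------------------------------------

APPLICATION_CLASSES <- c("pesticide", "pharmaceutical", "industrial",
                         "food ingredient", "biocide", "surfactant",
                         "transformation product", "other")

#' Construct a site metadata table
#'
#' @param df data.frame with columns `site_id`, `river`, `catchment`,
#'   `distance_from_source` (km), `wwtp_upstream` (logical),
#'   `conductivity` (uS/cm), `ph`, `oxygen_saturation` (percent),
#'   `abundance` (individuals per catch).
#' @return validated data.frame of class `site_metadata`.
#' @export
site_metadata <- function(df) {
  need <- c("site_id", "river", "catchment", "distance_from_source",
            "wwtp_upstream", "conductivity", "ph", "oxygen_saturation",
            "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id in metadata")
  if (any(df$distance_from_source < 0, na.rm = TRUE))
    stop("distance_from_source must be >= 0")
  df$wwtp_upstream <- as.logical(df$wwtp_upstream)
  class(df) <- c("site_metadata", "data.frame")
  df
}

#' Construct a site x compound concentration table
#'
#' @param values numeric matrix, sites x compounds, with row names = site
#'   ids and column names = compound names. Not-detected is coded 0, never
#'   `NA`.
#' @param matrix_kind `"water"` or `"tissue"`.
#' @return object of class `concentration_table` with a `units` field
#'   (ug/L for water, ng/g wet for tissue).
#' @export
concentration_table <- function(values, matrix_kind = c("tissue", "water")) {
  matrix_kind <- match.arg(matrix_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("concentration matrix needs site row names and compound column names")
  if (anyNA(values)) stop("concentrations may not be NA; code not-detected as 0")
  if (any(values < 0)) stop("negative concentration in ", matrix_kind, " table")
  structure(list(values = values, matrix_kind = matrix_kind,
                 units = if (matrix_kind == "water") "ug/L" else "ng/g wet"),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("concentration_table (", x$matrix_kind, ", ", x$units, "): ",
      nrow(x$values), " sites x ", ncol(x$values), " compounds\n", sep = "")
  invisible(x)
}

#' Construct a compound property table
#'
#' @param df data.frame with columns `compound`, `application_class`
#'   (from the controlled vocabulary in `APPLICATION_CLASSES`), and
#'   `log_dow` (log10 of the pH-dependent octanol-water distribution
#'   coefficient).
#' @return validated data.frame of class `compound_properties`.
#' @export
compound_properties <- function(df) {
  need <- c("compound", "application_class", "log_dow")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("compound properties missing columns: ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$application_class), APPLICATION_CLASSES)
  if (length(bad))
    stop("unknown application class(es): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(APPLICATION_CLASSES, collapse = ", "), ")")
  if (anyDuplicated(df$compound)) stop("duplicate compound names")
  class(df) <- c("compound_properties", "data.frame")
  df
}

#' Construct an LC50 record table
#'
#' @param df data.frame with columns `compound`, `species`,
#'   `duration_h` (hours), `lc50` (ug/L, positive).
#' @return validated data.frame of class `lc50_table`.
#' @export
lc50_table <- function(df) {
  need <- c("compound", "species", "duration_h", "lc50")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("LC50 table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$lc50 <= 0)) stop("lc50 values must be positive")
  class(df) <- c("lc50_table", "data.frame")
  df
}

#' Construct a labelled site-to-site distance matrix
#'
#' @param m symmetric non-negative numeric matrix with zero diagonal; row
#'   and column names are site ids.
#' @param kind one of `"waterway"`, `"aom_difference"`, `"tu_difference"`,
#'   `"fst"`, or `"other"`.
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(m, kind = "waterway") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("distance matrix needs site id names")
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix row/column names differ")
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(abs(m - t(m)) > 1e-9, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  if (any(diag(m) != 0, na.rm = TRUE))
    stop("distance matrix diagonal must be zero")
  structure(list(values = m, sites = rownames(m), kind = kind),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$kind, "): ", length(x$sites), " sites\n",
      sep = "")
  invisible(x)
}

#' Read and cross-validate a study bundle from delimited text files
#'
#' All tables are comma-separated with a header row. The distance matrix
#' file has site ids as the first column and as column headers. Sites
#' present in the metadata but absent from a concentration table are not an
#' error: they are retained and flagged as excluded from tissue-based
#' models (in the field study such gaps arise when too few animals were
#' caught for chemistry).
#'
#' @param metadata,tissue,water,compounds,lc50,distances file paths; `water`
#'   may be `NULL`.
#' @return a list of class `study_bundle` with elements `metadata`,
#'   `tissue`, `water`, `compounds`, `lc50`, `distances`, and
#'   `sites_without_tissue` (character vector of flagged sites).
#' @export
read_study_tables <- function(metadata, tissue, water = NULL, compounds,
                              lc50, distances) {
  md <- site_metadata(read.csv(metadata, stringsAsFactors = FALSE))
  read_conc <- function(path, kind) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    concentration_table(m, kind)
  }
  tis <- read_conc(tissue, "tissue")
  wat <- if (!is.null(water)) read_conc(water, "water") else NULL
  cp <- compound_properties(read.csv(compounds, stringsAsFactors = FALSE))
  lc <- lc50_table(read.csv(lc50, stringsAsFactors = FALSE))
  ddf <- read.csv(distances, check.names = FALSE, stringsAsFactors = FALSE)
  dm <- as.matrix(ddf[, -1, drop = FALSE])
  rownames(dm) <- ddf[[1]]
  dist <- distance_matrix(dm, "waterway")
  validate_study_bundle(md, tis, wat, cp, lc, dist)
}

#' Cross-validate in-memory study tables into a bundle
#'
#' @param metadata a `site_metadata` table.
#' @param tissue,water `concentration_table`s (water optional).
#' @param compounds a `compound_properties` table.
#' @param lc50 an `lc50_table`.
#' @param distances a `distance_matrix`.
#' @return a `study_bundle` list; see [read_study_tables()].
#' @export
validate_study_bundle <- function(metadata, tissue, water = NULL,
                                  compounds, lc50, distances) {
  sites <- metadata$site_id
  offenders <- function(found, where) {
    extra <- setdiff(found, sites)
    if (length(extra))
      stop("unknown site id(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  offenders(rownames(tissue$values), "tissue table")
  if (!is.null(water)) offenders(rownames(water$values), "water table")
  offenders(distances$sites, "distance matrix")
  miss_d <- setdiff(sites, distances$sites)
  if (length(miss_d))
    stop("sites missing from distance matrix: ",
         paste(miss_d, collapse = ", "))
  no_tissue <- setdiff(sites, rownames(tissue$values))
  unknown_cmp <- setdiff(colnames(tissue$values), compounds$compound)
  if (length(unknown_cmp))
    stop("tissue compounds without property records: ",
         paste(unknown_cmp, collapse = ", "))
  structure(list(metadata = metadata, tissue = tissue, water = water,
                 compounds = compounds, lc50 = lc50, distances = distances,
                 sites_without_tissue = no_tissue),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle:", nrow(x$metadata), "sites,",
      ncol(x$tissue$values), "tissue compounds\n")
  if (length(x$sites_without_tissue))
    cat("  flagged (no tissue chemistry):",
        paste(x$sites_without_tissue, collapse = ", "), "\n")
  invisible(x)
}

#' Write a distance matrix as delimited text
#'
#' @param x a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path) {
  df <- data.frame(site_id = x$sites, x$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
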