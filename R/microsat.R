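# Core genotype container -----------------------------------------------
#
# Diploid codominant genotypes are stored as two n x L integer matrices
# holding the (unordered) allele pair per individual and locus.  A missing
# genotype is missing as a whole: both allele slots are NA; half-missing
# calls are not representable by construction.

#' Microsatellite dataset
#'
#' Container for diploid microsatellite genotypes with the site / river /
#' catchment labelling used throughout the pipeline.  Allele calls are
#' unordered pairs of positive integer allele codes; a missing call sets
#' both slots to `NA` (there are no half-missing genotypes).
#'
#' @param ind_id character vector of individual identifiers.
#' @param site character vector (same length) of site identifiers.
#' @param loci character vector of locus names (unique, ordered).
#' @param allele1,allele2 integer matrices, individuals x loci; `NA` in both
#'   marks a missing call. Pairs are stored sorted so that
#'   `allele1 <= allele2`.
#' @param site_to_river named character vector mapping site id to river.
#' @param river_to_catchment named character vector mapping river to
#'   catchment.
#'
#' @return An object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(ind_id, site, loci, allele1, allele2,
                             site_to_river, river_to_catchment) {
  n <- length(ind_id)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  stopifnot(length(site) == n,
            nrow(allele1) == n, nrow(allele2) == n,
            ncol(allele1) == length(loci), ncol(allele2) == length(loci))
  if (anyDuplicated(loci))
    stop("duplicate locus names: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half))
    stop("half-missing genotypes are not allowed")
  bad <- !is.na(allele1) & (allele1 < 1 | allele2 < 1)
  if (any(bad)) stop("allele codes must be positive integers")
  # canonical order within the pair
  swap <- !is.na(allele1) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  unknown <- setdiff(unique(site), names(site_to_river))
  if (length(unknown))
    stop("sites missing from site_to_river map: ",
         paste(unknown, collapse = ", "))
  unknown_r <- setdiff(unique(unname(site_to_river)),
                       names(river_to_catchment))
  if (length(unknown_r))
    stop("rivers missing from river_to_catchment map: ",
         paste(unknown_r, collapse = ", "))
  dimnames(allele1) <- dimnames(allele2) <- list(ind_id, loci)
  structure(
    list(ind_id = as.character(ind_id),
         site = as.character(site),
         loci = as.character(loci),
         allele1 = allele1,
         allele2 = allele2,
         site_to_river = site_to_river,
         river_to_catchment = river_to_catchment),
    class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  cat("microsat_dataset:", length(x$ind_id), "individuals,",
      length(x$loci), "loci,", length(unique(x$site)), "sites\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param x a `microsat_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$ind_id)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$loci)

#' River label for each individual
#' @param x a `microsat_dataset`.
#' @return character vector, one entry per individual.
#' @export
ind_river <- function(x) unname(x$site_to_river[x$site])

#' Catchment label for each individual
#' @rdname ind_river
#' @export
ind_catchment <- function(x) {
  unname(x$river_to_catchment[x$site_to_river[x$site]])
}

#' Subset a dataset by individuals and/or loci
#'
#' @param x a `microsat_dataset`.
#' @param individuals logical/integer/character index of individuals to keep.
#' @param loci logical/integer/character index of loci to keep.
#' @return a `microsat_dataset`.
#' @export
subset_dataset <- function(x, individuals = NULL, loci = NULL) {
  ii <- if (is.null(individuals)) seq_along(x$ind_id) else individuals
  if (is.character(ii)) ii <- match(ii, x$ind_id)
  ll <- if (is.null(loci)) seq_along(x$loci) else loci
  if (is.character(ll)) ll <- match(ll, x$loci)
  microsat_dataset(x$ind_id[ii], x$site[ii], x$loci[ll],
                   x$allele1[ii, ll, drop = FALSE],
                   x$allele2[ii, ll, drop = FALSE],
                   x$site_to_river, x$river_to_catchment)
}

# Allele counts per locus for one group of individuals: named integer
# vector (names = allele codes).
allele_count_vector <- function(x, locus, rows) {
  a <- c(x$allele1[rows, locus], x$allele2[rows, locus])
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

#' Allele counts by group
#'
#' Tabulates gene-copy counts per locus for each group of individuals.
#'
#' @param x a `microsat_dataset`.
#' @param grouping `"site"`, `"river"`, or a vector of group labels (one per
#'   individual).
#' @return A list with one element per locus; each element is a list of
#'   named integer count vectors, one per group. Attribute `groups` holds
#'   the group labels.
#' @export
allele_counts <- function(x, grouping = "site") {
  g <- group_labels(x, grouping)
  groups <- sort(unique(g))
  out <- lapply(seq_along(x$loci), function(l) {
    cl <- lapply(groups, function(gr)
      allele_count_vector(x, l, which(g == gr)))
    names(cl) <- groups
    cl
  })
  names(out) <- x$loci
  attr(out, "groups") <- groups
  out
}

group_labels <- function(x, grouping) {
  if (length(grouping) == length(x$ind_id) && !is.null(x$ind_id) &&
      length(grouping) > 1) return(as.character(grouping))
  switch(as.character(grouping)[1],
         site = x$site,
         river = ind_river(x),
         catchment = ind_catchment(x),
         stop("unknown grouping: ", grouping))
}
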