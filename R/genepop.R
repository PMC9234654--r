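# GenePop reader / writer ------------------------------------------------
#
# The canonical GenePop dialect: a title line, locus names (one per line or
# comma-separated on one line), then population blocks introduced by a line
# containing only "Pop" (case-insensitive).  Individual lines are
# "<name> , <g1> <g2> ...", each genotype 2*allele_digits characters wide;
# "00"/"000" per allele encodes missing.  GenePop has no population names,
# so site ids travel as the individual-name prefix before the comma
# (convention: "<site>_<index>").

#' Read genotypes from a GenePop file
#'
#' @param path path to a `.gen` file.
#' @param allele_digits digits per allele (2 or 3).
#' @param site_to_river,river_to_catchment optional label maps; when omitted,
#'   each site becomes its own river in a single catchment, so that the
#'   dataset is self-consistent until real metadata is attached.
#' @return a [microsat_dataset()].
#' @export
read_genepop <- function(path, allele_digits = 3,
                         site_to_river = NULL, river_to_catchment = NULL) {
  stopifnot(allele_digits %in% c(2L, 3L))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2) stop("not a GenePop file (too short): ", path)
  body <- lines[-1]                       # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) {
    loc_lines <- body[nzchar(trimws(body))]
    pops <- integer(0)
  } else {
    loc_lines <- body[seq_len(first_pop - 1)]
    loc_lines <- loc_lines[nzchar(trimws(loc_lines))]
  }
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found in ", path)
  if (anyDuplicated(loci))
    stop("duplicate locus names in ", path, ": ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))

  gw <- 2L * allele_digits
  ind_id <- character(0); site <- character(0)
  a1 <- list(); a2 <- list()
  pop_sizes <- integer(0)
  cur <- 0L
  if (!is.na(first_pop)) {
    for (k in seq(first_pop, length(body))) {
      ln <- body[k]
      if (is_pop[k]) {
        if (cur > 0L && pop_sizes[cur] == 0L)
          stop("empty population block (block ", cur, ") in ", path)
        cur <- cur + 1L
        pop_sizes[cur] <- 0L
        next
      }
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(parts) < 2)
        stop("malformed individual line ", k + 1L, " in ", path,
             " (no comma): ", ln)
      nm <- trimws(parts[1])
      geno <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[ \t]+")[[1]]
      geno <- geno[nzchar(geno)]
      if (length(geno) != length(loci))
        stop("line ", k + 1L, " in ", path, ": expected ", length(loci),
             " genotypes, found ", length(geno))
      badw <- nchar(geno) != gw | grepl("\\D", geno)
      if (any(badw))
        stop("line ", k + 1L, " in ", path,
             ": malformed genotype width (expected ", gw,
             " digits): ", geno[which(badw)[1]])
      x1 <- as.integer(substr(geno, 1L, allele_digits))
      x2 <- as.integer(substr(geno, allele_digits + 1L, gw))
      miss <- x1 == 0L | x2 == 0L    # any zero half => whole call missing
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      ind_id <- c(ind_id, nm)
      site <- c(site, sub("_[^_]*$", "", nm))
      a1[[length(a1) + 1L]] <- x1
      a2[[length(a2) + 1L]] <- x2
      pop_sizes[cur] <- pop_sizes[cur] + 1L
    }
    if (cur > 0L && pop_sizes[cur] == 0L)
      stop("empty population block (block ", cur, ") in ", path)
  }
  n <- length(ind_id)
  m1 <- matrix(NA_integer_, n, length(loci))
  m2 <- matrix(NA_integer_, n, length(loci))
  if (n) {
    m1 <- do.call(rbind, a1)
    m2 <- do.call(rbind, a2)
  }
  sites <- unique(site)
  if (is.null(site_to_river))
    site_to_river <- setNames(sites, sites)
  if (is.null(river_to_catchment)) {
    rv <- unique(unname(site_to_river))
    river_to_catchment <- setNames(rep("C1", length(rv)), rv)
  }
  microsat_dataset(ind_id, site, loci, m1, m2,
                   site_to_river, river_to_catchment)
}

#' Write genotypes to a GenePop file
#'
#' Emits the canonical dialect (one locus name per line; individuals grouped
#' into `Pop` blocks by site in order of first appearance). Writing then
#' re-reading reproduces the dataset content exactly.
#'
#' @param x a [microsat_dataset()].
#' @param path output path.
#' @param allele_digits digits per allele (2 or 3); all allele codes must be
#'   `< 10^allele_digits`.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, allele_digits = 3,
                          title = "gammapop export") {
  stopifnot(allele_digits %in% c(2L, 3L))
  mx <- suppressWarnings(max(x$allele1, x$allele2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^allele_digits)
    stop("allele code ", mx, " does not fit in ", allele_digits, " digits")
  fmt <- paste0("%0", allele_digits, "d")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (s in unique(x$site)) {
    writeLines("Pop", con)
    rows <- which(x$site == s)
    for (i in rows) {
      g1 <- x$allele1[i, ]; g2 <- x$allele2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      geno <- paste0(sprintf(fmt, g1), sprintf(fmt, g2))
      writeLines(paste0(x$ind_id[i], " ,  ", paste(geno, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
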