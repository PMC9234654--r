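# Mantel and partial Mantel tests ----------------------------------------

as_dist_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) x$values else as.matrix(x)
}

lower_vec <- function(m) m[lower.tri(m)]

# all permutations of 1..n (for exhaustive mode; n <= 7 guard)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Difference-based distance matrix from a per-site scalar
#'
#' Builds `d(i, j) = |t(x_i) - t(x_j)|` with `t` the identity or log10.
#' Totals spanning orders of magnitude are compared on the log scale by
#' default; a quantity that is already log-scaled (such as log10 summed
#' toxic units) should use `transform = "identity"`.
#'
#' @param values named numeric vector (names = site ids).
#' @param transform `"log10"` or `"identity"`.
#' @param kind tag for the resulting matrix.
#' @return a [distance_matrix()]. Sites with undefined transformed values
#'   (`NA`, or non-positive under log10) are dropped with a warning.
#' @export
aom_distance_matrix <- function(values, transform = c("log10", "identity"),
                                kind = "aom_difference") {
  transform <- match.arg(transform)
  t_v <- if (transform == "log10") {
    out <- rep(NA_real_, length(values))
    out[!is.na(values) & values > 0] <-
      log10(values[!is.na(values) & values > 0])
    out
  } else values
  names(t_v) <- names(values)
  bad <- is.na(t_v)
  if (any(bad)) {
    warning("dropping site(s) with undefined value: ",
            paste(names(values)[bad], collapse = ", "))
    t_v <- t_v[!bad]
  }
  m <- abs(outer(t_v, t_v, "-"))
  dimnames(m) <- list(names(t_v), names(t_v))
  distance_matrix(m, kind)
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the lower triangles; significance is
#' by simultaneous row/column permutation of the second matrix.  The
#' default alternative is one-sided positive (the usual
#' isolation-by-distance direction).
#'
#' @param A,B symmetric matrices or [distance_matrix()] objects over the
#'   same sites (matched by name when available).
#' @param n_perm Monte-Carlo permutations; ignored in exhaustive mode.
#' @param seed optional seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive enumerate all `n!` relabelings (requires `n <= 7`);
#'   the p-value is then the exact proportion of relabelings (identity
#'   included) with a statistic at least as extreme as observed.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`,
#'   `partial = FALSE`, `alternative`.
#' @export
mantel <- function(A, B, n_perm = 9999, seed = NULL,
                   alternative = c("greater", "two.sided"),
                   exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  A <- as_dist_matrix(A); B <- as_dist_matrix(B)
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("matrices cover different site sets")
    B <- B[rownames(A), rownames(A)]
  }
  n <- nrow(A)
  if (n < 4) stop("need >= 4 sites for a Mantel test")
  if (nrow(B) != n) stop("non-conformable matrices")
  va <- lower_vec(A)
  r_obs <- cor(va, lower_vec(B))
  stat <- function(rp) if (alternative == "greater") rp else abs(rp)
  obs <- stat(r_obs)
  if (exhaustive) {
    if (n > 7) stop("exhaustive mode limited to n <= 7 sites")
    perms <- all_perms(n)
    rs <- vapply(perms, function(p) cor(va, lower_vec(B[p, p])), numeric(1))
    p <- mean(stat(rs) >= obs - 1e-12)
    n_used <- length(perms)
  } else if (n_perm < 1) {
    p <- NA_real_                  # undefined without permutations
    n_used <- 0L
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      p_idx <- sample.int(n)
      if (stat(cor(va, lower_vec(B[p_idx, p_idx]))) >= obs - 1e-12)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p_value = p, n_perm = n_used,
                 partial = FALSE, conditioning = NULL,
                 alternative = alternative),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between `A` and `B` after removing the linear effect of a
#' conditioning matrix `C` from both (Smouse-Long-Sokal: Pearson
#' correlation of the residuals of `A ~ C` and `B ~ C` on the lower
#' triangles).  Significance by simultaneous row/column permutation of
#' `A`, re-residualising the permuted matrix each time.
#'
#' @param A,B,C conformable symmetric matrices / [distance_matrix()]s.
#' @param n_perm,seed,alternative as in [mantel()].
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 9999, seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- as_dist_matrix(A); B <- as_dist_matrix(B); C <- as_dist_matrix(C)
  if (!is.null(rownames(A))) {
    if (!is.null(rownames(B))) B <- B[rownames(A), rownames(A)]
    if (!is.null(rownames(C))) C <- C[rownames(A), rownames(A)]
  }
  n <- nrow(A)
  if (n < 4) stop("need >= 4 sites for a partial Mantel test")
  vb <- lower_vec(B); vc <- lower_vec(C)
  rb <- resid(lm(vb ~ vc))
  pr <- function(m) {
    va <- lower_vec(m)
    cor(resid(lm(va ~ vc)), rb)
  }
  r_obs <- pr(A)
  stat <- function(rp) if (alternative == "greater") rp else abs(rp)
  obs <- stat(r_obs)
  if (n_perm < 1) {
    pval <- NA_real_
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      p_idx <- sample.int(n)
      if (stat(pr(A[p_idx, p_idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    pval <- (1 + hits) / (1 + n_perm)
  }
  structure(list(r = r_obs, p_value = pval,
                 n_perm = max(0L, as.integer(n_perm)), partial = TRUE,
                 conditioning = "C", alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (x$partial) "Partial Mantel" else "Mantel",
      sprintf("r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}
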