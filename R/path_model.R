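# Recursive path models (observed-variable SEM) ---------------------------
#
# A recursive system of structural equations over observed variables is
# just-identified, so per-equation least squares on standardized variables
# coincides with the ML / GLS covariance fit; no iterative estimation is
# needed.  Direct effects are the standardized regression coefficients;
# indirect effects are sums of products of direct effects along directed
# paths; total = direct + indirect.

#' Fit a recursive path model
#'
#' @param equations list of formulas, one structural equation per
#'   endogenous variable (e.g. `list(tu ~ tot, abun ~ tot, ar ~ tot + tu +
#'   abun + dist)`).  The implied graph must be acyclic and each response
#'   may appear only once.
#' @param data data.frame; only complete cases over all model variables
#'   are used.
#' @param standardize standardize all variables to unit variance before
#'   fitting (default `TRUE`), so coefficients are standardized path
#'   coefficients.
#' @return object of class `path_model_fit`: `paths` data.frame (response,
#'   predictor, estimate, se, t, p), `effects` (direct / indirect / total
#'   for every ordered variable pair connected by a directed path), `n`,
#'   `variables` (with exogenous / intermediate / response roles),
#'   `r_squared` per equation.
#' @export
fit_path_model <- function(equations, data, standardize = TRUE) {
  if (!length(equations)) stop("no equations given")
  responses <- vapply(equations, function(f) deparse(f[[2]]), character(1))
  if (anyDuplicated(responses))
    stop("each endogenous variable may have only one equation")
  preds <- lapply(equations, function(f)
    attr(stats::terms(f), "term.labels"))
  vars <- unique(c(responses, unlist(preds)))
  # acyclicity via Kahn's algorithm on response <- predictor edges
  edges <- do.call(rbind, lapply(seq_along(equations), function(i)
    if (length(preds[[i]]))
      data.frame(from = preds[[i]], to = responses[i],
                 stringsAsFactors = FALSE)))
  if (!is.null(edges)) {
    remaining <- vars
    repeat {
      has_in <- unique(edges$to[edges$from %in% remaining &
                                  edges$to %in% remaining])
      srcs <- setdiff(remaining, has_in)
      if (!length(srcs)) {
        if (length(remaining)) stop("cyclic equation system: ",
                                    paste(remaining, collapse = ", "))
        break
      }
      remaining <- setdiff(remaining, srcs)
      if (!length(remaining)) break
    }
  }
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variables absent from data: ",
                         paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  if (standardize)
    d[] <- lapply(d, function(z) (z - mean(z)) / sd(z))
  paths <- list(); r2 <- numeric(0)
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_along(equations)) {
    pv <- preds[[i]]
    if (n < length(pv) + 2)
      stop("too few complete cases (", n, ") for equation ",
           deparse(equations[[i]]))
    fit <- lm(equations[[i]], d)
    sm <- summary(fit)
    cf <- sm$coefficients
    rows <- setdiff(rownames(cf), "(Intercept)")
    paths[[i]] <- data.frame(response = responses[i], predictor = rows,
                             estimate = cf[rows, 1], se = cf[rows, 2],
                             t = cf[rows, 3], p = cf[rows, 4],
                             row.names = NULL, stringsAsFactors = FALSE)
    B[responses[i], rows] <- cf[rows, 1]
    r2[responses[i]] <- sm$r.squared
  }
  paths <- do.call(rbind, paths)
  # total effects: sum over all directed paths = (I - B)^-1 - I applied to
  # the direct-effect matrix (B[i, j] = effect of j on i)
  total <- solve(diag(length(vars)) - B) - diag(length(vars))
  dimnames(total) <- dimnames(B)
  eff <- NULL
  nz <- which(abs(total) > 1e-12, arr.ind = TRUE)
  if (nrow(nz)) {
    eff <- data.frame(response = vars[nz[, 1]], predictor = vars[nz[, 2]],
                      direct = B[nz], total = total[nz],
                      stringsAsFactors = FALSE)
    eff$indirect <- eff$total - eff$direct
  }
  role <- ifelse(!(vars %in% responses), "exogenous",
                 ifelse(vars %in% unlist(preds), "intermediate",
                        "response"))
  structure(list(paths = paths, effects = eff, n = n,
                 variables = data.frame(variable = vars, role = role,
                                        stringsAsFactors = FALSE),
                 r_squared = r2, standardized = standardize),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat("Recursive path model, n =", x$n,
      if (x$standardized) "(standardized)\n" else "\n")
  print(transform(x$paths, estimate = round(estimate, 3),
                  se = round(se, 3), t = round(t, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
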