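# Random-intercept linear mixed models ------------------------------------
#
# y = X beta + Z u + e, u ~ N(0, sigma_u^2 I_q), e ~ N(0, sigma^2 I_n),
# one random intercept per group.  The variance ratio
# lambda = sigma_u^2 / sigma^2 is profiled out by a 1-D bounded search of
# the (restricted) log-likelihood; at a given lambda the fixed effects are
# GLS with V* = I + lambda Z Z'.  The boundary lambda = 0 (no group
# variance) is always a candidate.

lmm_objective <- function(lambda, y, X, Z, reml) {
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  rss <- drop(crossprod(r, Vi_r))
  if (reml) {
    sig2 <- rss / (n - p)
    m2ll <- (n - p) * log(2 * pi * sig2) + logdetV +
      determinant(XtViX, logarithm = TRUE)$modulus[1] + (n - p)
  } else {
    sig2 <- rss / n
    m2ll <- n * log(2 * pi * sig2) + logdetV + n
  }
  list(m2ll = m2ll, beta = drop(beta), sigma2 = sig2,
       cov_unscaled = solve(XtViX))
}

# analytic d(-2 logL)/d(lambda) at the profiled beta / sigma2 (envelope:
# the beta derivative vanishes at the GLS solution)
lmm_gradient <- function(lambda, y, X, Z, reml) {
  n <- length(y); p <- ncol(X)
  ZZt <- tcrossprod(Z)
  V <- diag(n) + lambda * ZZt
  Vi <- solve(V)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% beta
  Vir <- Vi %*% r
  rss <- drop(crossprod(r, Vir))
  d_logdetV <- sum(Vi * ZZt)                      # tr(Vi ZZt)
  d_rss <- -drop(crossprod(Vir, ZZt %*% Vir))
  if (reml) {
    M <- solve(XtViX, crossprod(ViX, ZZt %*% ViX))
    (n - p) * d_rss / rss + d_logdetV - sum(diag(M))
  } else {
    n * d_rss / rss + d_logdetV
  }
}

#' Fit a single-random-intercept linear mixed model
#'
#' @param formula fixed-effects formula, e.g. `ar ~ log10_total + wwtp`.
#' @param data data.frame with the model variables.
#' @param group name of the grouping column (random intercept per level),
#'   or a vector of group labels.
#' @param method `"REML"` (default, for coefficient reporting) or `"ML"`
#'   (for likelihood comparison across fixed-effect structures).
#' @return object of class `lmm_fit`: `coefficients` data.frame (estimate,
#'   se, t, p with residual df `n - k_fixed`), `sigma_u2`, `sigma2`,
#'   `lambda`, `logLik` (of `method`), `logLik_ml` (always), `n`, `k`
#'   (fixed effects + 2 variance parameters), `AICc` (from the ML
#'   likelihood), `method`, `group_levels`.
#' @export
fit_lmm <- function(formula, data, group, method = c("REML", "ML")) {
  method <- match.arg(method)
  gvec <- if (length(group) == 1 && is.character(group))
    data[[group]] else group
  if (length(gvec) != nrow(data))
    stop("group labels do not match the data")
  keep <- complete.cases(data[, all.vars(formula), drop = FALSE]) &
    !is.na(gvec)
  data <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  g <- factor(gvec[keep])
  if (nlevels(g) < 2) stop("need >= 2 groups for a random intercept")
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    qx <- qr(X)
    stop("singular fixed-effect design; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  }
  if (n <= p + 1) stop("too few observations for the design")
  Z <- stats::model.matrix(~ g - 1)

  fit_at <- function(lambda, reml) lmm_objective(lambda, y, X, Z, reml)
  prof <- function(reml) {
    f <- function(loglam) fit_at(exp(loglam), reml)$m2ll
    opt <- optimize(f, interval = c(-30, 15), tol = 1e-10)
    lam <- exp(opt$minimum)
    # Brent stops near sqrt(eps); secant iterations on the analytic
    # gradient recover the digits the closed-form comparisons need
    g <- function(l) lmm_gradient(l, y, X, Z, reml)
    l0 <- lam * 0.999; l1 <- lam * 1.001
    g0 <- g(l0); g1 <- g(l1)
    for (it in 1:30) {
      if (!is.finite(g0) || !is.finite(g1) || g1 == g0) break
      l2 <- l1 - g1 * (l1 - l0) / (g1 - g0)
      if (!is.finite(l2) || l2 <= 0) break
      l0 <- l1; g0 <- g1
      l1 <- l2; g1 <- g(l1)
      if (abs(l1 - l0) < 1e-13 * (l1 + 1e-13)) break
    }
    if (is.finite(l1) && l1 > 0 &&
        fit_at(l1, reml)$m2ll <= opt$objective + 1e-9) lam <- l1
    if (fit_at(0, reml)$m2ll <= fit_at(lam, reml)$m2ll + 1e-10) lam <- 0
    lam
  }
  lam_reml <- prof(TRUE)
  lam_ml <- prof(FALSE)
  lam <- if (method == "REML") lam_reml else lam_ml
  sol <- fit_at(lam, method == "REML")
  sol_ml <- fit_at(lam_ml, FALSE)

  se <- sqrt(diag(sol$cov_unscaled) * sol$sigma2)
  tval <- sol$beta / se
  df_res <- n - p
  coefs <- data.frame(term = colnames(X), estimate = sol$beta, se = se,
                      t = tval, p = 2 * pt(-abs(tval), df_res),
                      row.names = NULL, stringsAsFactors = FALSE)
  k <- p + 2L
  ll_ml <- -sol_ml$m2ll / 2
  structure(list(coefficients = coefs,
                 sigma_u2 = lam * sol$sigma2, sigma2 = sol$sigma2,
                 lambda = lam,
                 logLik = -sol$m2ll / 2, logLik_ml = ll_ml,
                 n = n, k = k, AICc = aicc(ll_ml, k, n),
                 method = method, group_levels = levels(g),
                 formula = formula),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (", x$method, "), ", x$n, " obs, ",
      length(x$group_levels), " groups\n", sep = "")
  print(transform(x$coefficients,
                  estimate = round(estimate, 4), se = round(se, 4),
                  t = round(t, 3), p = signif(p, 3)))
  cat(sprintf("sigma_u^2 = %.5g, sigma^2 = %.5g, AICc = %.3f\n",
              x$sigma_u2, x$sigma2, x$AICc))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1)`; requires
#' `n - k - 1 > 0`, else `NA` with a warning.
#'
#' @param log_likelihood maximum log-likelihood (ML, not REML).
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model selection for a mixed model
#'
#' Fits every subset of the global model's fixed effects (intercept always
#' included, random intercept always retained) by maximum likelihood,
#' ranks by AICc, and reports models within `delta_max` of the best.  The
#' intercept-only model is always among the candidates, so "no predictor
#' explains the response better than nothing" is a visible outcome.
#'
#' @param formula global fixed-effects formula.
#' @param data data.frame.
#' @param group grouping column name or label vector.
#' @param delta_max retain models with `delta AICc < delta_max` (default 5).
#' @param max_terms refuse more candidate terms than this (default 12)
#'   unless `force = TRUE`.
#' @param force override the combinatorial guard.
#' @return object of class `model_ranking`: data.frame `ranking` with one
#'   row per retained model (term inclusion flags, k, logLik, AICc,
#'   delta), `n_candidates`, `best` (refitted by REML).
#' @export
dredge_lmm <- function(formula, data, group, delta_max = 5,
                       max_terms = 12, force = FALSE) {
  terms_all <- attr(stats::terms(formula), "term.labels")
  m <- length(terms_all)
  if (m > max_terms && !force)
    stop("refusing to enumerate 2^", m, " models; set force = TRUE")
  resp <- deparse(formula[[2]])
  # complete cases on the global model so every candidate sees the same n
  vars <- all.vars(formula)
  gcol <- if (length(group) == 1 && is.character(group)) data[[group]]
          else group
  cc <- complete.cases(data[, vars, drop = FALSE]) & !is.na(gcol)
  data <- data[cc, , drop = FALSE]
  gcol <- gcol[cc]
  rows <- list()
  fits <- list()
  for (code in 0:(2^m - 1)) {
    inc <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    rhs <- if (any(inc)) paste(terms_all[inc], collapse = " + ") else "1"
    f <- stats::as.formula(paste(resp, "~", rhs))
    fit <- fit_lmm(f, data, gcol, method = "ML")
    flags <- as.list(inc)
    names(flags) <- terms_all
    rows[[code + 1]] <- data.frame(model = rhs, flags, k = fit$k,
                                   logLik = fit$logLik_ml, AICc = fit$AICc,
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE)
    fits[[code + 1]] <- f
  }
  rk <- do.call(rbind, rows)
  rk$delta <- rk$AICc - min(rk$AICc)
  ord <- order(rk$AICc)
  rk <- rk[ord, ]
  fits <- fits[ord]
  keep <- rk$delta < delta_max
  best <- fit_lmm(fits[[1]], data, gcol, method = "REML")
  structure(list(ranking = rk[keep, ], all = rk,
                 n_candidates = 2^m, best = best,
                 null_retained = "1" %in% rk$model[keep]),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Model ranking (", x$n_candidates, " candidates, ",
      nrow(x$ranking), " within delta):\n", sep = "")
  print(transform(x$ranking, logLik = round(logLik, 3),
                  AICc = round(AICc, 3), delta = round(delta, 3)),
        row.names = FALSE)
  invisible(x)
}
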