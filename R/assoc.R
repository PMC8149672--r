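#' Fit the null phenotype model
#'
#' Fits the outcome on covariates only (no genotypes), by maximum
#' likelihood, and caches the ingredients needed by covariate-adjusted
#' score tests: fitted means, residuals, variance weights and the inverse
#' weighted covariate cross-product. All association tests in the package
#' condition on this null fit, so the expensive GLM is fitted once per
#' phenotype rather than once per window.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (may be
#'   empty; an intercept is always included).
#' @param family `"gaussian"` for quantitative traits or `"binomial"` for
#'   case-control traits.
#' @return An object of class `ks_null_model`.
#' @export
fit_null_model <- function(data, outcome, covariates = character(),
                           family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column `", outcome, "` not found", call. = FALSE)
  if (stats::var(y) == 0) stop("constant outcome", call. = FALSE)
  X <- if (length(covariates)) {
    stats::model.matrix(
      stats::reformulate(covariates),
      data = data
    )
  } else {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient", call. = FALSE)

  fit <- stats::glm.fit(X, y, family = if (family == "gaussian") {
    stats::gaussian()
  } else {
    stats::binomial()
  })
  if (family == "binomial") {
    if (!fit$converged) stop("binomial null model did not converge", call. = FALSE)
    if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
      stop("binomial null model shows (quasi-)separation: fitted ",
           "probabilities at 0 or 1", call. = FALSE)
    }
  }
  mu <- fit$fitted.values
  res <- y - mu
  n <- length(y)
  if (family == "gaussian") {
    sigma2 <- sum(res^2) / (n - ncol(X))
    w <- rep(sigma2, n)
  } else {
    sigma2 <- 1
    w <- mu * (1 - mu)
  }
  A <- solve(crossprod(X, w * X))
  structure(
    list(family = family, y = y, X = X, mu = mu, residuals = res,
         w = w, A = A, sigma2 = sigma2, n = n),
    class = "ks_null_model"
  )
}

#' @export
print.ks_null_model <- function(x, ...) {
  cat(sprintf("<ks_null_model> %s, n = %d, %d covariate column(s)\n",
              x$family, x$n, ncol(x$X)))
  invisible(x)
}

# Score-test ingredients for a set of columns g (n x k):
#   U_j   = g_j' (Y - mu)
#   V_j   = g_j' W g_j - (X'W g_j)' A (X'W g_j)
# with W the null variance weights (sigma2 for gaussian, mu(1-mu) for
# binomial) and A = (X'WX)^{-1}.
score_ingredients <- function(null, G) {
  G <- as.matrix(G)
  U <- drop(crossprod(G, null$residuals))
  B <- crossprod(null$X, null$w * G)
  V <- colSums(null$w * G * G) - colSums(B * (null$A %*% B))
  list(U = U, V = pmax(V, 0), B = B)
}

#' Single-variant score test
#'
#' Two-sided score test of one dosage vector against the outcome, adjusting
#' for the null-model covariates. For binomial traits with `use_spa = TRUE`
#' the saddlepoint-approximated tail replaces the normal tail whenever the
#' standardized score exceeds the switch threshold, which corrects the
#' severe miscalibration of the normal approximation for rare variants in
#' unbalanced case-control designs.
#'
#' @param null A [fit_null_model()] object.
#' @param g Dosage vector.
#' @param use_spa Use the saddlepoint tail (binomial only).
#' @param spa_switch Standardized-score magnitude below which the normal
#'   tail is used even when `use_spa = TRUE`.
#' @return A p-value in `(0, 1]`.
#' @export
single_variant_test <- function(null, g, use_spa = FALSE, spa_switch = 2) {
  if (stats::var(g) == 0) stop("zero-variance genotype vector", call. = FALSE)
  si <- score_ingredients(null, g)
  if (si$V <= 0) return(1)
  if (use_spa && null$family == "binomial") {
    return(saddlepoint_pvalue(si$U, g, null, spa_switch = spa_switch))
  }
  pv <- stats::pchisq(si$U^2 / si$V, df = 1, lower.tail = FALSE)
  max(pv, 1e-300)
}

#' Saddlepoint p-value for a binomial score statistic
#'
#' Computes the two-sided tail of the covariate-adjusted score statistic
#' `S = g_adj' (Y - mu)` under the null Bernoulli model, using the
#' Lugannani-Rice formula on the statistic's cumulant generating function.
#' Below the switch threshold (default 2 standardized units), or if the
#' saddlepoint root-finding fails, the normal tail is used.
#'
#' @param score Observed score statistic (on the adjusted genotype).
#' @param g Dosage vector (adjusted internally for covariates).
#' @param null A binomial [fit_null_model()] object.
#' @param spa_switch Standardized-score threshold for switching to SPA.
#' @return A two-sided p-value in `(0, 1]`.
#' @export
saddlepoint_pvalue <- function(score, g, null, spa_switch = 2) {
  stopifnot(null$family == "binomial")
  # covariate-adjusted genotype: score contributions g_adj_i (Y_i - mu_i)
  B <- crossprod(null$X, null$w * g)
  gadj <- g - drop(null$X %*% (null$A %*% B))
  # the covariate projection leaves the score unchanged (residuals are
  # X-orthogonal at the MLE), so the caller's statistic is used directly
  s <- score
  V <- sum(null$w * gadj^2)
  if (V <= 0) return(1)
  z <- s / sqrt(V)
  if (abs(z) < 1e-12) return(1)
  if (abs(z) < spa_switch) {
    return(max(2 * stats::pnorm(-abs(z)), 1e-300))
  }
  # mid-lattice continuity correction: for rare variants the score is
  # near-lattice with spacing set by the carrier dosages, and evaluating
  # the continuous saddlepoint tail half a jump below the observed score
  # approximates the discrete mid-p tail
  big <- abs(gadj) > 0.5 * max(abs(gadj))
  delta <- if (sum(big) <= 100) 0.5 * min(abs(gadj)[big]) else 0
  s_eff <- max(abs(s) - delta, abs(s) / 2)
  p_up <- spa_tail(s_eff, gadj, null$mu)
  p_lo <- spa_tail(s_eff, -gadj, null$mu)
  if (is.na(p_up) || is.na(p_lo)) {
    warning("saddlepoint root-finding failed; using normal tail")
    return(max(2 * stats::pnorm(-abs(z)), 1e-300))
  }
  max(min(p_up + p_lo, 1), 1e-300)
}

# P(S >= s) for S = sum_i c_i (Y_i - mu_i), Y_i ~ Bernoulli(mu_i).
# Cumulant computations are written in overflow-stable form so the
# saddlepoint can be followed arbitrarily far into the tail (scores near
# the supremum arise for rare variants whose carriers are all cases).
spa_tail <- function(s, c, mu) {
  # log(1 - mu + mu e^x), elementwise, stable for large |x|
  log_mgf <- function(x) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- x[pos] + log(mu[pos] + (1 - mu[pos]) * exp(-x[pos]))
    out[!pos] <- log1p(mu[!pos] * (exp(x[!pos]) - 1))
    out
  }
  # carrier probability pr_i(t) = mu e^{ct} / (1 - mu + mu e^{ct})
  prob_t <- function(t) 1 / (1 + (1 - mu) / mu * exp(-c * t))
  K <- function(t) sum(log_mgf(c * t)) - t * sum(c * mu)
  K1 <- function(t) sum(c * prob_t(t)) - sum(c * mu)
  K2 <- function(t) {
    pr <- prob_t(t)
    sum(c^2 * pr * (1 - pr))
  }
  smax <- sum(c[c > 0]) - sum(c * mu)  # sup of attainable scores
  if (s > smax - 1e-12) {
    # boundary: the event is "every positive-c carrier slot is a case and
    # every negative-c slot a control"; its exact probability
    return(exp(sum(log(mu[c > 0])) + sum(log(1 - mu[c < 0]))))
  }
  root <- tryCatch({
    up <- 1
    while (K1(up) < s && up < 2^20) up <- up * 2
    stats::uniroot(function(t) K1(t) - s, lower = 0, upper = up,
                   tol = 1e-12)$root
  }, error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  if (abs(root) < 1e-10) {
    return(stats::pnorm(s / sqrt(K2(0)), lower.tail = FALSE))
  }
  w <- sign(root) * sqrt(2 * (root * s - K(root)))
  v <- root * sqrt(K2(root))
  if (!is.finite(w) || !is.finite(v) || w == 0) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

#' Beta(1, 25) allele-frequency weights
#'
#' The standard rare-variant weighting: the Beta(1, 25) density evaluated
#' at the MAF, which up-weights rarer variants smoothly.
#'
#' @param maf Minor allele frequencies.
#' @return Nonnegative weights.
#' @export
beta_maf_weights <- function(maf) stats::dbeta(maf, 1, 25)

#' Burden score test
#'
#' Score test of the weighted dosage sum `b_i = sum_j w_j G_ij` against the
#' outcome, adjusting for covariates. Powered against same-direction
#' effects of the variants in the window.
#'
#' @param null A [fit_null_model()] object.
#' @param G Dosage matrix for the window's variants (n x k).
#' @param weights Per-variant nonnegative weights.
#' @return A p-value in `(0, 1]`.
#' @export
burden_test <- function(null, G, weights = rep(1, ncol(as.matrix(G)))) {
  G <- as.matrix(G)
  stopifnot(length(weights) == ncol(G))
  if (all(weights == 0)) stop("all burden weights are zero", call. = FALSE)
  b <- drop(G %*% weights)
  if (stats::var(b) == 0) stop("burden vector has zero variance", call. = FALSE)
  single_variant_test(null, b)
}

#' Dispersion (SKAT) test
#'
#' Variance-component quadratic-form test
#' `Q = sum_j w_j^2 (g_j' res)^2`, whose null distribution is a mixture of
#' 1-df chi-squares weighted by the eigenvalues of the covariate-projected,
#' weighted genotype cross-product. Powered against mixed-direction
#' effects. The mixture tail is computed by numerical inversion with a
#' saddlepoint far-tail and a moment-matching fallback (see [pchisqmix()]).
#'
#' @inheritParams burden_test
#' @param eigen_tol Relative eigenvalue cutoff; eigenvalues below
#'   `eigen_tol * max(eigenvalue)` are dropped.
#' @return A p-value in `(0, 1]`.
#' @export
skat_test <- function(null, G, weights = rep(1, ncol(as.matrix(G))),
                      eigen_tol = 1e-10) {
  G <- as.matrix(G)
  si <- score_ingredients(null, G)
  E <- crossprod(G, null$w * G) - crossprod(si$B, null$A %*% si$B)
  K <- E * tcrossprod(weights)
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > eigen_tol * max(lambda, 0)]
  if (!length(lambda)) stop("all SKAT eigenvalues are zero", call. = FALSE)
  Q <- sum((weights * si$U)^2)
  pchisqmix(Q, lambda)
}

#' Ultra-rare variant burden test
#'
#' Unweighted burden (carrier-count) score test over the window's
#' ultra-rare variants (MAC < 5) only. Single-variant tests are
#' uninformative at such counts; aggregating them recovers power against
#' combined effects of singletons and doubletons.
#'
#' @param null A [fit_null_model()] object.
#' @param G Dosage matrix of the ultra-rare variants in the window.
#' @return A p-value in `(0, 1]`.
#' @export
ultra_rare_burden <- function(null, G) {
  burden_test(null, as.matrix(G), rep(1, ncol(as.matrix(G))))
}

#' Cauchy combination of p-values (ACAT)
#'
#' Combines p-values with `T = sum_j w_j tan((0.5 - p_j) pi) / sum_j w_j`
#' and `p = 0.5 - atan(T)/pi`. The combination is calibrated under
#' arbitrary dependence of the inputs, which is what makes it usable for
#' the overlapping, correlated tests in a window ensemble. Inputs at or
#' above `1 - 1e-15` are truncated there; inputs below `1e-15` use the tan
#' asymptote `1/(p pi)` for numerical stability.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param weights Optional nonnegative weights (default equal).
#' @return Combined p-value in `(0, 1]`.
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (!length(p)) stop("empty p-value list", call. = FALSE)
  stopifnot(all(p > 0), all(p <= 1))
  if (is.null(weights)) weights <- rep(1, length(p))
  p <- pmin(p, 1 - 1e-15)
  t_j <- numeric(length(p))
  tiny <- p < 1e-15
  t_j[tiny] <- 1 / (p[tiny] * pi)
  t_j[!tiny] <- tanpi(0.5 - p[!tiny])
  T_stat <- sum(weights * t_j) / sum(weights)
  pv <- if (T_stat > 1e15) 1 / (T_stat * pi) else 0.5 - atan(T_stat) / pi
  max(min(pv, 1), 1e-300)
}
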