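test_that("null model reduces to the sample mean / prevalence with intercept only", {
  set.seed(1)
  y <- rnorm(50)
  null <- fit_null_model(tibble::tibble(y = y), "y", family = "gaussian")
  expect_equal(unique(null$mu), mean(y))
  yb <- rbinom(200, 1, 0.3)
  nb <- fit_null_model(tibble::tibble(y = yb), "y", family = "binomial")
  expect_equal(unique(nb$mu), mean(yb))
})

test_that("null model coefficients match a normal-equations solve and residuals are X-orthogonal", {
  set.seed(2)
  d <- tibble::tibble(x1 = rnorm(80), y = 1 + 2 * rnorm(80))
  null <- fit_null_model(d, "y", "x1", "gaussian")
  X <- cbind(1, d$x1)
  expect_equal(drop(crossprod(X, null$residuals)), c(0, 0), tolerance = 1e-9)
  mu_hat <- drop(X %*% solve(crossprod(X), crossprod(X, d$y)))
  expect_equal(unname(null$mu), mu_hat, tolerance = 1e-9)
  expect_error(fit_null_model(tibble::tibble(y = rep(1, 10)), "y"), "constant")
  expect_error(
    fit_null_model(tibble::tibble(y = rnorm(10), a = 1:10, b = 2 * (1:10)),
                   "y", c("a", "b")),
    "rank"
  )
})

test_that("single-variant score test matches the classical 2x2 chi-square for binary traits", {
  set.seed(3)
  n <- 500
  g <- rbinom(n, 1, 0.3)          # carrier indicator, one allele
  y <- rbinom(n, 1, 0.4)
  null <- fit_null_model(tibble::tibble(y = y), "y", family = "binomial")
  p_got <- single_variant_test(null, g, use_spa = FALSE)
  # classical score test on the collapsed table = Pearson chi-square
  p_chisq <- suppressWarnings(chisq.test(table(g, y), correct = FALSE)$p.value)
  expect_equal(p_got, p_chisq, tolerance = 1e-6)
})

test_that("a genotype already in the covariates gives score ~ 0, p ~ 1", {
  set.seed(4)
  g <- rbinom(300, 2, 0.3)
  d <- tibble::tibble(y = rnorm(300) + 0.5 * g, g = g)
  null <- fit_null_model(d, "y", "g", "gaussian")
  expect_gt(single_variant_test(null, g), 0.999)
  expect_error(single_variant_test(null, rep(1, 300)), "zero-variance")
})

test_that("score-test p-values are uniform under the null (KS)", {
  set.seed(5)
  n <- 300
  ps <- replicate(500, {
    d <- tibble::tibble(y = rnorm(n), x1 = rnorm(n))
    null <- fit_null_model(d, "y", "x1", "gaussian")
    single_variant_test(null, rbinom(n, 2, 0.3))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("tests are invariant to affine recoding of covariates", {
  set.seed(6)
  n <- 250
  x <- rnorm(n)
  d1 <- tibble::tibble(y = rnorm(n) + x, x1 = x)
  d2 <- tibble::tibble(y = d1$y, x1 = 100 + 7 * x)
  g <- rbinom(n, 2, 0.25)
  G <- cbind(g, rbinom(n, 2, 0.1))
  n1 <- fit_null_model(d1, "y", "x1", "gaussian")
  n2 <- fit_null_model(d2, "y", "x1", "gaussian")
  expect_equal(single_variant_test(n1, g), single_variant_test(n2, g),
               tolerance = 1e-8)
  expect_equal(burden_test(n1, G, c(1, 2)), burden_test(n2, G, c(1, 2)),
               tolerance = 1e-8)
  expect_equal(skat_test(n1, G, c(1, 2)), skat_test(n2, G, c(1, 2)),
               tolerance = 1e-6)
})

test_that("saddlepoint p-value: symmetry, near-Gaussian agreement, and unbalanced accuracy", {
  set.seed(7)
  n <- 2000
  # balanced design: SPA close to the normal tail
  yb <- rbinom(n, 1, 0.5)
  nb <- fit_null_model(tibble::tibble(y = yb), "y", family = "binomial")
  g <- rbinom(n, 2, 0.3)
  si <- kscreen:::score_ingredients(nb, g)
  p_norm <- 2 * pnorm(-abs(si$U) / sqrt(si$V))
  p_spa <- saddlepoint_pvalue(si$U, g, nb, spa_switch = 0)
  if (abs(si$U / sqrt(si$V)) > 0.3) {
    expect_equal(p_spa, p_norm, tolerance = 0.1 * p_norm + 0.01)
  }
  # zero score
  expect_equal(saddlepoint_pvalue(0, g, nb), 1)

  # 1:49 case:control imbalance, rare variant: SPA tracks the permutation
  # oracle where the normal tail does not
  set.seed(8)
  n <- 3000
  y <- rbinom(n, 1, 0.02)
  # carriers enriched among cases so the observed score is informative
  g <- numeric(n)
  g[sample(which(y == 1), 4)] <- 1
  g[sample(which(y == 0), 16)] <- 1
  null <- fit_null_model(tibble::tibble(y = y), "y", family = "binomial")
  obs <- sum(g * null$residuals)
  perm <- replicate(2e4, {
    gp <- sample(g)
    sum(gp * null$residuals)
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (2e4 + 1)
  p_spa <- saddlepoint_pvalue(obs, g, null, spa_switch = 0)
  si <- kscreen:::score_ingredients(null, g)
  p_norm <- 2 * pnorm(-abs(si$U) / sqrt(si$V))
  skip_if(p_perm > 0.4)  # uninformative draw
  expect_lt(abs(log(p_spa / p_perm)), log(2))
})

test_that("burden test reduces to the single-variant test and matches a permutation oracle", {
  set.seed(9)
  n <- 400
  d <- tibble::tibble(y = rnorm(n), x1 = rnorm(n))
  null <- fit_null_model(d, "y", "x1", "gaussian")
  g <- rbinom(n, 2, 0.3)
  expect_equal(burden_test(null, cbind(g), 1), single_variant_test(null, g))
  expect_error(burden_test(null, cbind(g, g), c(0, 0)), "zero")

  # 3-variant toy vs permutation oracle
  set.seed(10)
  n <- 150
  G <- matrix(rbinom(3 * n, 2, 0.2), n, 3)
  y <- rnorm(n) + 0.4 * G[, 1]
  null <- fit_null_model(tibble::tibble(y = y), "y", family = "gaussian")
  w <- c(1, 0.5, 2)
  p_got <- burden_test(null, G, w)
  b <- drop(G %*% w)
  obs <- abs(sum(b * null$residuals)) / sd(b)
  perm <- replicate(2e4, {
    bp <- b[sample.int(n)]
    abs(sum(bp * null$residuals)) / sd(bp)
  })
  p_perm <- (1 + sum(perm >= obs - 1e-12)) / (2e4 + 1)
  expect_lt(abs(p_got - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 2e4) + 0.01)
})

test_that("SKAT: 1-df reduction, null uniformity, and mixture-sampling oracle", {
  set.seed(11)
  n <- 300
  d <- tibble::tibble(y = rnorm(n), x1 = rnorm(n))
  null <- fit_null_model(d, "y", "x1", "gaussian")
  g <- rbinom(n, 2, 0.3)
  expect_equal(skat_test(null, cbind(g), 1),
               single_variant_test(null, g), tolerance = 1e-3)

  ps <- replicate(500, {
    dd <- tibble::tibble(y = rnorm(n))
    nn <- fit_null_model(dd, "y", family = "gaussian")
    skat_test(nn, matrix(rbinom(5 * n, 2, 0.2), n, 5))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # 5-variant toy: simulate from the fitted chi-square mixture
  set.seed(12)
  G <- matrix(rbinom(5 * n, 2, 0.25), n, 5)
  y <- rnorm(n)
  nn <- fit_null_model(tibble::tibble(y = y), "y", family = "gaussian")
  w <- rep(1, 5)
  si <- kscreen:::score_ingredients(nn, G)
  E <- kscreen:::safe_cor(G) * 0  # placeholder; recompute below
  E <- crossprod(G, nn$w * G) - crossprod(si$B, nn$A %*% si$B)
  lam <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam)]
  Q <- sum(si$U^2)
  draws <- colSums(lam * matrix(rchisq(length(lam) * 1e5, 1), length(lam)))
  p_mc <- mean(draws > Q)
  p_got <- skat_test(nn, G, w)
  expect_lt(abs(p_got - p_mc), 4 * sqrt(max(p_mc, 1e-4) / 1e5) + 0.005)
})

test_that("ultra-rare burden equals the single-singleton test and gains power by aggregation", {
  set.seed(13)
  n <- 800
  g1 <- c(rep(1, 3), rep(0, n - 3))
  d <- tibble::tibble(y = rnorm(n))
  null <- fit_null_model(d, "y", family = "gaussian")
  expect_equal(ultra_rare_burden(null, cbind(g1)),
               single_variant_test(null, g1))

  # effect injected on the carriers of 10 singletons: the aggregate should
  # usually beat the best the individual tests would need
  wins <- replicate(60, {
    G <- matrix(0, n, 10)
    for (j in 1:10) G[sample.int(n, 3), j] <- 1
    y <- rnorm(n) + 0.8 * rowSums(G)
    nn <- fit_null_model(tibble::tibble(y = y), "y", family = "gaussian")
    p_agg <- ultra_rare_burden(nn, G)
    p_ind <- vapply(1:10, function(j) single_variant_test(nn, G[, j]),
                    numeric(1))
    p_agg < min(p_ind)
  })
  expect_gte(mean(wins), 0.8)
})

test_that("Cauchy combination: fixed points, identity, and null uniformity", {
  expect_equal(cauchy_combine(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(cauchy_combine(0.137), 0.137, tolerance = 1e-12)
  expect_error(cauchy_combine(numeric(0)), "empty")
  # extreme inputs stay finite and ordered
  expect_gt(cauchy_combine(c(1e-320, 0.5)), 0)
  expect_lt(cauchy_combine(c(1e-320, 0.5)), 1e-300 * 1e10 + 1e-10)
  expect_lte(cauchy_combine(c(1 - 1e-16, 1 - 1e-16)), 1)

  set.seed(14)
  ps <- replicate(2000, cauchy_combine(runif(7)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
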