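test_that("tight-LD clustering groups duplicates and leaves independent variants alone", {
  set.seed(1)
  g <- rbinom(200, 2, 0.4)
  dup <- toy_panel(cbind(g, g, rbinom(200, 2, 0.4)))
  cl <- ld_clusters(dup)
  expect_equal(cl[1], cl[2])
  expect_false(cl[3] == cl[1])

  indep <- toy_panel(matrix(rbinom(600, 2, 0.4), 200, 3))
  expect_equal(length(unique(ld_clusters(indep))), 3)
})

test_that("no cross-cluster pair exceeds |r| = 0.75 after the cut (chained toy)", {
  # A-B and B-C tightly linked, A-C moderately: the chain must merge
  set.seed(2)
  n <- 2000
  z1 <- rnorm(n); z2 <- 0.95 * z1 + sqrt(1 - 0.95^2) * rnorm(n)
  z3 <- 0.95 * z2 + sqrt(1 - 0.95^2) * rnorm(n)
  w1 <- rnorm(n); w2 <- 0.95 * w1 + sqrt(1 - 0.95^2) * rnorm(n)
  w3 <- 0.95 * w2 + sqrt(1 - 0.95^2) * rnorm(n)
  th <- qnorm(0.6)
  dos <- cbind((z1 > th) + (w1 > th), (z2 > th) + (w2 > th),
               (z3 > th) + (w3 > th), rbinom(n, 2, 0.4))
  panel <- toy_panel(dos)
  r <- abs(cor(dos))
  skip_if(r[1, 2] <= 0.75 || r[2, 3] <= 0.75)  # construction check only
  cl <- ld_clusters(panel)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[2], cl[3])
  # exhaustive guarantee check on the toy
  for (i in 1:3) for (j in 4) {
    if (cl[i] != cl[j]) expect_lte(r[i, j], 0.75)
  }
})

test_that("neighbor selection matches a brute-force sort and respects the caps", {
  expect_equal(kscreen:::neighbor_cap(1000), 10L)
  expect_equal(kscreen:::neighbor_cap(27), 3L)

  set.seed(3)
  panel <- simulate_genotypes(400, 40, seed = 3)
  cl <- ld_clusters(panel)
  r <- kscreen:::safe_cor(panel$dosages)
  v <- variant_info(panel)
  for (j in c(1, 7, 20, 40)) {
    got <- select_neighbors(panel, cl, j, r = r)
    # brute-force oracle
    cand <- setdiff(which(abs(v$pos - v$pos[j]) <= 1e5 & cl != cl[j]), j)
    cand <- cand[abs(r[cand, j]) > 0.05]
    ord <- cand[order(-abs(r[cand, j]), abs(v$pos[cand] - v$pos[j]), cand)]
    want <- ord[seq_len(min(kscreen:::neighbor_cap(400), length(ord)))]
    expect_equal(got, want)
    expect_false(any(cl[got] == cl[j]))
  }

  # isolated variant: no |r| > 0.05 partner
  iso <- toy_panel(matrix(rbinom(20000, 2, 0.4), 10000, 2))
  cli <- ld_clusters(iso)
  if (abs(cor(iso$dosages))[1, 2] <= 0.05) {
    expect_length(select_neighbors(iso, cli, 1), 0)
  }
})

test_that("conditional mean fit matches an independent normal-equations solve", {
  set.seed(4)
  panel <- simulate_genotypes(200, 6, seed = 4)
  fit <- fit_conditional_mean(panel, list(), neighbors = 2:6, j = 1)
  X <- cbind(1, panel$dosages[, 2:6])
  beta <- solve(crossprod(X), crossprod(X, panel$dosages[, 1]))
  expect_equal(unname(fit$coef), unname(drop(beta)), tolerance = 1e-8)
  expect_equal(mean(fit$residual), 0, tolerance = 1e-10)

  # empty design reduces to the intercept-only fit
  f0 <- fit_conditional_mean(panel, list(), integer(0), 3)
  expect_equal(f0$fitted, rep(mean(panel$dosages[, 3]), 200))

  # exact linear dependence gives ~zero residual, rank deficiency tolerated
  lin <- toy_panel(cbind(panel$dosages[, 1], panel$dosages[, 1] * 2,
                         panel$dosages[, 1] * 2))
  fl <- fit_conditional_mean(lin, list(), neighbors = 2:3, j = 1)
  expect_lt(max(abs(fl$residual)), 1e-6)
})

test_that("single-variant knockoffs are permutations preserving marginal moments", {
  set.seed(5)
  panel <- toy_panel(matrix(rbinom(500, 2, 0.25), 500, 1))
  kn <- generate_knockoffs(panel, M = 3, seed = 9)
  g <- panel$dosages[, 1]
  for (m in 1:3) {
    gk <- kn$copies[[m]][, 1]
    expect_equal(mean(gk), mean(g))
    expect_equal(var(gk), var(g))
    expect_equal(sort(gk), sort(g))  # exact permutation of the column
  }
})

test_that("knockoffs reproduce cross-variant correlation (exchangeability) and same seed is bit-identical", {
  set.seed(6)
  reps <- 40
  diffs <- replicate(reps, {
    dos <- correlated_dosages(2000, 0.6)
    panel <- toy_panel(dos)
    kn <- generate_knockoffs(panel, M = 1, seed = sample.int(1e6, 1))
    cor(panel$dosages[, 1], kn$copies[[1]][, 2]) -
      cor(panel$dosages[, 1], panel$dosages[, 2])
  })
  expect_lt(abs(mean(diffs)), 0.05)

  # independent pair: knockoff stays uncorrelated
  set.seed(7)
  panel0 <- toy_panel(matrix(rbinom(8000, 2, 0.3), 4000, 2))
  kn0 <- generate_knockoffs(panel0, M = 1, seed = 11)
  expect_lt(abs(cor(panel0$dosages[, 1], kn0$copies[[1]][, 2])), 0.1)

  panel <- simulate_genotypes(300, 30, seed = 8)
  a <- generate_knockoffs(panel, M = 2, seed = 123)
  b <- generate_knockoffs(panel, M = 2, seed = 123)
  expect_identical(a$copies, b$copies)
  c2 <- generate_knockoffs(panel, M = 2, seed = 124)
  expect_false(identical(a$copies, c2$copies))
})

test_that("tight-cluster knockoffs are not near-copies of the originals", {
  set.seed(9)
  n <- 2000
  z <- rnorm(n); z2 <- 0.93 * z + sqrt(1 - 0.93^2) * rnorm(n)
  w <- rnorm(n); w2 <- 0.93 * w + sqrt(1 - 0.93^2) * rnorm(n)
  th <- qnorm(0.5)
  dos <- cbind((z > th) + (w > th), (z2 > th) + (w2 > th),
               rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
  panel <- toy_panel(dos)
  cl <- ld_clusters(panel)
  skip_if(cl[1] != cl[2])  # construction check
  kn <- generate_knockoffs(panel, M = 2, seed = 5)
  for (m in 1:2) {
    expect_lt(cor(panel$dosages[, 1], kn$copies[[m]][, 1]), 0.95)
    expect_lt(cor(panel$dosages[, 2], kn$copies[[m]][, 2]), 0.95)
  }
})

test_that("generation cost scales roughly linearly in p", {
  panel1 <- simulate_genotypes(500, 60, seed = 10)
  panel2 <- simulate_genotypes(500, 120, region_length = 4e5, seed = 10)
  t1 <- min(replicate(3, system.time(
    generate_knockoffs(panel1, M = 2, seed = 1)
  )["elapsed"]))
  t2 <- min(replicate(3, system.time(
    generate_knockoffs(panel2, M = 2, seed = 1)
  )["elapsed"]))
  expect_lt(t2 / t1, 3)  # soft O(np) check: doubling p stays near 2x
})
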