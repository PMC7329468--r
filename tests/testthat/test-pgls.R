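test_that("phylogenetic covariance holds shared path lengths", {
  star <- ape::stree(5, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  v <- build_covariance(star)$v_matrix
  expect_equal(unname(diag(v)), rep(1, 5))
  expect_equal(max(abs(v[upper.tri(v)])), 0)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  v2 <- build_covariance(tr, c("A", "B", "C"))$v_matrix
  expect_equal(v2["A", "B"], 1)
  expect_equal(v2["A", "C"], 0)
  expect_equal(v2["A", "A"], 2)

  expect_error(build_covariance(tr, c("A", "Z")), "Z")
})

test_that("covariances from random birth trees are symmetric and PSD", {
  set.seed(51)
  for (i in 1:20) {
    tr <- simulate_tree(sample(5:40, 1))
    v <- build_covariance(tr)$v_matrix
    expect_equal(v, t(v))
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("the lambda transform scales only off-diagonal entries", {
  tr <- simulate_tree(8, seed = 52)
  cov <- build_covariance(tr)
  v5 <- lambda_transform(cov, 0.5)
  expect_equal(diag(v5), diag(cov$v_matrix))
  off <- upper.tri(v5)
  expect_equal(v5[off], 0.5 * cov$v_matrix[off])
})

test_that("PGLS with lambda 0 reproduces ordinary least squares", {
  tr <- simulate_tree(25, seed = 53)
  x <- rnorm(25); names(x) <- tr$tip.label
  d <- simulate_traits(tr, x, lambda_true = 0.8, slope = 1.5, sigma2 = 2,
                       seed = 54)
  f <- pgls_fit(d, y, x, tr, species = species, lambda = 0)
  ols <- lm(y ~ x, data = d)
  expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(f$p_value, summary(ols)$coefficients[2, 4], tolerance = 1e-8)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("on a star tree PGLS equals OLS for every lambda", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- rnorm(12); names(x) <- star$tip.label
  d <- simulate_traits(star, x, lambda_true = 0, slope = -2, sigma2 = 1,
                       seed = 55)
  ols <- lm(y ~ x, data = d)
  for (lam in c(0, 0.3, 0.7, 1)) {
    f <- pgls_fit(d, y, x, star, species = species, lambda = lam)
    expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-8)
    expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
  }
})

test_that("ML lambda and slope agree with an independent GLS implementation", {
  tr <- simulate_tree(40, seed = 56)
  x <- rnorm(40); names(x) <- tr$tip.label
  d <- simulate_traits(tr, x, lambda_true = 0.7, slope = 1, sigma2 = 1,
                       seed = 57)
  mine <- pgls_fit(d, y, x, tr, species = species)
  dd <- as.data.frame(d)
  rownames(dd) <- dd$species
  ref <- nlme::gls(y ~ x, data = dd,
                   correlation = ape::corPagel(0.5, tr, form = ~species),
                   method = "ML")
  expect_equal(mine$lambda, unname(coef(ref$modelStruct$corStruct)),
               tolerance = 1e-4)
  expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(mine$p_value, summary(ref)$tTable[2, 4], tolerance = 1e-4)
})

test_that("the profiled lambda is a global maximum over the grid", {
  tr <- simulate_tree(30, seed = 58)
  x <- rnorm(30); names(x) <- tr$tip.label
  d <- simulate_traits(tr, x, lambda_true = 0.5, slope = 1, sigma2 = 1,
                       seed = 59)
  f <- pgls_fit(d, y, x, tr, species = species)
  expect_gte(f$logLik, max(f$profile$logLik) - 1e-9)
  # continuity: neighbouring grid points change smoothly
  expect_lt(max(abs(diff(f$profile$logLik))), 10)
})

test_that("a species observed for both organelles enters as two samples", {
  tr <- simulate_tree(10, seed = 60)
  sp <- c(tr$tip.label, tr$tip.label[1]) # duplicate one tip
  cov <- build_covariance(tr, sp)
  v <- cov$v_matrix
  n <- length(sp)
  expect_equal(dim(v), c(n, n))
  dup <- which(sp == sp[1])
  expect_equal(v[dup[1], dup[2]], v[dup[1], dup[1]] - 1e-8)
  expect_silent(chol(v))

  d <- tibble::tibble(species = sp, x = rnorm(n), y = rnorm(n))
  f <- pgls_fit(d, y, x, tr, species = species)
  expect_equal(f$n, 11)
  expect_true(is.finite(f$p_value))
})

test_that("degenerate designs are rejected", {
  tr <- simulate_tree(6, seed = 61)
  d <- tibble::tibble(species = tr$tip.label, x = rep(1, 6), y = rnorm(6))
  expect_error(pgls_fit(d, y, x, tr, species = species), "singular")
  expect_error(pgls_fit(d[1:2, ], y, x, tr, species = species), "at least 3")
})

test_that("trait simulation honours its covariance contract", {
  tr <- simulate_tree(12, seed = 62)
  x <- rnorm(12); names(x) <- tr$tip.label
  d0 <- simulate_traits(tr, x, lambda_true = 1, slope = 3, intercept = -1,
                        sigma2 = 0, seed = 63)
  expect_equal(d0$y, -1 + 3 * d0$x, tolerance = 1e-12)

  # empirical covariance approaches sigma2 * V(lambda)
  v <- lambda_transform(build_covariance(tr), 0.6)
  set.seed(64)
  eps <- replicate(3000, {
    d <- simulate_traits(tr, x, lambda_true = 0.6, slope = 0, sigma2 = 1)
    d$y
  })
  emp <- cov(t(eps))
  expect_lt(max(abs(emp - v)), 0.35 * max(diag(v)))
})
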