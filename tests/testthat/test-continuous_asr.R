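test_that("BM likelihood matches direct dense evaluation", {
  ## single-branch reduction: N(root, sigma2 * v) density
  t2 <- ape::read.tree(text = "(A:1.5,B:0.5);")
  x <- c(A = 3.2, B = 2.4)
  ll <- bm_loglik(t2, x, sigma2 = 0.8, root_state = 3, lambda = 1)
  C <- 0.8 * tree_covariance(t2, 1)
  r <- x[c("A", "B")] - 3
  direct <- -0.5 * (2 * log(2 * pi) + log(det(C)) +
                      drop(t(r) %*% solve(C) %*% r))
  expect_equal(ll, direct, tolerance = 1e-10)

  ## 3-tip fixture against dense linear algebra
  tr <- tree3()
  x3 <- c(A = 3.1, B = 2.7, C = 3.9)
  C3 <- 0.5 * tree_covariance(tr, 0.7)
  r3 <- x3[rownames(C3)] - 2.9
  direct3 <- -0.5 * (3 * log(2 * pi) + log(det(C3)) +
                       drop(t(r3) %*% solve(C3) %*% r3))
  expect_equal(bm_loglik(tr, x3, 0.5, 2.9, 0.7), direct3, tolerance = 1e-10)

  ## lambda = 0 is the independent-tips limit
  ll0 <- bm_loglik(tr, x3, 0.5, 2.9, 0)
  depths <- diag(tree_covariance(tr, 1))
  expect_equal(ll0, sum(dnorm(x3[names(depths)], 2.9,
                              sqrt(0.5 * depths), log = TRUE)),
               tolerance = 1e-10)
})

test_that("lambda profile fit dominates a grid and flags boundaries", {
  set.seed(61)
  tr <- simulate_tree(50)
  C <- tree_covariance(tr, 1)
  x <- setNames(drop(t(chol(C)) %*% rnorm(50)) + 3, tr$tip.label)
  f <- fit_lambda(tr, x)
  for (lam in c(0, 0.5, 1)) {
    fl <- fit_bm(tr, x, lambda = lam)
    expect_gte(f$loglik, fl$loglik - 1e-6)
  }
  expect_error(fit_lambda(ape::read.tree(text = "(A:1,B:1);"),
                          c(A = 1, B = 2)), "4 tips")
})

test_that("lambda recovery separates Brownian from unstructured data", {
  set.seed(62)
  tr <- simulate_tree(80)
  C <- tree_covariance(tr, 1)
  L <- t(chol(C))
  lam_bm <- replicate(20, fit_lambda(
    tr, setNames(drop(L %*% rnorm(80)) + 3, tr$tip.label))$lambda)
  lam_iid <- replicate(20, fit_lambda(
    tr, setNames(rnorm(80, 3, 0.5), tr$tip.label))$lambda)
  expect_gte(median(lam_bm), 0.85)
  expect_lte(median(lam_iid), 0.15)
})

test_that("lambda and ancestral estimates agree with phytools", {
  skip_if_not_installed("phytools")
  set.seed(63)
  tr <- simulate_tree(40)
  C <- tree_covariance(tr, 1)
  x <- setNames(drop(t(chol(C)) %*% rnorm(40)) * 0.4 + 3, tr$tip.label)
  f <- fit_lambda(tr, x)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(f$lambda, min(ps$lambda, 1), tolerance = 0.02)

  fa <- phytools::fastAnc(tr, x, CI = TRUE)
  mine <- anc_states(tr, x, fit_bm(tr, x, lambda = 1))
  est <- mine$estimate[mine$type == "internal"]
  expect_equal(est, unname(fa$ace), tolerance = 1e-5)
  ## interval shape agrees closely; fastAnc's rate estimate uses a slightly
  ## different denominator so half-widths differ at the percent level
  hw_mine <- mine$estimate[mine$type == "internal"] - mine$ci_lo[mine$type == "internal"]
  hw_fa <- unname(fa$ace - fa$CI95[, 1])
  expect_equal(hw_mine, hw_fa, tolerance = 0.03)
})

test_that("ancestral states match the dense conditional-MVN oracle", {
  set.seed(64)
  tr <- random_tree(6)
  x <- setNames(rnorm(6, 3, 0.7), tr$tip.label)
  f <- fit_bm(tr, x, lambda = 0.8)
  mine <- anc_states(tr, x, f)
  orc <- oracle_anc(tr, x, f)
  idx <- mine$type == "internal"
  ## the oracle's flat-root prior is approximated by a large but finite
  ## prior variance, so agreement is to ~1/ridge
  expect_equal(mine$estimate[idx], orc$estimate, tolerance = 1e-3)
  expect_equal(mine$var[idx], orc$var, tolerance = 1e-3)
})

test_that("ancestral reconstruction has GLS symmetry and equivariance", {
  ## two-tip symmetric tree: root is the average
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  x <- c(A = 2.2, B = 3.8)
  res <- anc_states(t2, x, fit_bm(t2, x, lambda = 1))
  root <- res[res$type == "internal", ]
  expect_equal(root$estimate, 3)
  expect_equal(root$estimate - root$ci_lo, root$ci_hi - root$estimate)

  ## translation equivariance
  set.seed(65)
  tr <- random_tree(8)
  x8 <- setNames(rnorm(8, 3), tr$tip.label)
  f <- fit_bm(tr, x8, 1)
  r1 <- anc_states(tr, x8, f)
  f2 <- fit_bm(tr, x8 + 5, 1)
  r2 <- anc_states(tr, x8 + 5, f2)
  expect_equal(r2$estimate, r1$estimate + 5, tolerance = 1e-9)
  expect_equal(r2$var, r1$var, tolerance = 1e-9)

  ## root estimate lies inside the observed range; doubling deviations
  ## doubles the deviations of every node estimate
  for (i in 1:10) {
    trr <- random_tree(10)
    xr <- setNames(rnorm(10, 3), trr$tip.label)
    rr <- anc_states(trr, xr, fit_bm(trr, xr, 1))
    root <- rr$estimate[rr$node == 11]
    expect_gte(root, min(xr)); expect_lte(root, max(xr))
    m <- mean(xr)
    x2 <- m + 2 * (xr - m)
    rr2 <- anc_states(trr, x2, fit_bm(trr, x2, 1))
    expect_equal(rr2$estimate - m, 2 * (rr$estimate - m), tolerance = 1e-8)
  }
})

test_that("root credible coverage is near nominal under Brownian truth", {
  set.seed(66)
  tr <- simulate_tree(50)
  L <- t(chol(tree_covariance(tr, 1)))
  hits <- replicate(500, {
    x <- setNames(drop(L %*% rnorm(50)) * 0.6 + 3, tr$tip.label)
    res <- anc_states(tr, x, fit_bm(tr, x, lambda = 1))
    root <- res[res$node == 51, ]
    root$ci_lo <= 3 && 3 <= root$ci_hi
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})
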