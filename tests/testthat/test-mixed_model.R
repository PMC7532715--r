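## short chains keep these tests fast; the sampler's block update makes
## location-effect draws nearly independent so 500-1000 retained suffice
quick_chain <- function(seed, niter = 4000, burnin = 1000, thin = 3) {
  list(niter = niter, burnin = burnin, thin = thin, seed = seed)
}

make_id_traits <- function(n_per_group = 30, sd = 0.05, seed = 1) {
  set.seed(seed)
  g <- rep(akc_groups(), each = n_per_group)
  n <- length(g)
  y <- pmin(pmax(c(Herding = 3.3, Hound = 3.1, `Non-sporting` = 2.7,
                   Sporting = 3.6, Terrier = 3.2, Toy = 2.5,
                   Working = 3.0)[g] + rnorm(n, 0, sd), 1), 5)
  breeds <- sprintf("B%03d", seq_len(n))
  traits <- data.frame(breed = breeds, mean = y, var = 0, n = 1000L, group = g)
  I <- diag(n); dimnames(I) <- list(breeds, breeds)
  list(traits = traits, I = I)
}

test_that("with identity structure the posterior means match group means", {
  d <- make_id_traits(n_per_group = 30, sd = 0.05, seed = 3)
  spec <- mm_spec(d$traits, d$I, d$I, chain = quick_chain(5))
  f <- fit_mm(spec)
  obs <- tapply(d$traits$mean, d$traits$group, mean)
  expect_lt(max(abs(colMeans(f$beta) - obs[f$groups])), 0.02)
  expect_true(all(c(f$sigma2_a, f$sigma2_b, f$sigma2_e) > 0))
  expect_equal(nrow(f$beta), 1000)
})

test_that("a zero-variance response collapses to the prior floor", {
  d <- make_id_traits(n_per_group = 5, sd = 0, seed = 1)
  d$traits$mean <- 3
  spec <- mm_spec(d$traits, d$I, d$I, chain = quick_chain(2))
  f <- fit_mm(spec)
  expect_lt(max(abs(colMeans(f$beta) - 3)), 0.05)
  expect_lt(median(f$sigma2_a), 0.01)
  expect_lt(median(f$sigma2_e), 0.01)
})

test_that("chains are reproducible from the seed and exchangeable in breed order", {
  s <- simulate_study(sim_config(n_breeds = 40, n_per_breed = 40, seed = 12))
  tt <- aggregate_scores(s$individuals, s$groups)
  f1 <- fit_mm(mm_spec(tt, s$A, s$H, chain = quick_chain(9)))
  f2 <- fit_mm(mm_spec(tt, s$A, s$H, chain = quick_chain(9)))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2_a, f2$sigma2_a)

  ## permuting the breed rows (matrices are joined by label) changes nothing
  ## but Monte Carlo noise
  perm <- sample(nrow(tt))
  f3 <- fit_mm(mm_spec(tt[perm, ], s$A, s$H, chain = quick_chain(9)))
  expect_lt(max(abs(apply(f1$beta, 2, median) - apply(f3$beta, 2, median))), 0.15)
})

test_that("measurement error variances are honoured as known noise", {
  ## same data, much larger mev: posterior residual variance cannot absorb
  ## it, so beta uncertainty grows
  d <- make_id_traits(n_per_group = 15, sd = 0.3, seed = 8)
  t_small <- d$traits; t_small$var <- 0.001 * t_small$n
  t_big <- d$traits; t_big$var <- 0.5 * t_big$n
  f_small <- fit_mm(mm_spec(t_small, d$I, d$I, chain = quick_chain(3)))
  f_big <- fit_mm(mm_spec(t_big, d$I, d$I, chain = quick_chain(3)))
  w_small <- mean(apply(f_small$beta, 2, sd))
  w_big <- mean(apply(f_big$beta, 2, sd))
  expect_gt(w_big, w_small)
})

test_that("DIC has positive effective parameters and needs enough draws", {
  s <- simulate_study(sim_config(n_breeds = 40, n_per_breed = 40, seed = 13))
  tt <- aggregate_scores(s$individuals, s$groups)
  f <- fit_mm(mm_spec(tt, s$A, s$H, chain = quick_chain(4)))
  expect_gt(attr(f$dic, "pD"), 0)
  f_short <- f; f_short$retained <- 50
  expect_error(mm_dic(f_short), "100 retained")
})

test_that("contrast pMCMC follows its definition and floor", {
  fake <- structure(list(
    beta = cbind(Herding = rep(c(3, 3.2), 250), Toy = rep(c(3, 3.2), 250),
                 Sporting = rep(c(3, 3.2), 250) + 2),
    groups = c("Herding", "Toy", "Sporting")), class = "mm_fit")
  ct <- group_contrasts(fake)
  ht <- ct[ct$group1 == "Herding" & ct$group2 == "Toy", ]
  expect_equal(ht$pMCMC, 1)           # identical chains
  hs <- ct[ct$group1 == "Herding" & ct$group2 == "Sporting", ]
  expect_equal(hs$pMCMC, 2 / 500)     # all differences one-sided: floor
  expect_true(hs$significant)
  expect_equal(nrow(ct), choose(3, 2))

  ## bonferroni flag multiplies by the number of pairs
  ctb <- group_contrasts(fake, bonferroni = TRUE)
  expect_equal(ctb$pMCMC[ctb$group1 == "Herding" & ctb$group2 == "Sporting"],
               2 / 500 * 3)
})

test_that("group posterior summaries are coherent five-number summaries", {
  set.seed(20)
  fake <- structure(list(
    beta = cbind(A = rnorm(2000, 3, 0.1), B = rnorm(2000, 3.5, 0.1)),
    group_level = cbind(A = rnorm(2000, 3.1, 0.1), B = rnorm(2000, 3.4, 0.1)),
    groups = c("A", "B")), class = "mm_fit")
  sm <- group_posterior_summary(fake)
  expect_equal(sm$median, sm$mean, tolerance = 0.02)
  expect_true(all(sm$min <= sm$lower & sm$lower <= sm$median &
                    sm$median <= sm$upper & sm$upper <= sm$max))
  ## thinning by two moves the median only within Monte Carlo error
  fake2 <- fake
  fake2$beta <- fake$beta[seq(1, 2000, 2), ]
  fake2$group_level <- fake$group_level[seq(1, 2000, 2), ]
  sm2 <- group_posterior_summary(fake2)
  expect_lt(max(abs(sm2$median - sm$median)), 0.05)
})

test_that("prior scale is not driving the variance estimates", {
  s <- simulate_study(sim_config(n_breeds = 60, n_per_breed = 200, seed = 21))
  tt <- aggregate_scores(s$individuals, s$groups)
  f1 <- fit_mm(mm_spec(tt, s$A, s$H, priors = list(V = 0.5),
                       chain = quick_chain(6, niter = 6000, burnin = 2000)))
  f2 <- fit_mm(mm_spec(tt, s$A, s$H, priors = list(V = 2),
                       chain = quick_chain(6, niter = 6000, burnin = 2000)))
  m1 <- median(f1$sigma2_a); m2 <- median(f2$sigma2_a)
  expect_lt(abs(m1 - m2) / max(m1, m2), 0.25)
})

test_that("sigma2_a shrinks toward zero when simulated without ancestry signal", {
  hits <- sapply(1:6, function(i) {
    s <- simulate_study(sim_config(n_breeds = 60, n_per_breed = 200,
                                   sigma2_a = 0, seed = 300 + i))
    tt <- aggregate_scores(s$individuals, s$groups)
    f <- fit_mm(mm_spec(tt, s$A, s$H, chain = quick_chain(i)))
    median(f$sigma2_a) < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("non-PSD inputs and missing breeds are rejected up front", {
  d <- make_id_traits(2, seed = 2)
  bad <- d$I; bad[1, 2] <- bad[2, 1] <- 2
  expect_error(mm_spec(d$traits, bad, d$I, chain = quick_chain(1)),
               "positive semi-definite")
  small <- d$I[1:10, 1:10]
  expect_error(mm_spec(d$traits, small, d$I, chain = quick_chain(1)),
               "lacks breeds")
  expect_error(mm_spec(d$traits, d$I, d$I), "seed")
})
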