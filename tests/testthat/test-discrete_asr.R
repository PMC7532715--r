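test_that("ER transition kernel has its closed form and limits", {
  expect_equal(er_transition(0, 2, 5), diag(5))
  P <- er_transition(1, 1e6, 2)
  expect_equal(P, matrix(0.5, 2, 2), tolerance = 1e-12)
  ## k alpha t = log 2 gives P_ii = 0.75 for k = 2
  P2 <- er_transition(1, log(2) / 2, 2)
  expect_equal(P2[1, 1], 0.75)
  expect_error(er_transition(1, -1, 2), "t must be")

  ## generic matrix-exponential oracle, k = 7
  skip_if_not_installed("Matrix")
  a <- 0.37; t <- 1.3; k <- 7
  Q <- matrix(a, k, k); diag(Q) <- -(k - 1) * a
  Pexp <- as.matrix(Matrix::expm(Q * t))
  expect_equal(er_transition(a, t, k), unname(Pexp), tolerance = 1e-10)
  expect_equal(rowSums(er_transition(a, t, k)), rep(1, k))
})

test_that("pruning likelihood matches exhaustive enumeration", {
  ## two identical tips at rate 0: only the root prior contributes
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  st2 <- c(A = "1", B = "1")
  expect_equal(mk_loglik(t2, st2, er_model(3, 0)), log(1 / 3))

  ## the spec fixture, against the 4-term enumeration
  tr <- tree3()
  st <- c(A = "1", B = "1", C = "2")
  expect_equal(mk_loglik(tr, st, er_model(2, 0.5)),
               log(enum_mk_lik(tr, st, 2, 0.5)), tolerance = 1e-12)

  ## random alpha grid over several shapes and state counts
  set.seed(14)
  for (tf in list(tree3, tree4_bal, tree4_cat, tree4_poly)) {
    tr <- tf()
    for (k in c(2, 3)) {
      st <- setNames(as.character(sample.int(k, length(tr$tip.label), TRUE)),
                     tr$tip.label)
      for (a in runif(3, 0.05, 2.5)) {
        expect_equal(mk_loglik(tr, st, er_model(k, a)),
                     log(enum_mk_lik(tr, st, k, a)), tolerance = 1e-9)
      }
    }
  }
})

test_that("ER likelihood is invariant to state relabelling", {
  tr <- tree4_cat()
  st <- c(A = "1", B = "2", C = "1", D = "3")
  perm <- c("1" = "3", "2" = "1", "3" = "2")
  st_p <- setNames(perm[st], names(st))
  m <- er_model(3, 0.7)
  expect_equal(mk_loglik(tr, st, m), mk_loglik(tr, st_p, m))
})

test_that("SYM and ARD generators agree with ER when rates are equal", {
  tr <- tree4_bal()
  st <- c(A = "1", B = "2", C = "2", D = "1")
  ll_er <- mk_loglik(tr, st, er_model(3, 0.4))
  ll_sym <- mk_loglik(tr, st, mk_model(3, rep(0.4, 3), "SYM"))
  ll_ard <- mk_loglik(tr, st, mk_model(3, rep(0.4, 6), "ARD"))
  expect_equal(ll_sym, ll_er, tolerance = 1e-9)
  expect_equal(ll_ard, ll_er, tolerance = 1e-9)
})

test_that("ML rate estimation behaves at boundaries and recovers truth", {
  tr <- simulate_tree(40, seed = 31)
  ## invariant data: monotone likelihood, boundary flag
  st0 <- setNames(rep("1", 40), tr$tip.label)
  f0 <- fit_er(tr, st0, k = 3, states = as.character(1:3))
  expect_true(f0$boundary)
  expect_lte(f0$alpha, 1e-7)

  ## profile check: the optimum dominates halved and doubled rates
  st <- simulate_discrete(tr, 1.2, 3, seed = 77)
  f <- fit_er(tr, st, k = 3)
  for (a in c(0.5, 2) * f$alpha) {
    expect_gte(f$loglik, mk_loglik(tr, st, er_model(3, a, f$model$states)) - 1e-6)
  }

  ## recovery: median alpha-hat near truth over replicates
  set.seed(55)
  tr200 <- simulate_tree(200)
  ahat <- replicate(30, {
    st <- simulate_discrete(tr200, 1.0, 4)
    fit_er(tr200, st, k = 4)$alpha
  })
  expect_gte(median(ahat), 0.7)
  expect_lte(median(ahat), 1.4)
})

test_that("marginal scaled likelihoods match brute-force Bayes", {
  tr <- tree3()
  st <- c(A = "1", B = "1", C = "2")
  m <- er_model(2, 0.5)
  post <- marginal_asr(tr, st, m)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  for (node in 4:5) {
    expect_equal(unname(post[as.character(node), ]),
                 enum_marginal(tr, st, 2, 0.5, node), tolerance = 1e-9)
  }

  ## near-zero rate with uniform tips: root pinned on the observed state
  stA <- c(A = "1", B = "1", C = "1")
  postA <- marginal_asr(tr, stA, er_model(3, 1e-9))
  expect_equal(unname(postA["4", "1"]), 1, tolerance = 1e-6)

  ## tips reported as indicators when requested
  post_t <- marginal_asr(tr, st, m, include_tips = TRUE)
  expect_equal(unname(post_t["1", ]), c(1, 0), ignore_attr = TRUE)

  ## time-rate rescaling invariance
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 3.7
  post2 <- marginal_asr(tr2, st, er_model(2, 0.5 / 3.7))
  expect_equal(post2, post, tolerance = 1e-10)
})

test_that("marginal reconstruction agrees with ape::ace on a larger tree", {
  set.seed(8)
  tr <- simulate_tree(30)
  st <- simulate_discrete(tr, 0.6, 3)
  f <- fit_er(tr, st, k = 3)
  a <- ape::ace(factor(st[tr$tip.label]), tr, type = "discrete", model = "ER")
  expect_equal(f$alpha, unname(a$rates), tolerance = 1e-3)
  post <- marginal_asr(tr, st, f$model)
  expect_equal(unname(post), unname(a$lik.anc), tolerance = 1e-3)
})
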