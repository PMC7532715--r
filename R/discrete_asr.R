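## Mk-model likelihoods by the pruning algorithm, maximum-likelihood rate
## estimation, and marginal ancestral scaled likelihoods (inside-outside).
## The equal-rates (ER) model has a closed-form transition kernel; SYM and
## ARD use the spectral decomposition of their generator.

#' Equal-rates Markov transition matrix
#'
#' Closed form for the k-state ER model:
#' \eqn{P_{ii}(t) = 1/k + (k-1)/k\,e^{-k\alpha t}},
#' \eqn{P_{ij}(t) = 1/k - 1/k\,e^{-k\alpha t}}.  Rows sum to 1.
#'
#' @param alpha Transition rate per unit branch length, `>= 0`.
#' @param t Branch length, `>= 0`.
#' @param k Number of states, `>= 2`.
#' @return `k` x `k` stochastic matrix.
#' @export
er_transition <- function(alpha, t, k) {
  if (t < 0) bp_stop_validation("branch length t must be >= 0")
  if (alpha < 0) bp_stop_validation("alpha must be >= 0")
  if (k < 2) bp_stop_validation("k must be >= 2")
  ekt <- exp(-k * alpha * t)
  P <- matrix((1 - ekt) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * ekt
  P
}

#' Define a k-state Markov model of discrete trait evolution
#'
#' `"ER"` has one rate for every transition; `"SYM"` one rate per unordered
#' state pair; `"ARD"` one rate per ordered pair.  Rates fill the generator
#' off-diagonals column-wise (upper triangle for SYM, row-major off-diagonal
#' order for ARD).
#'
#' @param k Number of states.
#' @param rates Numeric vector of non-negative rates (length 1 for ER,
#'   `k(k-1)/2` for SYM, `k(k-1)` for ARD).
#' @param type One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param states Optional state labels.
#' @return An object of class `"mk_model"`.
#' @export
mk_model <- function(k, rates, type = c("ER", "SYM", "ARD"), states = NULL) {
  type <- match.arg(type)
  k <- as.integer(k)
  if (k < 2) bp_stop_validation("k must be >= 2")
  need <- switch(type, ER = 1L, SYM = k * (k - 1L) %/% 2L, ARD = k * (k - 1L))
  if (length(rates) != need)
    bp_stop_validation(sprintf("%s with k=%d needs %d rate(s)", type, k, need))
  if (any(rates < 0)) bp_stop_validation("rates must be >= 0")
  Q <- matrix(0, k, k)
  if (type == "ER") {
    Q[] <- rates
  } else if (type == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  } else {
    Q[row(Q) != col(Q)] <- rates  # column-wise fill of off-diagonals
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(states)) states <- as.character(seq_len(k))
  structure(list(type = type, k = k, rates = rates, Q = Q, states = states),
            class = "mk_model")
}

#' Shortcut for an equal-rates model
#'
#' @param k Number of states.
#' @param alpha Common transition rate.
#' @param states Optional state labels.
#' @return An `"mk_model"` of type `"ER"`.
#' @export
er_model <- function(k, alpha, states = NULL) mk_model(k, alpha, "ER", states)

## per-branch transition probabilities; closed form for ER, eigen otherwise
transition_matrix <- function(model, t) {
  if (t < 0) bp_stop_validation("branch length t must be >= 0")
  if (model$type == "ER") return(er_transition(model$rates, t, model$k))
  eg <- eigen(model$Q)
  P <- Re(eg$vectors %*% diag(exp(eg$values * t), model$k) %*% solve(eg$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

## map tip states (character/factor) to integer codes 1..k in tip order
code_tip_states <- function(tree, tip_states, states) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(tip_states))
  if (length(missing_tips))
    bp_stop_validation(sprintf("tips missing a state: %s",
                               paste(missing_tips, collapse = ", ")))
  st <- as.character(tip_states[tips])
  bad <- !(st %in% states)
  if (any(bad))
    bp_stop_validation(sprintf("states not in model state set: %s",
                               paste(unique(st[bad]), collapse = ", ")))
  match(st, states)
}

## pruning pass: per-node conditional likelihoods with per-edge rescaling.
## Returns list(L = node x k partials (rescaled), logscale, down = per-edge
## messages down_e(s_parent), tr = postorder tree).
mk_prune <- function(tree, tip_states, model) {
  validate_phylogeny(tree)
  k <- model$k
  ntip <- length(tree$tip.label)
  if (ntip < 2) bp_stop_validation("tree has a single tip: unusable for reconstruction")
  code <- code_tip_states(tree, tip_states, model$states)
  tr <- ape::reorder.phylo(tree, "postorder")
  nE <- nrow(tr$edge)
  L <- matrix(1, ntip + tr$Nnode, k)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), code)] <- 1
  down <- matrix(0, nE, k)
  logscale <- 0
  P <- vector("list", nE)
  for (e in seq_len(nE)) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P[[e]] <- transition_matrix(model, tr$edge.length[e])
    msg <- as.numeric(P[[e]] %*% L[child, ])
    s <- max(msg)
    if (s <= 0) bp_stop_numeric("zero likelihood during pruning")
    down[e, ] <- msg / s
    logscale <- logscale + log(s)
    L[parent, ] <- L[parent, ] * down[e, ]
  }
  list(L = L, logscale = logscale, down = down, P = P, tr = tr, ntip = ntip)
}

#' Log-likelihood of tip states under an Mk model (pruning algorithm)
#'
#' Post-order dynamic programming with per-edge rescaling (the accumulated
#' log factors guard against underflow on large trees), and a flat root
#' prior `1/k` per state (the ER stationary distribution).
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param tip_states Named vector of states, one per tip label.
#' @param model An `"mk_model"` (e.g. [er_model()]).
#' @return Log-likelihood (a single number).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  pr <- mk_prune(tree, tip_states, model)
  root <- pr$ntip + 1L
  log(sum(pr$L[root, ] / model$k)) + pr$logscale
}

#' Maximum-likelihood fit of the equal-rates model
#'
#' Bounded one-dimensional optimization of the ER rate on
#' `[1e-8, alpha_max]`.  If fewer than two distinct states are observed the
#' likelihood is monotone decreasing in the rate, so the lower bound is
#' returned with `boundary = TRUE` rather than an error.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_states Named vector of tip states.
#' @param k Number of states (defaults to the number of distinct observed
#'   states; pass 7 for the AKC groups even when some are unobserved).
#' @param states Optional state labels (defaults to sorted observed states
#'   padded to `k`).
#' @param alpha_max Upper search bound; default `1000 / depth` where depth
#'   is the maximum root-to-tip path length.
#' @return List of class `"er_fit"` with `model`, `alpha`, `loglik`,
#'   `boundary` and `converged`.
#' @export
fit_er <- function(tree, tip_states, k = NULL, states = NULL, alpha_max = NULL) {
  obs <- sort(unique(as.character(tip_states)))
  if (is.null(states)) {
    states <- obs
    if (!is.null(k) && k > length(states))
      states <- c(states, setdiff(as.character(seq_len(k)), states))[seq_len(k)]
  }
  if (is.null(k)) k <- length(states)
  if (is.null(alpha_max)) {
    depth <- max(ape::node.depth.edgelength(tree))
    alpha_max <- 1000 / max(depth, .Machine$double.eps)
  }
  lower <- 1e-8
  if (length(obs) < 2) {
    model <- er_model(k, lower, states)
    return(structure(list(model = model, alpha = lower,
                          loglik = mk_loglik(tree, tip_states, model),
                          boundary = TRUE, converged = TRUE),
                     class = "er_fit"))
  }
  nll <- function(a) -mk_loglik(tree, tip_states, er_model(k, a, states))
  opt <- stats::optimize(nll, interval = c(lower, alpha_max), tol = 1e-8)
  boundary <- opt$minimum <= lower * 1.01 || opt$minimum >= alpha_max * 0.99
  structure(list(model = er_model(k, opt$minimum, states),
                 alpha = opt$minimum, loglik = -opt$objective,
                 boundary = boundary, converged = is.finite(opt$objective)),
            class = "er_fit")
}

#' @export
print.er_fit <- function(x, ...) {
  cat(sprintf("ER Mk fit: k = %d, alpha = %.6g, loglik = %.4f%s\n",
              x$model$k, x$alpha, x$loglik,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Marginal ancestral scaled likelihoods at every internal node
#'
#' For each internal node, the marginal posterior probability of each state
#' given all tip states under a flat root prior, computed by an
#' inside-outside (rerooting-equivalent) scheme: post-order "down" messages
#' from the pruning pass are combined with pre-order "up" messages carrying
#' everything outside each subtree.  Each node's vector sums to 1.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_states Named vector of tip states.
#' @param model An `"mk_model"` (typically from [fit_er()]).
#' @param include_tips If `TRUE`, also return rows for tips (indicator
#'   vectors on the observed states).
#' @return Matrix of scaled likelihoods, rows named by ape node number
#'   (internal nodes `ntip+1 ...`), columns by state.
#' @export
marginal_asr <- function(tree, tip_states, model, include_tips = FALSE) {
  pr <- mk_prune(tree, tip_states, model)
  tr <- pr$tr
  k <- model$k
  ntip <- pr$ntip
  nnode <- tr$Nnode
  nE <- nrow(tr$edge)
  root <- ntip + 1L
  U <- matrix(0, ntip + nnode, k)
  U[root, ] <- 1 / k
  edges_of <- split(seq_len(nE), tr$edge[, 1])
  ## reverse postorder = parents before children
  for (e in rev(seq_len(nE))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    sib <- setdiff(edges_of[[as.character(parent)]], e)
    out_msg <- U[parent, ]
    for (e2 in sib) out_msg <- out_msg * pr$down[e2, ]
    u <- as.numeric(out_msg %*% pr$P[[e]])  # sum_s out(s) P(s -> t)
    s <- sum(u)
    if (s <= 0) bp_stop_numeric("zero outside message in marginal reconstruction")
    U[child, ] <- u / s
  }
  post <- U * pr$L
  post <- post / rowSums(post)
  rownames(post) <- as.character(seq_len(ntip + nnode))
  colnames(post) <- model$states
  idx <- if (include_tips) seq_len(ntip + nnode) else (ntip + 1L):(ntip + nnode)
  post[idx, , drop = FALSE]
}
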