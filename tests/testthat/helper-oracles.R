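## Independent oracles and small fixtures shared across tests.

## fixed small trees
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree4_bal <- function() ape::read.tree(text = "((A:0.6,B:0.4):0.7,(C:0.9,D:1.1):0.3);")
tree4_cat <- function() ape::read.tree(text = "(((A:0.5,B:0.8):0.4,C:1.2):0.6,D:2.1);")
tree4_poly <- function() ape::read.tree(text = "((A:0.7,B:0.9,C:0.5):0.8,D:1.6);")

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05  # keep away from zero
  tr
}

## Exhaustive-enumeration likelihood for an Mk model: sum over every
## assignment of states to internal nodes of the product of transition
## probabilities along all edges, times a flat root prior.
enum_mk_lik <- function(tree, tip_states, k, alpha) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  code <- match(as.character(tip_states[tree$tip.label]), as.character(seq_len(k)))
  total <- 0
  grid <- do.call(expand.grid, rep(list(seq_len(k)), nnode))
  for (r in seq_len(nrow(grid))) {
    state <- c(code, as.integer(grid[r, ]))
    p <- 1 / k  # flat root prior
    for (e in seq_len(nrow(tree$edge))) {
      P <- breedplay::er_transition(alpha, tree$edge.length[e], k)
      p <- p * P[state[tree$edge[e, 1]], state[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  total
}

## Brute-force marginal posterior of an internal node's state (Bayes over
## enumerated histories).
enum_marginal <- function(tree, tip_states, k, alpha, node) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  code <- match(as.character(tip_states[tree$tip.label]), as.character(seq_len(k)))
  num <- numeric(k)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), nnode))
  for (r in seq_len(nrow(grid))) {
    state <- c(code, as.integer(grid[r, ]))
    p <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      P <- breedplay::er_transition(alpha, tree$edge.length[e], k)
      p <- p * P[state[tree$edge[e, 1]], state[tree$edge[e, 2]]]
    }
    num[state[node]] <- num[state[node]] + p
  }
  num / sum(num)
}

## Dense conditional-MVN oracle for continuous ancestral states: joint
## tips+nodes covariance with a large-variance normal prior on the root
## mean (flat-prior limit), conditioned on the tips by plain solve().
oracle_anc <- function(tree, x, fit, ridge = 1e4) {
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(depth[M], N, N) * fit$lambda
  diag(S) <- c(depth[seq_len(ntip)], fit$lambda * depth[(ntip + 1):N])
  S <- fit$sigma2 * S + ridge  # common root-mean uncertainty on every entry
  iy <- seq_len(ntip); iz <- (ntip + 1):N
  W <- S[iz, iy] %*% solve(S[iy, iy])
  est <- drop(W %*% x[tree$tip.label])
  v <- diag(S[iz, iz] - W %*% S[iy, iz])
  list(estimate = est, var = v)
}
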