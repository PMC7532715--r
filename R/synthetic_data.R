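## Synthetic-study generator: breed tree, functional-group labels evolving
## under an equal-rates Markov process, latent breed play values with dual
## (ancestry + gene flow) covariance structure, and individual ordinal scores
## emulating a five-level standardized play test.

#' Configuration of a synthetic breed study
#'
#' Defaults mirror the magnitudes of the real analysis: 132 AKC-categorized
#' breeds, group means near the fitted group coefficients, and variance
#' components \eqn{\sigma^2_a = 0.354} (common ancestry),
#' \eqn{\sigma^2_b = 0.133} (gene flow) and \eqn{\sigma^2_e = 0.012}
#' (residual), with full phylogenetic signal (`lambda_true = 1`).  The
#' default per-breed sample size (677) matches the average of 89,352 scored
#' dogs over 132 breeds.
#'
#' @param n_breeds Number of breeds (tree tips), at least 4.
#' @param er_rate Equal-rates transition rate of the group character, in
#'   transitions per unit branch length.
#' @param group_means Named numeric vector of true group means (one per AKC
#'   group label).
#' @param sigma2_a Common-ancestry variance component (trait units squared).
#' @param sigma2_b Gene-flow variance component.
#' @param sigma2_e Residual variance component.
#' @param lambda_true Pagel's lambda used to build the ancestry covariance.
#' @param n_per_breed Individuals scored per breed (scalar or one value per
#'   breed).
#' @param ordinal_cutpoints Four strictly increasing cutpoints mapping the
#'   latent score plus standard-normal noise to the scores 1..5.
#' @param n_blocks Number of admixture blocks in the haplotype-sharing
#'   matrix.
#' @param admix_strength Strength of block similarity in `[0, 1]`.
#' @param seed Integer seed governing every random draw of the study.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_breeds = 132,
                       er_rate = 0.1,
                       group_means = c(Herding = 3.341, Hound = 3.142,
                                       `Non-sporting` = 2.709, Sporting = 3.553,
                                       Terrier = 3.152, Toy = 2.491,
                                       Working = 3.101),
                       sigma2_a = 0.354,
                       sigma2_b = 0.133,
                       sigma2_e = 0.012,
                       lambda_true = 1,
                       n_per_breed = 677,
                       ordinal_cutpoints = c(1.5, 2.5, 3.5, 4.5),
                       n_blocks = 8,
                       admix_strength = 0.4,
                       seed = 1L) {
  cfg <- list(n_breeds = as.integer(n_breeds), er_rate = er_rate,
              group_means = group_means, sigma2_a = sigma2_a,
              sigma2_b = sigma2_b, sigma2_e = sigma2_e,
              lambda_true = lambda_true, n_per_breed = n_per_breed,
              ordinal_cutpoints = ordinal_cutpoints, n_blocks = n_blocks,
              admix_strength = admix_strength, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_breeds < 4) bp_stop_validation("n_breeds must be >= 4")
  if (cfg$er_rate < 0) bp_stop_validation("er_rate must be >= 0")
  if (!setequal(names(cfg$group_means), akc_groups()))
    bp_stop_validation("group_means must be named by the 7 AKC group labels")
  if (any(c(cfg$sigma2_a, cfg$sigma2_b, cfg$sigma2_e) < 0))
    bp_stop_validation("variance components must be >= 0")
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1)
    bp_stop_validation("lambda_true must lie in [0, 1]")
  if (any(cfg$n_per_breed < 1)) bp_stop_validation("n_per_breed must be >= 1")
  if (length(cfg$ordinal_cutpoints) != 4 || any(diff(cfg$ordinal_cutpoints) <= 0))
    bp_stop_validation("ordinal_cutpoints must be 4 strictly increasing values")
  if (cfg$admix_strength < 0 || cfg$admix_strength > 1)
    bp_stop_validation("admix_strength must lie in [0, 1]")
  invisible(cfg)
}

#' Simulate a pure-birth breed tree
#'
#' Yule (pure-birth) rooted tree with `n_breeds` tips, branch lengths
#' rescaled so that the root-to-tip depth is exactly 1.  Tip labels are
#' `B001`, `B002`, ...
#'
#' @param n_breeds Number of tips, at least 4.
#' @param seed Optional integer seed (set only if supplied; callers that
#'   manage the RNG themselves pass `NULL`).
#' @return A `"phylo"` object, ultrametric with depth 1.
#' @export
simulate_tree <- function(n_breeds, seed = NULL) {
  if (n_breeds < 4) bp_stop_validation("n_breeds must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_breeds, birth = 1, death = 0)
  tree$tip.label <- sprintf("B%03d", seq_len(n_breeds))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate a discrete character under the equal-rates Markov model
#'
#' The root state is drawn uniformly over the `n_states` states; states then
#' evolve tip-ward along each branch of length `t` with the ER kernel
#' \eqn{P_{ii}(t) = 1/k + (k-1)/k \, e^{-k\alpha t}},
#' \eqn{P_{ij}(t) = 1/k - 1/k \, e^{-k\alpha t}} (simulated exactly: with
#' probability \eqn{e^{-k\alpha t}} the state is inherited, otherwise it is
#' redrawn uniformly).
#'
#' @param tree A `"phylo"` tree.
#' @param er_rate Transition rate \eqn{\alpha \ge 0}.
#' @param n_states Number of states `k >= 2`.
#' @param states Optional character vector of state labels (defaults to
#'   `"1"`..`"k"`).
#' @param seed Optional seed.
#' @return Named character vector of tip states; the full node-state vector
#'   and the root state are attached as attributes `"node_states"` and
#'   `"root_state"`.
#' @export
simulate_discrete <- function(tree, er_rate, n_states, states = NULL, seed = NULL) {
  if (n_states < 2) bp_stop_validation("n_states must be >= 2")
  if (er_rate < 0) bp_stop_validation("er_rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(n_states)
  if (is.null(states)) states <- as.character(seq_len(k))
  stopifnot(length(states) == k)
  ntip <- length(tree$tip.label)
  state <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  state[root] <- sample.int(k, 1)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  keep <- exp(-k * er_rate * tr$edge.length)
  u <- runif(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    state[child] <- if (u[e] < keep[e]) state[parent] else sample.int(k, 1)
  }
  out <- setNames(states[state[seq_len(ntip)]], tree$tip.label)
  attr(out, "node_states") <- states[state]
  attr(out, "root_state") <- states[state[root]]
  out
}

## draw one MVN(0, Sigma) vector tolerating PSD (singular) Sigma
rmvn_psd <- function(Sigma) {
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  drop(eg$vectors %*% (sqrt(ev) * rnorm(length(ev))))
}

#' Simulate latent breed trait values with dual covariance structure
#'
#' Latent value of breed i is
#' \eqn{\beta_{g(i)} + a_i + h_i + e_i} with
#' \eqn{a \sim MVN(0, \sigma^2_a A)}, \eqn{h \sim MVN(0, \sigma^2_b H)} and
#' iid residual \eqn{e_i \sim N(0, \sigma^2_e)}.  `A` is the tree covariance
#' at `lambda_true`, rescaled to unit diagonal (correlation form) so that
#' \eqn{\sigma^2_a} is on the trait scale.
#'
#' @param tree Breed tree.
#' @param groups Named breed-to-group map (values must be AKC labels).
#' @param H Haplotype-sharing relatedness matrix (labels matching the tree).
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return Named numeric vector of latent values; components `a`, `h`, `e`
#'   and the `A` matrix used are attached as attributes.
#' @export
simulate_latent <- function(tree, groups, H, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  H <- validate_rel_matrix(H)
  H <- harmonize_matrix(H, tips, "H matrix")
  if (!all(tips %in% names(groups)))
    bp_stop_validation("groups must cover every tree tip")
  g <- groups[tips]
  if (!all(g %in% names(config$group_means)))
    bp_stop_validation("group labels must match names(group_means)")
  A <- stats::cov2cor(tree_covariance(tree, config$lambda_true))
  a <- sqrt(config$sigma2_a) * rmvn_psd(A)
  h <- sqrt(config$sigma2_b) * rmvn_psd(H)
  e <- rnorm(length(tips), 0, sqrt(config$sigma2_e))
  latent <- setNames(config$group_means[g] + a + h + e, tips)
  attr(latent, "a") <- setNames(a, tips)
  attr(latent, "h") <- setNames(h, tips)
  attr(latent, "e") <- setNames(e, tips)
  attr(latent, "A") <- A
  latent
}

#' Simulate individual ordinal play scores
#'
#' Each individual of breed i receives the score
#' `1 + #[cutpoints below latent_i + eps]` with `eps ~ N(0, 1)`, emulating
#' the five-level ordinal scoring of the play test so that breed means and
#' within-breed variances are nondegenerate.  The ordinal noise has unit
#' variance by convention; the cutpoints carry the scale.
#'
#' @param latent Named numeric vector of breed latent values.
#' @param n_per_breed Scalar or per-breed vector of individual counts.
#' @param cutpoints Four strictly increasing cutpoints.
#' @param seed Optional seed.
#' @return Data frame with columns `breed` and `score` (integer in 1..5).
#' @export
simulate_individuals <- function(latent, n_per_breed,
                                 cutpoints = c(1.5, 2.5, 3.5, 4.5),
                                 seed = NULL) {
  if (length(cutpoints) != 4 || any(diff(cutpoints) <= 0))
    bp_stop_validation("cutpoints must be 4 strictly increasing values")
  if (!is.null(seed)) set.seed(seed)
  nb <- length(latent)
  n_i <- if (length(n_per_breed) == 1) rep(n_per_breed, nb) else n_per_breed
  if (length(n_i) != nb) bp_stop_validation("n_per_breed must be scalar or one per breed")
  if (any(n_i < 1)) bp_stop_validation("n_per_breed must be >= 1")
  breed <- rep(names(latent), n_i)
  x <- rep(unname(latent), n_i) + rnorm(length(breed))
  score <- findInterval(x, cutpoints) + 1L
  data.frame(breed = breed, score = as.integer(score), stringsAsFactors = FALSE)
}

#' Construct a block-structured haplotype-sharing matrix
#'
#' Stand-in for gene flow: a PSD matrix with unit diagonal in which randomly
#' chosen sets of breeds ("admixture blocks") share elevated similarity that
#' is deliberately not aligned with tree structure.  With loading matrix `Z`
#' (breeds x blocks, 0/1 membership) the matrix is the correlation form of
#' `I + s Z Z'` where `s` is `admix_strength`.
#'
#' @param tree Breed tree (only tip labels are used) or a character vector
#'   of breed labels.
#' @param n_blocks Number of blocks, at least 1.
#' @param admix_strength Block similarity strength in `[0, 1]`; 0 gives the
#'   identity matrix.
#' @param seed Optional seed.
#' @return Labelled PSD matrix with unit diagonal.
#' @export
make_haplotype_matrix <- function(tree, n_blocks, admix_strength, seed = NULL) {
  labels <- if (inherits(tree, "phylo")) tree$tip.label else as.character(tree)
  if (n_blocks < 1) bp_stop_validation("n_blocks must be >= 1")
  if (admix_strength < 0 || admix_strength > 1)
    bp_stop_validation("admix_strength must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  Z <- matrix(0, n, n_blocks)
  size <- max(2L, ceiling(n / n_blocks))
  for (b in seq_len(n_blocks)) Z[sample.int(n, min(size, n)), b] <- 1
  M <- diag(n) + admix_strength * tcrossprod(Z)
  H <- stats::cov2cor(M)
  dimnames(H) <- list(labels, labels)
  H
}

#' Generate a complete synthetic breed study
#'
#' Runs the whole generator under a single seed: tree, group labels under
#' the ER process, haplotype-sharing matrix, latent breed values and
#' individual ordinal scores.  Identical configs give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"synthetic_study"` with elements `tree`, `A`
#'   (unit-diagonal ancestry matrix), `H`, `groups`, `individuals` (data
#'   frame of breed/score rows) and `truth` (config echo plus realized
#'   latent values, components and root group).
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  tree <- simulate_tree(config$n_breeds)
  groups <- simulate_discrete(tree, config$er_rate, 7L, states = akc_groups())
  H <- make_haplotype_matrix(tree, config$n_blocks, config$admix_strength)
  latent <- simulate_latent(tree, groups, H, config)
  individuals <- simulate_individuals(latent, config$n_per_breed,
                                      config$ordinal_cutpoints)
  structure(list(
    tree = tree,
    A = attr(latent, "A"),
    H = H,
    groups = setNames(as.character(groups), names(groups)),
    individuals = individuals,
    truth = list(config = unclass(config),
                 latent = setNames(as.numeric(latent), names(latent)),
                 a = attr(latent, "a"), h = attr(latent, "h"),
                 e = attr(latent, "e"),
                 root_group = attr(groups, "root_state"))
  ), class = "synthetic_study")
}

#' Write a synthetic study bundle to disk
#'
#' Emits `tree.nwk`, `A.csv`, `H.csv`, `individuals.csv`, `groups.csv` and
#' `truth.json` into `dir`.
#'
#' @param study A `"synthetic_study"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write_rel_matrix(study$A, file.path(dir, "A.csv"))
  write_rel_matrix(study$H, file.path(dir, "H.csv"))
  utils::write.csv(study$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(breed = names(study$groups),
                              group = unname(study$groups)),
                   file.path(dir, "groups.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic breed study: %d breeds, %d individuals\n",
              length(x$tree$tip.label), nrow(x$individuals)))
  cat(sprintf("  root group: %s\n", x$truth$root_group))
  cat(sprintf("  sigma2 (ancestry, gene flow, residual): %.3f / %.3f / %.3f\n",
              x$truth$config$sigma2_a, x$truth$config$sigma2_b,
              x$truth$config$sigma2_e))
  invisible(x)
}
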