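## Brownian-motion ML ancestral states with 95% CIs and Pagel's lambda.
## Root state and BM rate are profiled in closed form by GLS given lambda;
## lambda itself is found by bounded search on [0, 1] with explicit
## comparison against both boundaries (the data may put the optimum at 1).

## profile log-likelihood pieces at a fixed lambda-scaled covariance
bm_profile <- function(C, x) {
  n <- length(x)
  ch <- tryCatch(chol(C), error = function(e)
    bp_stop_numeric("covariance matrix is singular; zero-length branches may need jitter"))
  u <- backsolve(ch, x, transpose = TRUE)     # solves t(ch) %*% u = x
  v <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(v * u) / sum(v * v)               # GLS phylogenetic mean
  q <- sum((u - mu * v)^2)                    # (x - mu)' C^-1 (x - mu)
  sigma2 <- q / n                             # ML rate
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + 2 * sum(log(diag(ch))) + n)
  list(mu = mu, sigma2 = sigma2, loglik = ll, chol = ch)
}

scale_lambda <- function(C, lambda) {
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

#' Brownian-motion log-likelihood of tip values
#'
#' Multivariate normal log-density of the tip values with mean
#' `root_state` and covariance `sigma2 * C(lambda)`, where `C` is the
#' shared-path-length matrix of the tree with off-diagonals scaled by
#' Pagel's lambda.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_values Named numeric vector, one value per tip.
#' @param sigma2 BM rate (trait units squared per unit branch length), `> 0`.
#' @param root_state Root (ancestral mean) value.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return Log-likelihood.
#' @export
bm_loglik <- function(tree, tip_values, sigma2, root_state, lambda = 1) {
  if (sigma2 <= 0) bp_stop_validation("sigma2 must be > 0")
  C <- tree_covariance(tree, lambda)
  x <- align_tip_values(tree, tip_values)
  n <- length(x)
  ch <- tryCatch(chol(sigma2 * C), error = function(e)
    bp_stop_numeric("covariance matrix is singular; zero-length branches may need jitter"))
  u <- backsolve(ch, x - root_state, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

align_tip_values <- function(tree, tip_values) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(tip_values))
  if (length(missing_tips))
    bp_stop_validation(sprintf("tip values missing for: %s",
                               paste(missing_tips, collapse = ", ")))
  x <- as.numeric(tip_values[tips])
  if (any(!is.finite(x))) bp_stop_validation("tip values must be finite")
  x
}

#' Joint ML fit of Brownian motion with Pagel's lambda
#'
#' For each candidate lambda the root state and BM rate have closed-form
#' GLS/ML solutions; the profile likelihood is then maximized over lambda
#' on `[0, 1]` by bounded search, compared explicitly against both
#' endpoints so boundary optima (notably lambda = 1) are reported exactly,
#' with a `boundary` flag.
#'
#' @param tree A `"phylo"` tree with at least 4 tips.
#' @param tip_values Named numeric vector of breed trait values.
#' @return List of class `"bm_fit"`: `sigma2`, `root_state`, `lambda`,
#'   `loglik`, `boundary`.
#' @export
fit_lambda <- function(tree, tip_values) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 4)
    bp_stop_validation("fit_lambda needs at least 4 tips")
  x <- align_tip_values(tree, tip_values)
  C1 <- tree_covariance(tree, 1)
  prof_ll <- function(lam) bm_profile(scale_lambda(C1, lam), x)$loglik
  opt <- stats::optimize(function(l) -prof_ll(l), interval = c(0, 1), tol = 1e-8)
  cand <- c(0, opt$minimum, 1)
  ll <- vapply(cand, prof_ll, numeric(1))
  lambda <- cand[which.max(ll)]
  pr <- bm_profile(scale_lambda(C1, lambda), x)
  structure(list(sigma2 = pr$sigma2, root_state = pr$mu, lambda = lambda,
                 loglik = pr$loglik,
                 boundary = lambda %in% c(0, 1)),
            class = "bm_fit")
}

#' Brownian-motion fit at a fixed lambda
#'
#' @param tree A `"phylo"` tree.
#' @param tip_values Named numeric vector.
#' @param lambda Fixed Pagel's lambda (default 1, plain Brownian motion).
#' @return A `"bm_fit"` list.
#' @export
fit_bm <- function(tree, tip_values, lambda = 1) {
  x <- align_tip_values(tree, tip_values)
  pr <- bm_profile(scale_lambda(tree_covariance(tree, 1), lambda), x)
  structure(list(sigma2 = pr$sigma2, root_state = pr$mu, lambda = lambda,
                 loglik = pr$loglik, boundary = lambda %in% c(0, 1)),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("BM fit: sigma2 = %.6g, root = %.4f, lambda = %.4f%s, loglik = %.4f\n",
              x$sigma2, x$root_state, x$lambda,
              if (x$boundary) " (boundary)" else "", x$loglik))
  invisible(x)
}

## joint (tips + internal nodes) covariance on the lambda-transformed tree:
## shared MRCA depth off the diagonal (times lambda), tip depths on the tip
## diagonal, lambda * depth on the internal-node diagonal (internal branches
## are the ones scaled by lambda; pendant depth is preserved).
node_covariance <- function(tree, lambda) {
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(depth[M], nrow(M), ncol(M))
  ntip <- length(tree$tip.label)
  Sl <- S * lambda
  diag(Sl) <- c(depth[seq_len(ntip)],
                lambda * depth[(ntip + 1):length(depth)])
  Sl
}

#' ML ancestral states for a continuous trait, with 95% CIs
#'
#' Each internal node's estimate is the conditional mean of its state given
#' the tip values under the fitted Brownian model (lambda applied to the
#' covariance), with the root mean treated as unknown (flat prior), so the
#' root estimate is the GLS phylogenetic mean
#' \eqn{(1'C^{-1}1)^{-1} 1'C^{-1}x} and every node variance includes the
#' uncertainty in that mean.  Confidence intervals are
#' `estimate +/- 1.96 * sqrt(variance)` using the ML rate.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_values Named numeric vector of tip trait values.
#' @param fit A `"bm_fit"`; defaults to [fit_lambda()] on the data.
#' @return Data frame with one row per node (ape numbering; tips first,
#'   then internal nodes starting at the root `ntip + 1`): `node`, `type`,
#'   `estimate`, `var`, `ci_lo`, `ci_hi`.  Tip rows echo the observed
#'   values with variance 0.
#' @export
anc_states <- function(tree, tip_values, fit = NULL) {
  validate_phylogeny(tree)
  x <- align_tip_values(tree, tip_values)
  if (is.null(fit)) fit <- fit_lambda(tree, tip_values)
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  S <- node_covariance(tree, fit$lambda)
  idx_tip <- seq_len(ntip)
  idx_node <- (ntip + 1L):N
  Cyy <- S[idx_tip, idx_tip]
  Czy <- S[idx_node, idx_tip, drop = FALSE]
  ch <- tryCatch(chol(Cyy), error = function(e)
    bp_stop_numeric("tip covariance is singular; zero-length branches may need jitter"))
  Ci1 <- backsolve(ch, backsolve(ch, rep(1, ntip), transpose = TRUE))
  denom <- sum(Ci1)                      # 1' C^-1 1
  mu <- sum(Ci1 * x) / denom             # GLS phylogenetic mean
  W <- t(backsolve(ch, backsolve(ch, t(Czy), transpose = TRUE)))  # Czy C^-1
  est <- mu + as.numeric(W %*% (x - mu))
  resid_var <- diag(S)[idx_node] - rowSums(W * Czy)
  mean_adj <- (1 - as.numeric(W %*% rep(1, ntip)))^2 / denom
  v <- fit$sigma2 * pmax(resid_var + mean_adj, 0)
  out <- data.frame(
    node = seq_len(N),
    type = rep(c("tip", "internal"), c(ntip, tree$Nnode)),
    estimate = c(x, est),
    var = c(rep(0, ntip), v),
    stringsAsFactors = FALSE)
  out$ci_lo <- out$estimate - 1.96 * sqrt(out$var)
  out$ci_hi <- out$estimate + 1.96 * sqrt(out$var)
  out$label <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  attr(out, "fit") <- fit
  out
}
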