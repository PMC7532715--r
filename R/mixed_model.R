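## Bayesian phylogenetic mixed model: among-breed variance partitioned into
## common-ancestry (A) and gene-flow (H) components, AKC group fixed
## effects, known per-breed measurement-error variances, DIC and posterior
## group contrasts.  The Gibbs sampler itself lives in src/gibbs.cpp.

#' Specify a phylogenetic mixed model
#'
#' Builds and validates the inputs of the animal model
#' \eqn{y_i = \beta_{g(i)} + a_i + h_i + m_i + e_i} with
#' \eqn{a \sim N(0, \sigma^2_a A)}, \eqn{h \sim N(0, \sigma^2_b H)},
#' fixed measurement error \eqn{m_i \sim N(0, mev_i)} and iid residual.
#' There is no global intercept: one coefficient per group
#' (group-means parameterization).  `A` and `H` are harmonized to the
#' trait-table breed order by label and rescaled to unit diagonal (with a
#' warning) if needed; breeds with missing group labels are dropped with a
#' message.
#'
#' @param traits Trait table (from [aggregate_scores()] or
#'   [read_trait_table()]).
#' @param A Genetic-similarity (common ancestry) relatedness matrix.
#' @param H Haplotype-sharing (gene flow) relatedness matrix.
#' @param fixed `"group"` (default) for the seven group means, or
#'   `"intercept"` for the null model with a single mean.
#' @param priors List with elements `nu`, `V` (scaled-inverse-chi-square
#'   variance prior, default `nu = 0.002`, `V = 1`) and `beta_var`
#'   (zero-mean normal prior variance on fixed effects, default `1e10`).
#' @param chain List with `niter`, `burnin`, `thin`, `seed`.  Defaults:
#'   130000 / 30000 / 100 (1000 retained); `seed` is mandatory.
#' @return List of class `"mm_spec"`.
#' @export
mm_spec <- function(traits, A, H, fixed = c("group", "intercept"),
                    priors = list(), chain = list()) {
  fixed <- match.arg(fixed)
  traits <- validate_trait_table(traits)
  drop_idx <- is.na(traits$group)
  if (fixed == "group" && any(drop_idx)) {
    message(sprintf("dropping %d breed(s) without group labels from the mixed model",
                    sum(drop_idx)))
    traits <- traits[!drop_idx, , drop = FALSE]
  }
  if (nrow(traits) < 8) bp_stop_validation("too few breeds for the mixed model")
  A <- validate_rel_matrix(A)
  H <- validate_rel_matrix(H)
  A <- harmonize_matrix(A, traits$breed, "A matrix")
  H <- harmonize_matrix(H, traits$breed, "H matrix")
  A <- normalize_diag(A, "A")
  H <- normalize_diag(H, "H")
  pr <- utils::modifyList(list(nu = 0.002, V = 1, beta_var = 1e10), priors)
  ch <- utils::modifyList(list(niter = 130000L, burnin = 30000L, thin = 100L,
                               seed = NULL), chain)
  if (is.null(ch$seed)) bp_stop_validation("chain$seed is mandatory")
  if ((ch$niter - ch$burnin) / ch$thin < 1)
    bp_stop_validation("chain settings retain no samples")
  structure(list(traits = traits, A = A, H = H, fixed = fixed,
                 priors = pr, chain = ch), class = "mm_spec")
}

normalize_diag <- function(m, what) {
  d <- diag(m)
  if (any(d <= 0)) bp_stop_validation(sprintf("%s has non-positive diagonal", what))
  if (max(abs(d - 1)) > 1e-8) {
    warning(sprintf("%s matrix rescaled to unit diagonal", what))
    m <- stats::cov2cor(m)
  }
  m
}

## robust inverse of a PSD relatedness matrix; tiny ridge if near-singular
psd_inverse <- function(m) {
  eg <- eigen(m, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    m <- m + diag(1e-8 * max(eg$values), nrow(m))
  chol2inv(chol(m))
}

#' Fit the phylogenetic mixed model by Gibbs sampling
#'
#' Conjugate Gibbs updates (normal for the location effects, with the
#' measurement-error variances entering the location update as a known
#' additive diagonal; scaled-inverse-chi-square for the three variance
#' components).  Reproducible through `chain$seed`.
#'
#' @param spec An [mm_spec()].
#' @return List of class `"mm_fit"` with posterior samples (`beta`,
#'   `sigma2_a`, `sigma2_b`, `sigma2_e`, `group_level`, `deviance`),
#'   posterior means of the random effects, DIC, effective sample sizes and
#'   lag-1 autocorrelations.
#' @export
fit_mm <- function(spec) {
  stopifnot(inherits(spec, "mm_spec"))
  tr <- spec$traits
  y <- tr$mean
  groups_present <- sort(unique(tr$group))
  if (spec$fixed == "group") {
    X <- sapply(groups_present, function(g) as.numeric(tr$group == g))
    gidx <- match(tr$group, groups_present)
    colnames(X) <- groups_present
  } else {
    X <- matrix(1, nrow(tr), 1, dimnames = list(NULL, "(Intercept)"))
    gidx <- rep(1L, nrow(tr))
  }
  Ainv <- psd_inverse(spec$A)
  Hinv <- psd_inverse(spec$H)
  set.seed(spec$chain$seed)
  raw <- .gibbs_mm(y, X, Ainv, Hinv, tr$mev, gidx,
                   spec$priors$nu, spec$priors$V, spec$priors$beta_var,
                   as.integer(spec$chain$niter), as.integer(spec$chain$burnin),
                   as.integer(spec$chain$thin))
  colnames(raw$beta) <- colnames(X)
  colnames(raw$group_level) <- colnames(X)
  for (nm in c("sigma2_a", "sigma2_b", "sigma2_e", "deviance"))
    raw[[nm]] <- as.numeric(raw[[nm]])
  samples <- cbind(raw$beta, sigma2_a = raw$sigma2_a, sigma2_b = raw$sigma2_b,
                   sigma2_e = raw$sigma2_e)
  fit <- structure(list(
    beta = raw$beta, sigma2_a = raw$sigma2_a, sigma2_b = raw$sigma2_b,
    sigma2_e = raw$sigma2_e, group_level = raw$group_level,
    deviance = raw$deviance, beta_mean = drop(raw$beta_mean),
    a_mean = drop(raw$a_mean), h_mean = drop(raw$h_mean),
    retained = raw$retained, groups = colnames(X), spec = spec,
    ess = apply(samples, 2, ess_univariate),
    lag1 = apply(samples, 2, function(z)
      if (stats::sd(z) == 0) 0 else stats::acf(z, lag.max = 1, plot = FALSE)$acf[2])
  ), class = "mm_fit")
  fit$dic <- mm_dic(fit)
  fit
}

## effective sample size by the initial positive sequence estimator
ess_univariate <- function(z) {
  S <- length(z)
  if (stats::sd(z) == 0) return(S)
  rho <- stats::acf(z, lag.max = min(S - 1, 200), plot = FALSE)$acf[-1]
  tau <- 1
  for (l in seq_along(rho)) {
    if (rho[l] <= 0) break
    tau <- tau + 2 * rho[l]
  }
  S / tau
}

#' Deviance information criterion of a mixed-model fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, using the conditional
#' Gaussian deviance given the location effects (animal-model convention)
#' and posterior means as the plug-in.
#'
#' @param fit An `"mm_fit"`.
#' @return The DIC (a single number); the effective number of parameters is
#'   attached as `attr(, "pD")`.
#' @export
mm_dic <- function(fit) {
  if (fit$retained < 100)
    bp_stop_validation("DIC requires at least 100 retained samples")
  dbar <- mean(fit$deviance)
  tr <- fit$spec$traits
  X <- if (fit$spec$fixed == "group")
    sapply(fit$groups, function(g) as.numeric(tr$group == g))
  else matrix(1, nrow(tr), 1)
  mu <- drop(X %*% fit$beta_mean) + fit$a_mean + fit$h_mean
  vv <- mean(fit$sigma2_e) + tr$mev
  dhat <- sum(log(2 * pi * vv) + (tr$mean - mu)^2 / vv)
  pd <- dbar - dhat
  structure(dbar + pd, pD = pd)
}

#' All pairwise posterior group contrasts
#'
#' For every unordered pair of groups, the posterior of the difference
#' \eqn{\Delta = \beta_g - \beta_{g'}} and
#' `pMCMC = 2 min(Pr(Delta > 0), Pr(Delta < 0))`, floored at `2 / draws`.
#' No multiple-testing correction by default (set `bonferroni = TRUE` to
#' multiply by the number of pairs, capped at 1).
#'
#' @param fit An `"mm_fit"` with group fixed effects.
#' @param bonferroni Apply a Bonferroni correction across pairs?
#' @return Data frame with columns `group1`, `group2`, `delta_median`,
#'   `pMCMC`, `significant` (pMCMC < 0.05).
#' @export
group_contrasts <- function(fit, bonferroni = FALSE) {
  if (length(fit$groups) < 2)
    bp_stop_validation("contrasts need at least two groups")
  pairs <- utils::combn(fit$groups, 2)
  S <- nrow(fit$beta)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    delta_median = NA_real_, pMCMC = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    d <- fit$beta[, pairs[1, i]] - fit$beta[, pairs[2, i]]
    ## ties (exact zeros) count toward both tails so equal chains give 1
    p <- 2 * min(mean(d >= 0), mean(d <= 0))
    out$delta_median[i] <- stats::median(d)
    out$pMCMC[i] <- min(max(p, 2 / S), 1)
  }
  if (bonferroni) out$pMCMC <- pmin(out$pMCMC * ncol(pairs), 1)
  out$significant <- out$pMCMC < 0.05
  out
}

#' Five-number posterior summaries per group
#'
#' Range, lower hinge (first quartile), median and upper hinge of each
#' group's posterior, suitable for violin/box display.  `type = "beta"`
#' summarizes the group coefficients; `type = "group_level"` adds the
#' group-averaged posterior random effects to each coefficient (a
#' breed-composition-aware group level).
#'
#' @param fit An `"mm_fit"`.
#' @param type `"beta"` or `"group_level"`.
#' @return Data frame with columns `group`, `min`, `lower`, `median`,
#'   `upper`, `max`, `mean`.
#' @export
group_posterior_summary <- function(fit, type = c("beta", "group_level")) {
  type <- match.arg(type)
  m <- if (type == "beta") fit$beta else fit$group_level
  out <- data.frame(
    group = colnames(m),
    min = apply(m, 2, min),
    lower = apply(m, 2, stats::quantile, 0.25),
    median = apply(m, 2, stats::median),
    upper = apply(m, 2, stats::quantile, 0.75),
    max = apply(m, 2, max),
    mean = colMeans(m),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Posterior medians and 95% credible intervals of all parameters
#'
#' @param fit An `"mm_fit"`.
#' @return Data frame with `parameter`, `median`, `lo95`, `hi95`, `ess`.
#' @export
mm_summary <- function(fit) {
  m <- cbind(fit$beta, sigma2_a = fit$sigma2_a, sigma2_b = fit$sigma2_b,
             sigma2_e = fit$sigma2_e)
  data.frame(parameter = colnames(m),
             median = apply(m, 2, stats::median),
             lo95 = apply(m, 2, stats::quantile, 0.025),
             hi95 = apply(m, 2, stats::quantile, 0.975),
             ess = unname(fit$ess[colnames(m)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic mixed model (%s fixed effects): %d breeds, %d retained draws\n",
              x$spec$fixed, nrow(x$spec$traits), x$retained))
  cat(sprintf("  DIC = %.2f (pD = %.1f)\n", x$dic, attr(x$dic, "pD")))
  print(mm_summary(x), digits = 3)
  invisible(x)
}
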