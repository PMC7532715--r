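## End-to-end orchestration: simulate or ingest -> aggregate -> discrete ASR
## -> continuous ASR + lambda -> mixed model (+ null model, DIC, contrasts)
## -> machine-readable results bundle.

#' Build a pipeline run configuration
#'
#' Exactly one of synthetic mode (`sim` supplied) or real-input mode
#' (`paths` supplied) must be active.  All stage randomness derives from
#' the single top-level `seed`, split per stage.
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL`.
#' @param paths Named list for real-input mode: `tree`, plus either
#'   `individuals` (+ optional `groups`) or `traits`, and `A`, `H`.
#' @param stages Named logical toggles: `asr_discrete`, `asr_continuous`,
#'   `mixed_model` (all default `TRUE`).
#' @param chain Chain settings passed to [mm_spec()]; the pipeline default
#'   (13000 iterations, 3000 burn-in, thin 10, 1000 retained) is the
#'   package's desk-scale default, chosen so a full run completes in
#'   seconds while retaining the conventional 1000 draws.
#' @param seed Top-level integer seed (mandatory when any stochastic stage
#'   is enabled).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       stages = list(), chain = list(), seed = 1L) {
  if (is.null(sim) == is.null(paths))
    bp_stop_validation("exactly one of sim (synthetic mode) or paths (real mode) must be given")
  st <- utils::modifyList(list(asr_discrete = TRUE, asr_continuous = TRUE,
                               mixed_model = TRUE), stages)
  ch <- utils::modifyList(list(niter = 13000L, burnin = 3000L, thin = 10L), chain)
  if (is.null(seed)) bp_stop_validation("seed is mandatory")
  structure(list(sim = sim, paths = paths, stages = st, chain = ch,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with top-level keys `mode` (`synthetic` or
#'   `real`), `sim` or `paths`, optional `stages`, `chain`, `seed`.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    bp_stop_validation("the yaml package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  sim <- NULL
  if (identical(cfg$mode, "synthetic")) {
    sim_args <- cfg$sim %||% list()
    if (!is.null(sim_args$group_means))
      sim_args$group_means <- unlist(sim_args$group_means)
    sim <- do.call(sim_config, sim_args)
  }
  run_config(sim = sim, paths = cfg$paths, stages = cfg$stages %||% list(),
             chain = cfg$chain %||% list(), seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparative analysis pipeline
#'
#' Executes the enabled stages in dependency order, failing fast with a
#' stage-named error, and writes a results bundle to `out_dir`:
#' per-stage CSV outputs, `samples.csv`, `contrasts.csv` and a
#' deterministic `summary.json` (identical config + seed give byte-identical
#' summaries; wall-clock provenance goes to `provenance.json`).
#'
#' @param config A `"run_config"` (or a YAML path).
#' @param out_dir Output directory.
#' @return The results bundle (list of class `"results_bundle"`),
#'   invisibly written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  ## --- stage: inputs -------------------------------------------------
  inp <- with_stage("inputs", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- stage_seeds[1]
      study <- simulate_study(cfg)
      list(tree = study$tree, A = study$A, H = study$H,
           groups = study$groups, individuals = study$individuals,
           traits = NULL, truth = study$truth)
    } else {
      p <- config$paths
      tree <- read_newick(p$tree)
      groups <- NULL
      if (!is.null(p$groups)) {
        gdf <- utils::read.csv(p$groups, stringsAsFactors = FALSE)
        groups <- setNames(gdf$group, gdf$breed)
      }
      individuals <- if (!is.null(p$individuals))
        utils::read.csv(p$individuals, stringsAsFactors = FALSE) else NULL
      traits <- if (!is.null(p$traits)) read_trait_table(p$traits) else NULL
      if (is.null(individuals) && is.null(traits))
        bp_stop_validation("real mode needs either individuals or traits")
      list(tree = tree, A = read_rel_matrix(p$A), H = read_rel_matrix(p$H),
           groups = groups, individuals = individuals, traits = traits,
           truth = NULL)
    }
  })

  ## --- stage: aggregation --------------------------------------------
  traits <- with_stage("aggregation", {
    if (is.null(inp$traits)) aggregate_scores(inp$individuals, inp$groups)
    else inp$traits
  })
  missing_grp <- traits$breed[is.na(traits$group)]
  if (length(missing_grp))
    message(sprintf("pipeline: %d breed(s) lack group labels and enter ASR only",
                    length(missing_grp)))
  check_labels(inp$tree, traits, inp$A, inp$H)

  bundle <- list(config = config, traits = traits, truth = inp$truth,
                 tree = inp$tree)

  ## --- stage: discrete ASR -------------------------------------------
  if (config$stages$asr_discrete) {
    bundle$asr_discrete <- with_stage("asr_discrete", {
      lab <- traits[!is.na(traits$group), ]
      tr_d <- if (nrow(lab) < length(inp$tree$tip.label))
        ape::keep.tip(inp$tree, lab$breed) else inp$tree
      states <- setNames(lab$group, lab$breed)
      fit <- fit_er(tr_d, states, k = 7, states = akc_groups())
      scaled <- marginal_asr(tr_d, states, fit$model)
      list(fit = fit, scaled_lik = scaled,
           root = scaled[1, ],
           nodes = data.frame(node = as.integer(rownames(scaled)), scaled,
                              check.names = FALSE))
    })
  }

  ## --- stage: continuous ASR -----------------------------------------
  if (config$stages$asr_continuous) {
    bundle$asr_continuous <- with_stage("asr_continuous", {
      x <- setNames(traits$mean, traits$breed)
      fit <- fit_lambda(inp$tree, x)
      nodes <- anc_states(inp$tree, x, fit)
      root_row <- nodes[nodes$node == length(inp$tree$tip.label) + 1L, ]
      list(fit = fit, nodes = nodes, root = root_row)
    })
  }

  ## --- stage: mixed model --------------------------------------------
  if (config$stages$mixed_model) {
    bundle$mixed_model <- with_stage("mixed_model", {
      ch <- config$chain
      ch$seed <- stage_seeds[2]
      spec_full <- mm_spec(traits, inp$A, inp$H, fixed = "group", chain = ch)
      fit_full <- fit_mm(spec_full)
      ch$seed <- stage_seeds[3]
      spec_null <- mm_spec(traits, inp$A, inp$H, fixed = "intercept", chain = ch)
      fit_null <- fit_mm(spec_null)
      list(fit = fit_full, null_fit = fit_null,
           dic_full = as.numeric(fit_full$dic),
           dic_null = as.numeric(fit_null$dic),
           delta_dic = as.numeric(fit_null$dic) - as.numeric(fit_full$dic),
           contrasts = group_contrasts(fit_full),
           summary = mm_summary(fit_full),
           group_summary = group_posterior_summary(fit_full, "group_level"))
    })
  }

  class(bundle) <- "results_bundle"
  write_bundle(bundle, out_dir)
  invisible(bundle)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                        class = c(class(e)[1], "error", "condition")))
  })
}

check_labels <- function(tree, traits, A, H) {
  problems <- character(0)
  miss <- function(lbls, what) {
    d <- setdiff(traits$breed, lbls)
    if (length(d)) sprintf("%s lacks: %s", what, paste(d, collapse = ", "))
  }
  problems <- c(problems, miss(tree$tip.label, "tree"),
                miss(rownames(A), "A matrix"), miss(rownames(H), "H matrix"))
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (length(problems))
    bp_stop_validation(paste(c("label mismatch across inputs:", problems),
                             collapse = "\n  "))
  invisible(TRUE)
}

write_bundle <- function(bundle, out_dir) {
  cfg <- bundle$config
  summary <- list(
    seed = cfg$seed,
    n_breeds = nrow(bundle$traits),
    n_breeds_with_group = sum(!is.na(bundle$traits$group))
  )
  write_trait_table(bundle$traits, file.path(out_dir, "traits.csv"))
  if (!is.null(bundle$asr_discrete)) {
    d <- bundle$asr_discrete
    utils::write.csv(cbind(d$nodes, alpha = d$fit$alpha, loglik = d$fit$loglik),
                     file.path(out_dir, "nodes_discrete.csv"), row.names = FALSE)
    summary$asr_discrete <- list(alpha = d$fit$alpha, loglik = d$fit$loglik,
                                 boundary = d$fit$boundary,
                                 root_scaled_lik = as.list(d$root))
  }
  if (!is.null(bundle$asr_continuous)) {
    cc <- bundle$asr_continuous
    utils::write.csv(cc$nodes[, c("node", "type", "estimate", "var", "ci_lo", "ci_hi")],
                     file.path(out_dir, "nodes_continuous.csv"), row.names = FALSE)
    summary$asr_continuous <- list(
      lambda = cc$fit$lambda, sigma2 = cc$fit$sigma2, loglik = cc$fit$loglik,
      root_estimate = cc$root$estimate, root_ci = c(cc$root$ci_lo, cc$root$ci_hi))
  }
  if (!is.null(bundle$mixed_model)) {
    mm <- bundle$mixed_model
    samples <- cbind(mm$fit$beta, sigma2_a = mm$fit$sigma2_a,
                     sigma2_b = mm$fit$sigma2_b, sigma2_e = mm$fit$sigma2_e)
    utils::write.csv(samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
    utils::write.csv(mm$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(mm$group_summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    summary$mixed_model <- list(
      dic_full = mm$dic_full, dic_null = mm$dic_null, delta_dic = mm$delta_dic,
      parameters = mm$summary,
      n_significant_contrasts = sum(mm$contrasts$significant))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("breedplay")),
         timestamp = format(Sys.time(), tz = "UTC"),
         mode = if (is.null(cfg$sim)) "real" else "synthetic",
         seed = cfg$seed),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
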