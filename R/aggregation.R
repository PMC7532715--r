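## Collapse individual ordinal scores to breed-level means and sampling
## variances (the measurement-error variances carried into the mixed model).

#' Aggregate individual scores to a breed-level trait table
#'
#' One row per breed with the arithmetic mean score, the unbiased sample
#' variance (divisor n - 1), the count n, and the measurement-error variance
#' `mev = var / n` of the breed mean.  Breeds observed once get `var = 0`
#' and `mev = 0` with a warning (they are kept, not excluded).
#'
#' @param individuals Data frame with columns `breed` and `score`; scores
#'   must be integers in 1..5.
#' @param groups Optional named breed-to-group map; breeds without an entry
#'   are retained with `NA` group and a warning.
#' @return Trait table data frame (`breed`, `mean`, `var`, `n`, `group`,
#'   `mev`), ordered by breed id.
#' @export
aggregate_scores <- function(individuals, groups = NULL) {
  if (!all(c("breed", "score") %in% names(individuals)))
    bp_stop_validation("individuals must have columns breed, score")
  if (nrow(individuals) == 0) bp_stop_validation("no records in individuals")
  s <- individuals$score
  if (any(!is.finite(s)) || any(s != round(s)) || any(s < 1) || any(s > 5))
    bp_stop_validation("scores must be integers in {1,...,5}")
  by_breed <- split(as.numeric(s), individuals$breed)
  breed <- names(by_breed)
  n <- vapply(by_breed, length, integer(1))
  m <- vapply(by_breed, mean, numeric(1))
  v <- vapply(by_breed, function(x) if (length(x) > 1) stats::var(x) else 0, numeric(1))
  if (any(n == 1))
    warning(sprintf("%d breed(s) with a single individual: variance and mev set to 0",
                    sum(n == 1)))
  out <- data.frame(breed = breed, mean = m, var = v, n = n,
                    group = NA_character_, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    out$group <- unname(groups[out$breed])
    missing_grp <- out$breed[is.na(out$group)]
    if (length(missing_grp))
      warning(sprintf("no group label for %d breed(s): %s", length(missing_grp),
                      paste(utils::head(missing_grp, 10), collapse = ", ")))
  }
  validate_trait_table(out)
}
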