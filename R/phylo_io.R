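## Readers/writers for trees, trait tables and relatedness matrices, and the
## Brownian covariance construction used by the continuous analyses.

#' Read a rooted phylogeny from a Newick file
#'
#' Reads a single Newick tree and validates it for downstream comparative
#' analyses: tip labels must be unique and non-empty, branch lengths must be
#' present and non-negative.  Polytomies are permitted; zero-length branches
#' are kept literally (cladogram-style trees are legitimate input).
#'
#' @param path Path to a file containing one Newick string.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) bp_stop_validation(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_string(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) bp_stop_validation(sprintf("malformed Newick in %s: %s", path, conditionMessage(e)))
  )
  if (is.null(tree)) bp_stop_validation(sprintf("malformed Newick in %s", path))
  validate_phylogeny(tree)
  tree
}

## cheap structural scan so parse failures can name a character offset
check_newick_string <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        bp_stop_validation(sprintf("malformed Newick: unmatched ')' at character offset %d", i))
    }
  }
  if (depth != 0L)
    bp_stop_validation(sprintf(
      "malformed Newick: %d unclosed '(' at character offset %d", depth, length(chars)))
  if (!any(chars == ";"))
    bp_stop_validation("malformed Newick: missing terminating ';'")
  invisible(TRUE)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly, if valid; otherwise a validation error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) bp_stop_validation("not a 'phylo' object")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) bp_stop_validation("empty tip labels are not allowed")
  if (anyDuplicated(tips))
    bp_stop_validation(sprintf(
      "duplicate tip labels: %s", paste(unique(tips[duplicated(tips)]), collapse = ", ")))
  if (is.null(tree$edge.length))
    bp_stop_validation("tree has no branch lengths; they are required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    bp_stop_validation("branch lengths must be finite and >= 0")
  invisible(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a breed-level trait table
#'
#' Expects a comma-separated file (header required, UTF-8, decimal point)
#' with columns `breed`, `mean`, `var`, `n`, `group`.  `mean` is the breed
#' mean play score on the 1--5 scale, `var` the unbiased within-breed
#' variance, `n` the number of scored individuals and `group` the AKC
#' functional group (may be empty; such rows are retained but flagged).
#' The measurement-error variance `mev = var / n` is added on read.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `breed`, `mean`, `var`, `n`, `group`,
#'   `mev`; rows with missing group labels carry `NA` in `group` and the
#'   breed ids are recorded in `attr(, "missing_group")`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) bp_stop_validation(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0) bp_stop_validation(sprintf("no records in %s", path))
  need <- c("breed", "mean", "var", "n", "group")
  if (!all(need %in% names(df)))
    bp_stop_validation(sprintf("trait table must have columns %s", paste(need, collapse = ", ")))
  df <- df[, need]
  df$group[!is.na(df$group) & !nzchar(trimws(df$group))] <- NA_character_
  validate_trait_table(df)
}

#' Validate (and finalize) a trait table
#'
#' @param df Data frame with columns `breed`, `mean`, `var`, `n` and `group`.
#' @return The validated data frame with an added `mev` column.
#' @export
validate_trait_table <- function(df) {
  if (nrow(df) == 0) bp_stop_validation("no records in trait table")
  if (anyDuplicated(df$breed))
    bp_stop_validation(sprintf("duplicate breed ids: %s",
      paste(unique(df$breed[duplicated(df$breed)]), collapse = ", ")))
  if (any(!is.finite(df$mean)) || any(df$mean < 1) || any(df$mean > 5))
    bp_stop_validation("mean score must lie in [1, 5] (the five-level play scale)")
  if (any(!is.finite(df$var)) || any(df$var < 0))
    bp_stop_validation("within-breed variance must be finite and >= 0")
  if (any(df$n < 1) || any(df$n != round(df$n)))
    bp_stop_validation("n must be a positive integer count of individuals")
  bad <- !is.na(df$group) & !(df$group %in% akc_groups())
  if (any(bad))
    bp_stop_validation(sprintf("unknown group labels: %s",
      paste(unique(df$group[bad]), collapse = ", ")))
  df$mev <- df$var / df$n
  attr(df, "missing_group") <- df$breed[is.na(df$group)]
  df
}

#' Write a trait table to CSV
#'
#' @param df Trait table as returned by [aggregate_scores()] or
#'   [read_trait_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(df, path) {
  cols <- c("breed", "mean", "var", "n", "group")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled breed-by-breed relatedness matrix
#'
#' Reads a square CSV whose first column holds row labels and whose header
#' holds column labels.  The matrix must be symmetric (tolerance `1e-8` on
#' the largest absolute asymmetry) and positive semi-definite (smallest
#' eigenvalue at least `-1e-8` times the largest), with row labels equal to
#' column labels in the same order.
#'
#' @param path Path to the CSV file.
#' @return A labelled numeric matrix.
#' @export
read_rel_matrix <- function(path) {
  if (!file.exists(path)) bp_stop_validation(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  validate_rel_matrix(m)
}

#' Validate a relatedness matrix
#'
#' @param m Square labelled numeric matrix.
#' @param tol Symmetry / PSD tolerance (default `1e-8`).
#' @return The matrix, if valid.
#' @export
validate_rel_matrix <- function(m, tol = 1e-8) {
  if (nrow(m) != ncol(m)) bp_stop_validation("relatedness matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    bp_stop_validation("relatedness matrix must carry row and column labels")
  if (!identical(rownames(m), colnames(m)))
    bp_stop_validation("row labels and column labels differ (order matters)")
  if (anyDuplicated(rownames(m))) bp_stop_validation("duplicate matrix labels")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) bp_stop_validation("matrix entries must be finite")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    bp_stop_validation(sprintf("matrix asymmetric: max |m - t(m)| = %.3g > %.1g", asym, tol))
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    bp_stop_validation(sprintf(
      "matrix is not positive semi-definite: smallest eigenvalue %.3g", min(ev)))
  m
}

#' Write a relatedness matrix to labelled CSV
#'
#' @param m Labelled square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rel_matrix <- function(m, path) {
  df <- data.frame(breed = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Brownian covariance matrix of a tree, with Pagel's lambda
#'
#' Entry (i, j) is the root-to-tip path length shared by tips i and j (the
#' depth of their most recent common ancestor); the diagonal holds each
#' tip's root-to-tip depth.  `lambda` multiplies the off-diagonal entries
#' only: `lambda = 1` is the full Brownian structure, `lambda = 0` the
#' star-phylogeny (independence) limit.
#'
#' @param tree A `"phylo"` object with at least two tips.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return Labelled covariance matrix in tip-label order.
#' @export
tree_covariance <- function(tree, lambda = 1) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2)
    bp_stop_validation("tree has a single tip: unusable for covariance construction")
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0 || lambda > 1)
    bp_stop_validation("lambda must be a single value in [0, 1]")
  C <- ape::vcv.phylo(tree)
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  C
}

## reorder a labelled matrix to a given label vector; exact set match required
harmonize_matrix <- function(m, labels, what = "matrix") {
  missing_lab <- setdiff(labels, rownames(m))
  extra_lab <- setdiff(rownames(m), labels)
  if (length(missing_lab))
    bp_stop_validation(sprintf("%s lacks breeds: %s", what,
                               paste(missing_lab, collapse = ", ")))
  if (length(extra_lab))
    m <- m[!(rownames(m) %in% extra_lab), !(colnames(m) %in% extra_lab), drop = FALSE]
  m[labels, labels, drop = FALSE]
}
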