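## Human-readable report rendering from a results bundle: annotated tree,
## group posterior table and basic plots (tree with branch colouring by
## reconstructed trait value; box summaries of group posteriors).

#' Render report files from a results bundle
#'
#' Writes (a) a node-annotated Newick tree whose internal-node labels are
#' the ape node numbers keyed to the per-node tables, (b) the per-group
#' posterior summary table, and (c) a PDF with a tree whose branches are
#' coloured by the reconstructed play score plus box summaries of the
#' group posteriors.  Stages absent from the bundle are noted as skipped
#' in `report.txt`.
#'
#' @param bundle A `"results_bundle"` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
render_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  notes <- character(0)

  tree <- bundle$tree
  ntip <- length(tree$tip.label)
  tree$node.label <- as.character((ntip + 1L):(ntip + tree$Nnode))
  write_newick(tree, file.path(dir, "annotated_tree.nwk"))

  if (!is.null(bundle$mixed_model)) {
    utils::write.csv(bundle$mixed_model$group_summary,
                     file.path(dir, "group_summary.csv"), row.names = FALSE)
  } else notes <- c(notes, "mixed model stage skipped: no group posterior table")

  grDevices::pdf(file.path(dir, "report_plots.pdf"), width = 8, height = 8)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (!is.null(bundle$asr_continuous)) {
    nodes <- bundle$asr_continuous$nodes
    est <- nodes$estimate
    ## colour each edge by the estimate at its child node: red = low play,
    ## blue = high play
    pal <- grDevices::colorRampPalette(c("red", "grey60", "blue"))(100)
    rng <- range(est)
    idx <- pmax(1, pmin(100, 1 + floor(99 * (est[tree$edge[, 2]] - rng[1]) /
                                         max(rng[2] - rng[1], 1e-12))))
    graphics::plot(tree, edge.color = pal[idx], cex = 0.4, no.margin = TRUE)
    graphics::legend("bottomleft", legend = sprintf("%.2f", seq(rng[1], rng[2], length.out = 5)),
                     fill = pal[c(1, 25, 50, 75, 100)], title = "play score", cex = 0.7)
  } else notes <- c(notes, "continuous ASR stage skipped: no coloured tree")
  if (!is.null(bundle$mixed_model)) {
    gl <- bundle$mixed_model$fit$group_level
    graphics::boxplot(as.data.frame(gl), las = 2,
                      ylab = "posterior play score",
                      main = "Group posterior distributions")
  }
  if (is.null(bundle$asr_continuous) && is.null(bundle$mixed_model)) {
    graphics::plot.new(); graphics::title("no plottable stages in bundle")
  }

  writeLines(c("breedplay report", if (length(notes)) notes else "all stages present"),
             file.path(dir, "report.txt"))
  invisible(dir)
}
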