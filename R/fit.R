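#' Discover candidate surface markers from a spectral-count time course
#'
#' The package's central fit. Takes a spectral-count matrix in any state
#' (raw counts are depth-normalized in rationale mode and averaged;
#' normalized counts are averaged) and runs the marker-discovery chain:
#' PCA of the log2(x+1) time course, K-means clustering of standardized
#' trajectories, selection of clusters upregulated after DOX induction and
#' maximal at the F-class end state, and loading-based ranking of the
#' selected groups against the components separating F-class from ESC and
#' from MEF.
#'
#' @param counts a [count_matrix()] in raw, normalized or averaged state.
#' @param K number of trajectory clusters (default 10).
#' @param seed RNG seed for the clustering.
#' @param restarts K-means restarts (default 25).
#' @param scale. unit-variance scaling in the PCA (default `FALSE`).
#' @param score_method how the two contrast contributions combine:
#'   `"min"` (default), `"max"` or `"product"`.
#' @param state_labels optional list (`fclass`, `esc`, `mef`) of column
#'   labels; resolved from the design when `NULL`.
#' @param fclass_samples optional F-class end-state column labels for
#'   cluster selection; default: latest DOXH point.
#' @return object of class `marker_fit` with components `pca`,
#'   `clusters`, `selected_clusters`, `ranking`, `matrix` (the averaged
#'   count matrix), `state_labels`, `K`, `seed`, `call`.
#' @seealso [rank_markers()], [select_fclass_clusters()], [run_pca()]
#' @examples
#' sim <- simulate_timecourse(simulation_config(n_groups = 60, seed = 7))
#' counts <- simulate_counts(sim)
#' fit <- discover_markers(counts, K = 5, seed = 7)
#' head(summary(fit)$ranking)
#' @export
discover_markers <- function(counts, K = 10, seed = 1, restarts = 25,
                             scale. = FALSE,
                             score_method = c("min", "max", "product"),
                             state_labels = NULL, fclass_samples = NULL) {
  score_method <- match.arg(score_method)
  m <- counts
  if (m$state == "raw") m <- normalize_counts(m, mode = "rationale")
  if (m$state == "normalized") m <- average_replicates(m)
  pca <- run_pca(m, scale. = scale.)
  clusters <- cluster_trajectories(m, K = K, seed = seed,
                                   restarts = restarts)
  selected <- select_fclass_clusters(clusters, m,
                                     fclass_samples = fclass_samples)
  if (is.null(state_labels)) state_labels <- .resolve_states(m$design)
  ranking <- rank_markers(pca, clusters, selected,
                          state_labels = state_labels,
                          method = score_method)
  structure(list(pca = pca, clusters = clusters,
                 selected_clusters = selected, ranking = ranking,
                 matrix = m, state_labels = state_labels, K = K,
                 seed = seed, call = match.call()),
            class = "marker_fit")
}

#' @export
print.marker_fit <- function(x, ...) {
  cat("Surface-marker discovery fit\n")
  cat(sprintf("  %d proteoform groups x %d time points\n",
              nrow(x$matrix$values), ncol(x$matrix$values)))
  cat(sprintf("  PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
              100 * x$pca$variance_explained[1L],
              100 * x$pca$variance_explained[2L]))
  cat(sprintf("  K = %d clusters; selected (DOX-up, F-class-max): %s\n",
              x$K, if (length(x$selected_clusters))
                paste(x$selected_clusters, collapse = ", ") else "none"))
  cat(sprintf("  %d candidate markers ranked", nrow(x$ranking)))
  if (nrow(x$ranking)) {
    cat(sprintf("; top: %s (score %.3f)", x$ranking$primary_id[1L],
                x$ranking$score[1L]))
  }
  cat("\n")
  invisible(x)
}

#' @method summary marker_fit
#' @export
summary.marker_fit <- function(object, n_top = 10, ...) {
  out <- list(
    n_groups = nrow(object$matrix$values),
    n_points = ncol(object$matrix$values),
    variance_explained = object$pca$variance_explained,
    cluster_sizes = table(object$clusters$cluster),
    selected_clusters = object$selected_clusters,
    separating_components = c(
      fclass_vs_esc = attr(object$ranking, "pc_fclass_esc"),
      fclass_vs_mef = attr(object$ranking, "pc_fclass_mef")),
    ranking = utils::head(as.data.frame(object$ranking), n_top)
  )
  class(out) <- "summary.marker_fit"
  out
}

#' @export
print.summary.marker_fit <- function(x, ...) {
  cat(sprintf("Marker discovery: %d groups, %d time points\n",
              x$n_groups, x$n_points))
  cat("Variance explained (first 4 PCs): ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 4)),
            collapse = ", "), "\n", sep = "")
  cat("Cluster sizes: ", paste(x$cluster_sizes, collapse = "/"), "\n",
      sep = "")
  cat("Selected clusters: ",
      if (length(x$selected_clusters))
        paste(x$selected_clusters, collapse = ", ") else "none", "\n",
      sep = "")
  cat(sprintf("Separating components: PC%d (F-class vs ESC), PC%d (F-class vs MEF)\n",
              x$separating_components[[1L]], x$separating_components[[2L]]))
  cat("Top candidates:\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Marker scores of a discovery fit
#' @param object a `marker_fit`.
#' @param ... unused.
#' @return named numeric vector of marker scores (descending).
#' @method coef marker_fit
#' @export
coef.marker_fit <- function(object, ...) {
  stats::setNames(object$ranking$score, object$ranking$primary_id)
}

#' Plot a marker-discovery fit
#'
#' Left panel: PCA score plot (PC1 vs PC2) with points labelled by
#' condition. Right panel: mean standardized trajectories of the selected
#' clusters across the DOXH arm.
#'
#' @param x a `marker_fit`.
#' @param ... passed to [graphics::plot()].
#' @method plot marker_fit
#' @export
plot.marker_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sc <- x$pca$scores
  d <- x$matrix$design
  cond <- factor(d$condition[match(rownames(sc), d$sample_id)],
                 levels = CONDITION_LEVELS)
  graphics::plot(sc[, 1L], sc[, 2L], col = as.integer(cond), pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$pca$variance_explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$pca$variance_explained[2L]),
                 main = "Time-course PCA", ...)
  graphics::legend("topright", legend = levels(cond),
                   col = seq_along(levels(cond)), pch = 19, cex = 0.7)
  doxh <- d$sample_id[d$condition %in% c("MEF", "DOXH")]
  z <- .zscore_rows(log2(x$matrix$values + 1))[, doxh, drop = FALSE]
  days <- d$day[match(doxh, d$sample_id)]
  graphics::plot(range(days), range(z), type = "n", xlab = "day",
                 ylab = "mean z-scored log2 count",
                 main = "Selected cluster trajectories")
  ks <- if (length(x$selected_clusters)) x$selected_clusters else
    sort(unique(x$clusters$cluster))
  for (i in seq_along(ks)) {
    traj <- colMeans(z[x$clusters$cluster == ks[i], , drop = FALSE])
    graphics::lines(days[order(days)], traj[order(days)], col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = paste("cluster", ks),
                   col = seq_along(ks), lwd = 2, cex = 0.7)
  invisible(x)
}
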