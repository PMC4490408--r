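# Downstream time-course analysis: fold-change flags, the down-then-up
# overlap statistic, functional-category dispersion, PCA of the averaged
# counts, K-means trajectory clustering with the F-class selection rule,
# and PC-loading marker ranking. Plus delta-delta-Ct and hierarchical
# clustering for validation panels.

#' Fold changes between ordered sample pairs
#'
#' For each proteoform group and each (early, late) column pair of an
#' averaged count matrix, computes the pseudocounted ratio
#' `(late + c) / (early + c)` and flags it `up` when >= theta, `down` when
#' <= 1/theta, `none` otherwise.
#'
#' @param m an averaged-state [count_matrix()].
#' @param pairs list of length-2 character vectors `c(early, late)` naming
#'   columns of `m`.
#' @param theta fold-change threshold, > 1 (default 2).
#' @param pseudocount additive constant c (default 0.5; spectral counts
#'   are small integers).
#' @return data frame with columns `pair`, `primary_id`, `early`, `late`,
#'   `ratio`, `flag`.
#' @export
fold_changes <- function(m, pairs, theta = 2, pseudocount = 0.5) {
  if (!is.numeric(theta) || theta <= 1) {
    stop("theta must be greater than 1", call. = FALSE)
  }
  if (!is.list(pairs)) pairs <- list(pairs)
  out <- lapply(pairs, function(p) {
    stopifnot(length(p) == 2L)
    if (!all(p %in% colnames(m$values))) {
      stop("sample(s) not in matrix: ",
           paste(setdiff(p, colnames(m$values)), collapse = ", "),
           call. = FALSE)
    }
    early <- m$values[, p[1L]]
    late <- m$values[, p[2L]]
    ratio <- (late + pseudocount) / (early + pseudocount)
    flag <- ifelse(ratio >= theta, "up", ifelse(ratio <= 1 / theta, "down",
                                                "none"))
    data.frame(pair = paste(p, collapse = "->"),
               primary_id = rownames(m$values), early = early, late = late,
               ratio = ratio, flag = flag, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Down-then-up overlap percentage
#'
#' Of the proteoform groups upregulated across the late pair (e.g. day 18
#' to the final iPSC state), the percentage that were previously
#' downregulated at least theta-fold across the early pair (e.g. days 0 to
#' 2). Errors when no group is late-upregulated, since the percentage is
#' then undefined.
#'
#' @inheritParams fold_changes
#' @param early_pair,late_pair length-2 character vectors `c(early, late)`.
#' @return percentage in \[0, 100\].
#' @export
down_up_overlap <- function(m, early_pair, late_pair, theta = 2,
                            pseudocount = 0.5) {
  fc <- fold_changes(m, list(early_pair, late_pair), theta = theta,
                     pseudocount = pseudocount)
  early <- fc[fc$pair == paste(early_pair, collapse = "->"), ]
  late <- fc[fc$pair == paste(late_pair, collapse = "->"), ]
  late_up <- late$primary_id[late$flag == "up"]
  if (!length(late_up)) {
    stop("no late-upregulated groups: overlap percentage undefined",
         call. = FALSE)
  }
  early_down <- early$primary_id[early$flag == "down"]
  100 * length(intersect(late_up, early_down)) / length(late_up)
}

#' Functional-category composition and its dispersion over time
#'
#' At each time point the detected proteoform groups (count > 0) are
#' tabulated into functional categories as percentages summing to 100.
#' For each category the standard deviation of its percentage across time
#' points is computed, and those s.d. values are averaged (unweighted)
#' into a single stability figure. A composition that is stable over the
#' course gives a mean s.d. near zero.
#'
#' @param m an averaged-state [count_matrix()].
#' @param annotations named character vector primary_id -> category;
#'   unannotated groups fall into `"other"`.
#' @return list with `percentages` (category x time point matrix),
#'   `per_category_sd`, and `mean_sd`.
#' @export
category_dispersion <- function(m, annotations) {
  ids <- rownames(m$values)
  cat_of <- ifelse(ids %in% names(annotations), annotations[ids], "other")
  cats <- sort(unique(cat_of))
  pct <- matrix(0, nrow = length(cats), ncol = ncol(m$values),
                dimnames = list(cats, colnames(m$values)))
  for (j in seq_len(ncol(m$values))) {
    detected <- cat_of[m$values[, j] > 0]
    if (length(detected)) {
      tab <- table(factor(detected, levels = cats))
      pct[, j] <- 100 * as.numeric(tab) / length(detected)
    }
  }
  if (ncol(pct) < 2L) {
    warning("single time point: category s.d. undefined, reported as 0",
            call. = FALSE)
    sds <- stats::setNames(rep(0, length(cats)), cats)
  } else {
    sds <- apply(pct, 1L, stats::sd)
  }
  list(percentages = pct, per_category_sd = sds, mean_sd = mean(sds))
}

#' PCA of the averaged time course
#'
#' Samples (time points) are the observations and proteoform groups the
#' variables. Counts are transformed as log2(x + 1) and column-centred;
#' unit-variance scaling is off by default since spectral counts share a
#' scale.
#'
#' @param m an averaged-state [count_matrix()] (>= 2 samples, >= 2
#'   groups).
#' @param scale. scale variables to unit variance (default `FALSE`).
#' @param transform transformation applied to counts before PCA.
#' @return list of class `csc_pca` with `scores` (sample x component),
#'   `loadings` (group x component), `variance_explained` (fractions,
#'   non-increasing, summing to 1) and the underlying `prcomp` fit.
#' @export
run_pca <- function(m, scale. = FALSE, transform = function(x) log2(x + 1)) {
  if (ncol(m$values) < 2L || nrow(m$values) < 2L) {
    stop("PCA needs at least 2 samples and 2 groups", call. = FALSE)
  }
  x <- t(transform(m$values))
  v <- apply(x, 2L, stats::var)
  if (all(v < .Machine$double.eps)) {
    stop("constant matrix: no variance to decompose", call. = FALSE)
  }
  if (isTRUE(scale.)) {
    # zero-variance variables cannot be scaled; leave them unscaled
    x[, v < .Machine$double.eps] <- 0
    sdv <- sqrt(pmax(v, .Machine$double.eps))
    x <- sweep(x, 2L, ifelse(v < .Machine$double.eps, 1, sdv), `/`)
    fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  } else {
    fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 variance_explained = ve, prcomp = fit,
                 design = m$design),
            class = "csc_pca")
}

#' @export
print.csc_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d groups; variance explained PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$variance_explained[1L],
              100 * x$variance_explained[min(2L, length(x$variance_explained))]))
  invisible(x)
}

.zscore_rows <- function(values) {
  mu <- rowMeans(values)
  sdv <- apply(values, 1L, stats::sd)
  z <- (values - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' K-means clustering of standardized trajectories
#'
#' Each group's trajectory is z-scored across time points (so clustering
#' sees shape, not abundance) and partitioned by K-means; the best of
#' `restarts` random initializations by total within-cluster sum of
#' squares is kept. Deterministic for a fixed seed.
#'
#' @param m an averaged-state [count_matrix()].
#' @param K number of clusters (>= 2, <= number of groups; default 10).
#' @param seed RNG seed.
#' @param restarts random restarts (default 25).
#' @param transform transformation applied before z-scoring, matching the
#'   PCA transform.
#' @return list of class `trajectory_clusters` with `cluster` (named
#'   integer vector), `centers` (cluster x time point, on the z scale) and
#'   `tot_withinss`.
#' @export
cluster_trajectories <- function(m, K = 10, seed = 1, restarts = 25,
                                 transform = function(x) log2(x + 1)) {
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (K > nrow(m$values)) {
    stop("K (", K, ") exceeds the number of groups (", nrow(m$values), ")",
         call. = FALSE)
  }
  z <- .zscore_rows(transform(m$values))
  set.seed(seed)
  km <- stats::kmeans(z, centers = K, nstart = restarts, iter.max = 100)
  structure(list(cluster = stats::setNames(km$cluster, rownames(m$values)),
                 centers = km$centers, tot_withinss = km$tot.withinss,
                 K = K, seed = seed),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf("K-means trajectory clustering: K = %d, sizes %s\n", x$K,
              paste(table(x$cluster), collapse = "/")))
  invisible(x)
}

.resolve_states <- function(design) {
  # F-class end state: the late DOXH plateau (day >= 18 under sustained
  # DOX-high, falling back to the latest point for shorter courses); MEF
  # start: the day-0 point; ESC reference: the ESC condition (iPSC points
  # are the separate transgene-independent end state).
  doxh <- design[design$condition == "DOXH", , drop = FALSE]
  fclass <- doxh$sample_id[doxh$day >= 18L]
  if (!length(fclass) && nrow(doxh)) {
    fclass <- doxh$sample_id[doxh$day == max(doxh$day)]
  }
  mef <- design$sample_id[design$day == 0L]
  esc <- design$sample_id[design$condition == "ESC"]
  list(fclass = fclass, esc = esc, mef = mef)
}

#' Select clusters upregulated after induction and peaking at F-class
#'
#' A cluster is selected iff its mean standardized trajectory (a) rises
#' from the day-0 point to the first post-induction point and (b) attains
#' its maximum at an F-class end-state sample.
#'
#' @param clusters a `trajectory_clusters` object.
#' @param m the averaged [count_matrix()] the clustering was run on.
#' @param fclass_samples column labels regarded as the F-class end state;
#'   default: the latest-day DOXH point.
#' @return integer vector of selected cluster ids (possibly empty).
#' @export
select_fclass_clusters <- function(clusters, m, fclass_samples = NULL) {
  d <- m$design
  if (is.null(fclass_samples)) {
    fclass_samples <- .resolve_states(d)$fclass
  }
  if (!length(fclass_samples) || !all(fclass_samples %in% colnames(m$values))) {
    stop("no F-class end-state sample resolvable from the design",
         call. = FALSE)
  }
  day0 <- d$sample_id[d$day == 0L]
  if (!length(day0)) stop("design has no day-0 point", call. = FALSE)
  post_days <- d$day[d$day > 0L & d$condition %in% c("DOXH", "DOXL-", "DOXH-")]
  if (!length(post_days)) stop("design has no post-induction point", call. = FALSE)
  first_post <- d$sample_id[d$day == min(post_days) &
                              d$condition %in% c("DOXH", "DOXL-", "DOXH-")]
  z <- .zscore_rows(log2(m$values + 1))
  sel <- integer(0)
  for (k in sort(unique(clusters$cluster))) {
    traj <- colMeans(z[clusters$cluster == k, , drop = FALSE])
    rises <- mean(traj[first_post]) > mean(traj[day0])
    peak <- names(traj)[which.max(traj)]
    if (rises && peak %in% fclass_samples) sel <- c(sel, k)
  }
  sel
}

.separating_component <- function(pca, samples_a, samples_b) {
  # centroid gap in score units: scores already carry each component's
  # variance, so the raw gap finds the component along which the two
  # states are genuinely far apart; dividing by the per-component score
  # s.d. would instead inflate trailing near-zero-variance components
  sc <- pca$scores
  gap <- vapply(seq_len(ncol(sc)), function(c) {
    abs(mean(sc[samples_a, c]) - mean(sc[samples_b, c]))
  }, 0)
  which.max(gap)
}

#' Rank marker candidates by principal-component contribution
#'
#' For each of the two contrasts (F-class vs ESC, F-class vs MEF) the
#' separating component is the PC with the largest standardized centroid
#' difference between the two states' score coordinates. A group's
#' contribution on a component is `|loading| / max |loading|` over all
#' groups on that component; its marker score is by default the minimum of
#' its two contributions, guaranteeing separation from both reference
#' states. Only groups in selected clusters are scored; ranking is by
#' descending score, ties broken by primary ID.
#'
#' @param pca a `csc_pca` fit on the averaged matrix.
#' @param clusters a `trajectory_clusters` object on the same matrix.
#' @param selected integer vector of selected cluster ids
#'   (see [select_fclass_clusters()]).
#' @param state_labels list with elements `fclass`, `esc`, `mef`, each a
#'   non-empty character vector of column labels; default resolved from
#'   the design (latest DOXH point, ESC condition, day-0 point).
#' @param method combine the two contributions by `"min"` (default),
#'   `"max"` or `"product"`.
#' @return data frame of class `marker_ranking`: `rank`, `primary_id`,
#'   `score`, `contrib_fclass_esc`, `contrib_fclass_mef`, `cluster`; with
#'   attributes `pc_fclass_esc` and `pc_fclass_mef` naming the separating
#'   components.
#' @export
rank_markers <- function(pca, clusters, selected, state_labels = NULL,
                         method = c("min", "max", "product")) {
  method <- match.arg(method)
  if (is.null(state_labels)) state_labels <- .resolve_states(pca$design)
  for (nm in c("fclass", "esc", "mef")) {
    if (!length(state_labels[[nm]])) {
      stop("state '", nm, "' has no samples", call. = FALSE)
    }
    if (!all(state_labels[[nm]] %in% rownames(pca$scores))) {
      stop("state '", nm, "' names samples absent from the PCA",
           call. = FALSE)
    }
  }
  pc1 <- .separating_component(pca, state_labels$fclass, state_labels$esc)
  pc2 <- .separating_component(pca, state_labels$fclass, state_labels$mef)
  contrib <- function(pc) {
    l <- abs(pca$loadings[, pc])
    mx <- max(l)
    if (mx == 0) rep(0, length(l)) else l / mx
  }
  c1 <- contrib(pc1)
  c2 <- contrib(pc2)
  score <- switch(method,
                  min = pmin(c1, c2),
                  max = pmax(c1, c2),
                  product = c1 * c2)
  ids <- names(clusters$cluster)[clusters$cluster %in% selected]
  ids <- intersect(ids, rownames(pca$loadings))
  out <- data.frame(primary_id = ids, score = score[ids],
                    contrib_fclass_esc = c1[ids], contrib_fclass_mef = c2[ids],
                    cluster = clusters$cluster[ids], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$primary_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "pc_fclass_esc") <- pc1
  attr(out, "pc_fclass_mef") <- pc2
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target - Ct_reference)_sample -
#' (Ct_target - Ct_reference)_calibrator`, reported as fold change
#' `2^(-ddCt)` relative to the calibrator sample, per gene.
#'
#' @param ct data frame from [read_ct_table()] (columns `gene`,
#'   `sample_id`, `ct_target`, `ct_reference`).
#' @param calibrator sample_id of the calibrator; must carry Ct values for
#'   every gene.
#' @return data frame with `gene`, `sample_id`, `ddct`, `fold_change`.
#' @export
relative_expression_ddct <- function(ct, calibrator) {
  .require_columns(ct, c("gene", "sample_id", "ct_target", "ct_reference"),
                   "Ct table")
  if (anyNA(ct$ct_reference)) {
    stop("missing reference Ct value(s)", call. = FALSE)
  }
  out <- lapply(split(ct, ct$gene), function(g) {
    cal <- g[g$sample_id == calibrator, , drop = FALSE]
    if (nrow(cal) != 1L) {
      stop("calibrator sample '", calibrator, "' missing for gene ",
           g$gene[1L], call. = FALSE)
    }
    dct <- g$ct_target - g$ct_reference
    ddct <- dct - (cal$ct_target - cal$ct_reference)
    data.frame(gene = g$gene, sample_id = g$sample_id, ddct = ddct,
               fold_change = 2^(-ddct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of an expression table
#'
#' Euclidean distance with average linkage by default, mirroring the
#' documented defaults of the common clustergram tools; both are
#' configurable. Deterministic leaf order for a fixed input.
#'
#' @param x numeric matrix with rownames (>= 2 rows, no missing values).
#' @param distance distance method for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list with `order` (leaf labels in dendrogram order), `merge`,
#'   `height` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(x, distance = "euclidean",
                                 linkage = "average") {
  if (!is.matrix(x) || nrow(x) < 2L) {
    stop("need a matrix with at least 2 rows", call. = FALSE)
  }
  if (anyNA(x) || any(is.nan(x))) {
    stop("missing or NaN entries in expression table", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  list(order = rownames(x)[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}
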