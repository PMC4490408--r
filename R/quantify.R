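# Spectral-count quantification: tally counts per proteoform group and
# replicate, square-root depth normalization against a reference total of
# 400, and replicate averaging with absence treated as zero.

#' Construct a spectral-count matrix
#'
#' The container used throughout quantification: a proteoform-group x
#' sample matrix plus the time-course design and a processing-state flag
#' (`raw` integer tallies, `normalized`, or `averaged` with one column per
#' (condition, day) point).
#'
#' @param values numeric matrix, rows = proteoform groups (rownames =
#'   primary IDs), columns = samples; non-negative, integer when `state`
#'   is `raw`.
#' @param design validated design data frame; `values` column names must
#'   be design sample IDs (for `raw`/`normalized`) or point labels (for
#'   `averaged`).
#' @param state one of `raw`, `normalized`, `averaged`.
#' @param mode normalization mode stamp (`rationale` or `literal`), `NA`
#'   until normalized.
#' @param reference_total the reference per-replicate total (default 400).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(values, design, state = c("raw", "normalized",
                                                   "averaged"),
                         mode = NA_character_, reference_total = 400) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative spectral counts", call. = FALSE)
  if (state == "raw" && any(values != round(values))) {
    stop("raw counts must be integers", call. = FALSE)
  }
  if (state != "averaged" &&
      !all(colnames(values) %in% design$sample_id)) {
    stop("column labels must be design sample ids", call. = FALSE)
  }
  structure(list(values = values, design = design, state = state,
                 mode = mode, reference_total = reference_total),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d proteoform groups x %d samples\n",
              x$state, nrow(x$values), ncol(x$values)))
  if (!is.na(x$mode)) {
    cat(sprintf("  normalization: %s mode, reference total %g\n",
                x$mode, x$reference_total))
  }
  cat(sprintf("  total counts: %g\n", sum(x$values)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Tally spectral counts per proteoform group and sample
#'
#' Entry (g, s) is the number of retained PSMs in sample s whose peptide
#' belongs to group g's peptide set. A peptide shared by several groups
#' contributes a count to each. Every design sample gets a column, all-zero
#' when it yielded no PSMs.
#'
#' @param retained_psms qualified PSM data frame (needs `peptide_sequence`
#'   and `sample_id`); every sample_id must appear in the design.
#' @param groups `proteoform_groups` data frame from [build_groups()].
#' @param design validated design.
#' @return a raw-state [count_matrix()].
#' @export
tally <- function(retained_psms, groups, design) {
  unknown <- setdiff(unique(retained_psms$sample_id), design$sample_id)
  if (length(unknown)) {
    stop("PSM(s) with sample_id not in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  samples <- design$sample_id
  values <- matrix(0L, nrow = nrow(groups), ncol = length(samples),
                   dimnames = list(groups$primary_id, samples))
  pep_counts <- table(retained_psms$peptide_sequence, retained_psms$sample_id)
  for (g in seq_len(nrow(groups))) {
    peps <- intersect(groups$peptides[[g]], rownames(pep_counts))
    if (length(peps)) {
      cnt <- colSums(pep_counts[peps, , drop = FALSE])
      values[g, names(cnt)] <- values[g, names(cnt)] + as.integer(cnt)
    }
  }
  count_matrix(values, design, state = "raw")
}

#' Depth-normalize raw spectral counts
#'
#' Each replicate's counts are rescaled through the square-root depth
#' factor `f_r = sqrt(R0 / T_r)` where `T_r` is the replicate's total
#' observed count and `R0` the reference total (400). The square root
#' deliberately compresses depth correction, balancing the expectation of
#' similar totals against the possibility of a real biological difference.
#'
#' Two readings of the published rule are provided: `rationale` (default)
#' multiplies by `f_r`, so deeper replicates are scaled down toward the
#' reference; `literal` divides by `f_r`, the sentence read verbatim. The
#' mode used is stamped on the result. Zero-total columns pass through
#' unchanged with a warning.
#'
#' @param m a raw-state [count_matrix()].
#' @param mode `"rationale"` or `"literal"`.
#' @param reference_total reference total R0 (default taken from `m`).
#' @return a normalized-state `count_matrix`.
#' @export
normalize_counts <- function(m, mode = c("rationale", "literal"),
                             reference_total = m$reference_total) {
  mode <- match.arg(mode)
  if (m$state != "raw") {
    stop("normalize_counts expects a raw-state count matrix, got ",
         m$state, call. = FALSE)
  }
  totals <- colSums(m$values)
  if (any(totals == 0)) {
    warning("zero-total column(s) left unchanged: ",
            paste(colnames(m$values)[totals == 0], collapse = ", "),
            call. = FALSE)
  }
  f <- ifelse(totals > 0, sqrt(reference_total / totals), 1)
  scale <- if (mode == "rationale") f else 1 / f
  values <- sweep(m$values, 2L, scale, `*`)
  out <- count_matrix(values, m$design, state = "normalized", mode = mode,
                      reference_total = reference_total)
  out$state <- "normalized"
  out
}

.point_label <- function(condition, day) sprintf("%s_d%d", condition, day)

#' Average technical replicates into one value per time point
#'
#' Produces one column per (condition, day) point. The denominator is the
#' designed replicate count for that point, so a replicate absent from the
#' matrix contributes zero — absence of spectral counts is evidence of
#' absence, not missingness.
#'
#' @param m a normalized-state [count_matrix()].
#' @return an averaged-state `count_matrix`; its `design` holds one row
#'   per point (replicate = number of designed replicates) and column
#'   labels are `<condition>_d<day>`.
#' @export
average_replicates <- function(m) {
  if (m$state != "normalized") {
    stop("average_replicates expects a normalized-state count matrix, got ",
         m$state, call. = FALSE)
  }
  d <- m$design
  d$condition <- factor(d$condition, levels = CONDITION_LEVELS)
  pts <- unique(d[order(d$condition, d$day), c("condition", "day")])
  values <- matrix(0, nrow = nrow(m$values), ncol = nrow(pts),
                   dimnames = list(rownames(m$values),
                                   .point_label(as.character(pts$condition),
                                                pts$day)))
  n_rep <- integer(nrow(pts))
  for (j in seq_len(nrow(pts))) {
    ids <- d$sample_id[d$condition == pts$condition[j] & d$day == pts$day[j]]
    n_rep[j] <- length(ids)
    present <- intersect(ids, colnames(m$values))
    if (length(present)) {
      values[, j] <- rowSums(m$values[, present, drop = FALSE]) / n_rep[j]
    }
  }
  avg_design <- data.frame(sample_id = colnames(values), day = pts$day,
                           condition = as.character(pts$condition),
                           replicate = n_rep, stringsAsFactors = FALSE)
  out <- count_matrix(values, avg_design, state = "averaged", mode = m$mode,
                      reference_total = m$reference_total)
  out
}

#' Write a count matrix as TSV with a metadata header line
#'
#' First line: `# count_matrix state=<s> mode=<m> reference_total=<r>`;
#' then a header row and one row per proteoform group. Values round-trip
#' bit-exactly through [read_count_matrix()] (integers as integers, reals
#' at full double precision).
#'
#' @param m a [count_matrix()].
#' @param path output path.
#' @export
write_count_matrix <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# count_matrix state=%s mode=%s reference_total=%.17g",
                     m$state, m$mode, m$reference_total), con)
  vals <- apply(m$values, c(1, 2), function(v) {
    if (v == round(v)) sprintf("%d", as.integer(v)) else sprintf("%.17g", v)
  })
  writeLines(paste(c("primary_id", colnames(m$values)), collapse = "\t"), con)
  writeLines(paste(rownames(m$values),
                   apply(vals, 1L, paste, collapse = "\t"), sep = "\t"), con)
  writeLines("#design", con)
  writeLines(paste(names(m$design), collapse = "\t"), con)
  writeLines(do.call(paste, c(m$design, sep = "\t")), con)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV path.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[1L]
  if (!startsWith(meta, "# count_matrix")) {
    stop("not a count_matrix file: ", path, call. = FALSE)
  }
  get_meta <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", meta)
  sep <- which(lines == "#design")
  body <- lines[2:(sep - 1L)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  values <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                     numeric(length(header) - 1L)))
  # single-column matrices come back transposed from vapply
  if (length(header) == 2L) values <- matrix(values, ncol = 1L)
  dimnames(values) <- list(vapply(rows, `[[`, "", 1L), header[-1L])
  dlines <- lines[(sep + 1L):length(lines)]
  dheader <- strsplit(dlines[1L], "\t", fixed = TRUE)[[1L]]
  drows <- strsplit(dlines[-1L], "\t", fixed = TRUE)
  design <- as.data.frame(do.call(rbind, drows), stringsAsFactors = FALSE)
  names(design) <- dheader
  design$day <- as.integer(design$day)
  design$replicate <- as.integer(design$replicate)
  mode <- get_meta("mode")
  if (get_meta("state") == "raw" && all(values == round(values))) {
    storage.mode(values) <- "integer"
  }
  count_matrix(values, design, state = get_meta("state"),
               mode = if (mode == "NA") NA_character_ else mode,
               reference_total = as.numeric(get_meta("reference_total")))
}
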