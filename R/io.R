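# Readers and writers for every table the pipeline touches. All files are
# UTF-8, tab-separated, with fixed column names but free column order.

CONDITION_LEVELS <- c("MEF", "DOXH", "DOXL-", "DOXH-", "ESC", "iPSC")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a PSM table, filtering on identification confidence
#'
#' Expects a tab-separated file with columns `peptide_sequence`,
#' `modifications` (see [as_modifications()] for the encoding),
#' `observed_mass` (neutral monoisotopic Da), `confidence` (a per-PSM
#' probability in \[0,1\] from an upstream search-engine validator),
#' `protein_accessions` (semicolon-joined), `sample_id` and
#' `replicate_id`. Column order is free.
#'
#' Records below the confidence threshold are dropped (default 0.98, the
#' conventional 98% identification confidence). Malformed rows are never
#' silently discarded: they are reported with their line numbers in a
#' warning and returned in the `malformed` attribute, so retained +
#' below-threshold + malformed row counts always sum to the input rows
#' (attributes `n_input` and `n_below_threshold`).
#'
#' @param path file path.
#' @param confidence_threshold minimum per-PSM confidence kept.
#' @return data frame of retained PSM records.
#' @export
read_psm_table <- function(path, confidence_threshold = 0.98) {
  df <- .read_tsv(path)
  required <- c("peptide_sequence", "modifications", "observed_mass",
                "confidence", "protein_accessions", "sample_id",
                "replicate_id")
  .require_columns(df, required, "PSM table")
  df <- df[, required]
  n_input <- nrow(df)
  mass <- suppressWarnings(as.numeric(df$observed_mass))
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad_mass <- is.na(mass) | mass <= 0
  bad_conf <- !bad_mass & (is.na(conf) | conf < 0 | conf > 1)
  seq_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$peptide_sequence)
  # modification positions must stay inside the peptide; parse the strings
  # lightly (unique ones only, they repeat heavily)
  mods_ok <- rep(TRUE, n_input)
  has_mods <- nzchar(df$modifications) & !is.na(df$modifications)
  if (any(has_mods)) {
    key <- paste(df$peptide_sequence[has_mods], df$modifications[has_mods],
                 sep = "\r")
    firsts <- which(!duplicated(key))
    ok_u <- vapply(firsts, function(j) {
      i <- which(has_mods)[j]
      tryCatch({
        m <- as_modifications(df$modifications[i])
        all(m$position >= 1L & m$position <= nchar(df$peptide_sequence[i]))
      }, error = function(e) FALSE)
    }, NA)
    mods_ok[has_mods] <- ok_u[match(key, key[firsts])]
  }
  bad_fmt <- !bad_mass & !bad_conf & !(seq_ok & mods_ok)
  bad <- bad_mass | bad_conf | bad_fmt
  bad_line <- which(bad) + 1L  # +1: header line
  bad_reason <- ifelse(bad_mass[bad],
                       "unparseable or non-positive observed_mass",
                       ifelse(bad_conf[bad], "confidence not a probability",
                              "invalid peptide sequence or modifications"))
  ok <- which(!bad)
  if (length(bad_line)) {
    warning("PSM table: ", length(bad_line), " malformed row(s) at line(s) ",
            paste(bad_line, collapse = ", "), call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  out$observed_mass <- mass[ok]
  out$confidence <- conf[ok]
  keep <- out$confidence >= confidence_threshold
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_input") <- n_input
  attr(res, "n_below_threshold") <- sum(!keep)
  attr(res, "malformed") <- data.frame(line = bad_line, reason = bad_reason,
                                       stringsAsFactors = FALSE)
  res
}

#' Write a PSM table
#' @param records PSM data frame.
#' @param path output path.
#' @export
write_psm_table <- function(records, path) {
  df <- records
  df$observed_mass <- sprintf("%.6f", as.numeric(df$observed_mass))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a time-course design table
#'
#' @param design data frame with columns `sample_id`, `day`, `condition`,
#'   `replicate`.
#' @return the validated design (days and replicates as integers,
#'   conditions checked against the closed vocabulary `MEF`, `DOXH`,
#'   `DOXL-`, `DOXH-`, `ESC`, `iPSC`).
#' @export
validate_design <- function(design) {
  .require_columns(design, c("sample_id", "day", "condition", "replicate"),
                   "design table")
  design$day <- suppressWarnings(as.integer(design$day))
  design$replicate <- suppressWarnings(as.integer(design$replicate))
  if (anyDuplicated(design$sample_id)) {
    stop("design table: duplicated sample_id: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(design$day) || any(design$day < 0L)) {
    stop("design table: day must be a non-negative integer", call. = FALSE)
  }
  unknown <- setdiff(unique(design$condition), CONDITION_LEVELS)
  if (length(unknown)) {
    stop("design table: unknown condition value(s): ",
         paste(unknown, collapse = ", "), "; allowed: ",
         paste(CONDITION_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (anyNA(design$replicate) || any(design$replicate < 1L)) {
    stop("design table: replicate must be a positive integer", call. = FALSE)
  }
  rownames(design) <- NULL
  design
}

#' Read a time-course design table
#' @param path tab-separated file with sample_id/day/condition/replicate.
#' @return validated design data frame.
#' @export
read_design <- function(path) {
  validate_design(.read_tsv(path))
}

#' Write a design table
#' @param design design data frame.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein FASTA database
#'
#' Accessions are the first whitespace-delimited token of each header and
#' must be unique; sequences are uppercased. Empty sequences are an error.
#'
#' @param path FASTA file.
#' @return named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(seqs))) {
    stop("FASTA: duplicate accession(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA: empty sequence for accession(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' Write a protein FASTA database
#' @param seqs named character vector (accession -> sequence).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read a functional-annotation table
#'
#' Two columns, `primary_id` and `functional_category`, mapping each
#' proteoform group to one category from a closed user-supplied vocabulary
#' (stands in for an external gene-list classification).
#'
#' @param path tab-separated file.
#' @return named character vector, primary_id -> category.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("primary_id", "functional_category"),
                   "annotation table")
  if (anyDuplicated(df$primary_id)) {
    stop("annotation table: more than one category for: ",
         paste(unique(df$primary_id[duplicated(df$primary_id)]),
               collapse = ", "), call. = FALSE)
  }
  stats::setNames(df$functional_category, df$primary_id)
}

#' Read an isoform index
#'
#' Maps each protein accession to its gene symbol and the primary protein
#' ID under which its isoform group is quantified collectively.
#'
#' @param path tab-separated file with accession/gene/primary_id columns.
#' @return data frame.
#' @export
read_isoform_index <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("accession", "gene", "primary_id"), "isoform index")
  if (anyDuplicated(df$accession)) {
    stop("isoform index: duplicated accession(s)", call. = FALSE)
  }
  df
}

#' Read a qPCR Ct table
#'
#' Columns: `gene`, `sample_id`, `ct_target`, `ct_reference` (cycle
#' thresholds of the gene of interest and of the internal reference gene,
#' e.g. Gapdh, in the same sample).
#'
#' @param path tab-separated file.
#' @return data frame with numeric Ct columns.
#' @export
read_ct_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene", "sample_id", "ct_target", "ct_reference"),
                   "Ct table")
  df$ct_target <- as.numeric(df$ct_target)
  df$ct_reference <- as.numeric(df$ct_reference)
  if (anyNA(df$ct_target) || anyNA(df$ct_reference) ||
      any(df$ct_target <= 0) || any(df$ct_reference <= 0)) {
    stop("Ct table: cycle thresholds must be positive numbers", call. = FALSE)
  }
  df
}
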