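# Peptide-to-protein mapping and proteoform-group construction. Isoforms of
# one gene share peptide evidence that cannot be attributed to a single
# isoform, so isoforms sharing a (gene, primary ID) key are quantified
# collectively as one proteoform group.

#' Map peptides onto a protein database by exact substring containment
#'
#' @param peptides character vector of peptide sequences.
#' @param fasta_db named character vector (accession -> protein sequence),
#'   e.g. from [read_fasta()]; must be non-empty.
#' @return named list, peptide -> character vector of accessions containing
#'   it (possibly empty). Peptides with zero hits are also listed in the
#'   `unmapped` attribute.
#' @export
map_peptides <- function(peptides, fasta_db) {
  if (!length(fasta_db)) stop("protein database is empty", call. = FALSE)
  peptides <- unique(peptides)
  hits <- lapply(peptides, function(p) {
    names(fasta_db)[grepl(p, fasta_db, fixed = TRUE)]
  })
  names(hits) <- peptides
  attr(hits, "unmapped") <- peptides[vapply(hits, length, 1L) == 0L]
  hits
}

#' Collapse protein isoforms into proteoform groups
#'
#' Accessions sharing a (gene, primary ID) key in the isoform index merge
#' into one group; each peptide attaches to every group that contains one
#' of its hits (by default a peptide shared across groups is counted in
#' each — the collective reading; `cross_gene = "exclude"` drops such
#' peptides instead). Groups left without peptides are dropped.
#'
#' @param peptide_map output of [map_peptides()].
#' @param isoform_index data frame with columns `accession`, `gene`,
#'   `primary_id` (see [read_isoform_index()]); every mapped accession must
#'   appear in it. An empty `primary_id` falls back to the
#'   lexicographically smallest member accession, for determinism.
#' @param cross_gene `"count_each"` (default) or `"exclude"`.
#' @return data frame of class `proteoform_groups`, one row per group,
#'   with columns `primary_id`, `gene_symbol`, `members`
#'   (semicolon-joined accessions) and a list column `peptides`; ordered
#'   by `primary_id`.
#' @export
build_groups <- function(peptide_map, isoform_index,
                         cross_gene = c("count_each", "exclude")) {
  cross_gene <- match.arg(cross_gene)
  mapped_acc <- unique(unlist(peptide_map, use.names = FALSE))
  missing <- setdiff(mapped_acc, isoform_index$accession)
  if (length(missing)) {
    stop("accession(s) missing from isoform index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- isoform_index
  key <- paste(idx$gene, idx$primary_id, sep = "\r")
  acc_key <- stats::setNames(key, idx$accession)

  # group key -> member accessions / primary id
  members <- split(idx$accession, key)
  primary <- vapply(members, function(acc) {
    pid <- unique(idx$primary_id[idx$accession %in% acc])
    pid <- pid[nzchar(pid)]
    if (length(pid)) pid[1L] else min(acc)
  }, "")
  gene <- vapply(members, function(acc) {
    g <- unique(idx$gene[idx$accession %in% acc])
    if (length(g)) g[1L] else ""
  }, "")

  # peptide -> group keys it hits
  pep_keys <- lapply(peptide_map, function(acc) unique(acc_key[acc]))
  pep_keys <- pep_keys[vapply(pep_keys, length, 1L) > 0L]
  if (cross_gene == "exclude") {
    pep_keys <- pep_keys[vapply(pep_keys, length, 1L) == 1L]
  }
  group_peps <- lapply(stats::setNames(names(members), names(members)),
                       function(k) {
    sort(names(pep_keys)[vapply(pep_keys, function(ks) k %in% ks, NA)])
  })
  nonempty <- vapply(group_peps, length, 1L) > 0L

  out <- data.frame(
    primary_id = unname(primary[nonempty]),
    gene_symbol = unname(gene[nonempty]),
    members = vapply(members[nonempty],
                     function(a) paste(sort(a), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  out$peptides <- unname(group_peps[nonempty])
  out <- out[order(out$primary_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("proteoform_groups", "data.frame")
  out
}

#' Write proteoform groups as TSV (peptides and members semicolon-joined)
#' @param groups a `proteoform_groups` data frame.
#' @param path output path.
#' @export
write_groups <- function(groups, path) {
  df <- data.frame(
    primary_id = groups$primary_id,
    gene_symbol = groups$gene_symbol,
    members = groups$members,
    peptides = vapply(groups$peptides, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read proteoform groups written by [write_groups()]
#' @param path TSV path.
#' @return `proteoform_groups` data frame.
#' @export
read_groups <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("primary_id", "gene_symbol", "members", "peptides"),
                   "groups table")
  df$peptides <- strsplit(df$peptides, ";", fixed = TRUE)
  class(df) <- c("proteoform_groups", "data.frame")
  df
}
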