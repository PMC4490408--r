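#' Locate N-glycosylation sequons in a peptide
#'
#' A full sequon is N-x-S/T with x any residue except proline. Because
#' proteolysis can split a sequon across two peptides, a peptide ending in
#' "N" (kind `truncated_N`) or in "N,x" with x != P (kind `truncated_Nx`)
#' carries at least the start of a sequon and is accepted when
#' `allow_truncated` is on.
#'
#' Overlapping full matches are all reported (e.g. "NNSS" twice).
#'
#' @param peptide_sequence uppercase amino-acid string.
#' @param allow_truncated also report C-terminally truncated sequons.
#' @return data frame with columns `position` (1-based index of the Asn)
#'   and `kind` (one of `full`, `truncated_N`, `truncated_Nx`); zero rows
#'   when the peptide carries no sequon.
#' @examples
#' find_sequons("GNASK")   # full match at 2
#' find_sequons("GNPSK")   # none: x = P excluded
#' find_sequons("GGKN")    # truncated_N at 4
#' @export
find_sequons <- function(peptide_sequence, allow_truncated = TRUE) {
  chars <- .check_sequence(peptide_sequence)
  n <- length(chars)
  pos <- integer(0)
  kind <- character(0)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (chars[i] == "N" && chars[i + 1L] != "P" &&
          chars[i + 2L] %in% c("S", "T")) {
        pos <- c(pos, i)
        kind <- c(kind, "full")
      }
    }
  }
  if (allow_truncated) {
    if (chars[n] == "N") {
      pos <- c(pos, n)
      kind <- c(kind, "truncated_N")
    }
    if (n >= 2L && chars[n - 1L] == "N" && chars[n] != "P") {
      pos <- c(pos, n - 1L)
      kind <- c(kind, "truncated_Nx")
    }
  }
  data.frame(position = pos, kind = kind, stringsAsFactors = FALSE)
}

#' Glycopeptide qualification settings
#'
#' @param ppm_tolerance accurate-mass tolerance in parts per million
#'   (default 20). `Inf` disables the mass gate.
#' @param require_deamidation require a deamidation modification as
#'   evidence of PNGase-F treatment (default `TRUE`).
#' @param allow_truncated_sequon accept peptides carrying only the start of
#'   a sequon at their C terminus (default `TRUE`); `FALSE` gives the
#'   strict full-sequon reading.
#' @param deamidation_on_sequon require the deamidation to sit on a sequon
#'   asparagine specifically, rather than anywhere in the peptide
#'   (default `TRUE`).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(ppm_tolerance = 20, require_deamidation = TRUE,
                          allow_truncated_sequon = TRUE,
                          deamidation_on_sequon = TRUE) {
  if (!is.numeric(ppm_tolerance) || ppm_tolerance <= 0) {
    stop("ppm_tolerance must be positive", call. = FALSE)
  }
  structure(list(ppm_tolerance = ppm_tolerance,
                 require_deamidation = isTRUE(require_deamidation),
                 allow_truncated_sequon = isTRUE(allow_truncated_sequon),
                 deamidation_on_sequon = isTRUE(deamidation_on_sequon)),
            class = "filter_config")
}

# Sequon/deamidation verdict and theoretical mass for one unique
# (sequence, modification-string) pair; records repeat peptides heavily,
# so qualification caches this per pair.
.qualify_key <- function(sequence, mods_string, mass_model, config) {
  sequons <- find_sequons(sequence,
                          allow_truncated = config$allow_truncated_sequon)
  if (!nrow(sequons)) {
    return(list(reason = "no_sequon", theoretical = NA_real_))
  }
  mods <- as_modifications(mods_string)
  if (config$require_deamidation) {
    deam_pos <- mods$position[.is_deamidation(mods$label)]
    hit <- if (config$deamidation_on_sequon) {
      any(deam_pos %in% sequons$position)
    } else {
      length(deam_pos) > 0L
    }
    if (!hit) return(list(reason = "no_deamidation", theoretical = NA_real_))
  }
  list(reason = NA_character_,
       theoretical = peptide_mass(sequence, mods, mass_model))
}

#' Qualify PSMs as genuine N-glycopeptide identifications
#'
#' Applies, in fixed order, the three qualification rules: (1) the peptide
#' must carry a sequon (optionally a C-terminally truncated one); (2) a
#' deamidation modification must sit on a sequon asparagine, the mass
#' signature of PNGase-F release; (3) the observed neutral mass must agree
#' with the theoretical modified mass within the ppm tolerance. A record
#' failing several rules reports the first failing one, so rejection
#' reasons are deterministic.
#'
#' @param records a PSM data frame as returned by [read_psm_table()] (at
#'   least columns `peptide_sequence`, `modifications`, `observed_mass`).
#' @param mass_model see [default_mass_model()].
#' @param config see [filter_config()].
#' @return list with elements `retained` (data frame of qualifying
#'   records) and `rejected` (the others, with an extra `reason` column
#'   drawn from `no_sequon`, `no_deamidation`, `mass_out_of_tolerance`).
#'   Every input row appears in exactly one of the two.
#' @export
qualify_psms <- function(records, mass_model = default_mass_model(),
                         config = filter_config()) {
  stopifnot(is.data.frame(records),
            all(c("peptide_sequence", "modifications", "observed_mass") %in%
                  names(records)))
  n <- nrow(records)
  key <- paste(records$peptide_sequence, records$modifications, sep = "\r")
  first <- which(!duplicated(key))
  info <- lapply(first, function(i) {
    .qualify_key(records$peptide_sequence[i], records$modifications[i],
                 mass_model, config)
  })
  names(info) <- key[first]
  idx <- match(key, key[first])
  reason <- vapply(info, `[[`, "", "reason")[idx]
  theo <- vapply(info, `[[`, 0, "theoretical")[idx]
  needs_mass <- is.na(reason)
  if (any(needs_mass)) {
    off <- ppm_error(records$observed_mass[needs_mass], theo[needs_mass]) >
      config$ppm_tolerance
    reason[needs_mass][off] <- "mass_out_of_tolerance"
  }
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}
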