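#' Monoisotopic mass model for peptide chemistry
#'
#' Residue masses are standard monoisotopic values (Da) for the 20 amino
#' acids, plus the constants the glycopeptide filter needs: the mass of
#' water added on hydrolysis, the carbamidomethyl delta fixed on cysteine
#' by iodoacetamide alkylation, and the asparagine-to-aspartate deamidation
#' delta left by PNGase F at formerly glycosylated sites.
#'
#' The deamidation delta is the chemical value +0.98402 Da. Input
#' modification tables are free to label deamidation with the commonly
#' printed rounded value (0.984 or 0.986); labels, not deltas, identify the
#' modification.
#'
#' @param ppm_tolerance unused here; see [filter_config()].
#' @return A list of class `mass_model` with elements `residue_masses`
#'   (named numeric, Da), `water_mass`, `carbamidomethyl_delta` and
#'   `deamidation_delta`.
#' @examples
#' m <- default_mass_model()
#' m$residue_masses[["G"]] + m$water_mass  # glycine peptide, 75.032 Da
#' @export
default_mass_model <- function() {
  residues <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.009185, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.040485, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  mm <- list(
    residue_masses = residues,
    water_mass = 18.010565,
    carbamidomethyl_delta = 57.02146,
    deamidation_delta = 0.98402
  )
  class(mm) <- "mass_model"
  stopifnot(all(mm$residue_masses > 0),
            abs(residues[["N"]] + mm$deamidation_delta - residues[["D"]]) < 1e-4)
  mm
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.check_sequence <- function(peptide_sequence) {
  if (!is.character(peptide_sequence) || length(peptide_sequence) != 1L ||
      is.na(peptide_sequence) || nchar(peptide_sequence) == 0L) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(peptide_sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("invalid residue(s) in peptide sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}

#' Parse or normalize a peptide modification set
#'
#' Modifications are triples (position, delta mass, label). They may be
#' given as a data frame with those columns, a list of such triples, or the
#' string encoding used in PSM tables: `"pos:delta:label"` entries joined
#' by `";"` (empty string = no modifications).
#'
#' @param mods modifications in any accepted form.
#' @return data frame with columns `position` (integer, 1-based),
#'   `delta_mass` (Da) and `label`.
#' @export
as_modifications <- function(mods) {
  empty <- data.frame(position = integer(), delta_mass = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (is.null(mods) || (is.character(mods) && length(mods) == 1L &&
                        (is.na(mods) || !nzchar(trimws(mods))))) {
    return(empty)
  }
  if (is.character(mods)) {
    parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    ok <- vapply(parts, length, 1L) == 3L
    if (!all(ok)) stop("malformed modification string: ", mods, call. = FALSE)
    out <- data.frame(
      position = as.integer(vapply(parts, `[[`, "", 1L)),
      delta_mass = as.numeric(vapply(parts, `[[`, "", 2L)),
      label = vapply(parts, `[[`, "", 3L),
      stringsAsFactors = FALSE
    )
    if (anyNA(out$position) || anyNA(out$delta_mass)) {
      stop("malformed modification string: ", mods, call. = FALSE)
    }
    return(out)
  }
  if (is.data.frame(mods)) {
    stopifnot(all(c("position", "delta_mass", "label") %in% names(mods)))
    out <- mods[, c("position", "delta_mass", "label")]
    out$position <- as.integer(out$position)
    return(out)
  }
  if (is.list(mods)) {
    if (!length(mods)) return(empty)
    return(do.call(rbind, lapply(mods, function(m) {
      data.frame(position = as.integer(m[[1L]]), delta_mass = as.numeric(m[[2L]]),
                 label = as.character(m[[3L]]), stringsAsFactors = FALSE)
    })))
  }
  stop("cannot interpret modifications of class ", class(mods)[1L], call. = FALSE)
}

#' Encode a modification table as a PSM-table string
#' @param mods modifications in any form accepted by [as_modifications()].
#' @return single string, `""` when there are no modifications.
#' @export
format_modifications <- function(mods) {
  mods <- as_modifications(mods)
  if (!nrow(mods)) return("")
  paste(sprintf("%d:%.5f:%s", mods$position, mods$delta_mass, mods$label),
        collapse = ";")
}

.is_deamidation <- function(label) grepl("deamid", label, ignore.case = TRUE)

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue monoisotopic masses plus one water plus all modification
#' deltas. The observed-mass column of a PSM table is expected on the same
#' scale (neutral monoisotopic Da); any charge or m/z conversion is the
#' producer's responsibility.
#'
#' @param peptide_sequence uppercase amino-acid string.
#' @param modifications see [as_modifications()].
#' @param mass_model a [default_mass_model()]-style list.
#' @return mass in Da.
#' @examples
#' peptide_mass("G")  # 75.03203
#' @export
peptide_mass <- function(peptide_sequence, modifications = NULL,
                         mass_model = default_mass_model()) {
  chars <- .check_sequence(peptide_sequence)
  mods <- as_modifications(modifications)
  if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > length(chars))) {
      stop("modification position outside peptide length", call. = FALSE)
    }
    deam <- .is_deamidation(mods$label)
    if (any(deam & chars[mods$position] != "N")) {
      stop("deamidation modification placed on a non-asparagine residue",
           call. = FALSE)
    }
  }
  sum(mass_model$residue_masses[chars]) + mass_model$water_mass +
    sum(mods$delta_mass)
}

#' Relative mass deviation in parts per million
#'
#' `|observed - theoretical| / theoretical * 1e6`, the quantity compared
#' against the accurate-mass tolerance (20 ppm by default) when qualifying
#' glycopeptide identifications.
#'
#' @param observed_mass,theoretical_mass masses in Da; `theoretical_mass`
#'   must be positive. Vectorized.
#' @return ppm error (non-negative).
#' @examples
#' ppm_error(1000.02, 1000)  # 20
#' @export
ppm_error <- function(observed_mass, theoretical_mass) {
  if (any(theoretical_mass <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  abs(observed_mass - theoretical_mass) / theoretical_mass * 1e6
}
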