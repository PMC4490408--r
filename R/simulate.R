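# Synthetic-data generator with planted ground truth. Emulates a 30-day,
# three-arm reprogramming time course sampled by cell-surface-capture
# glycoproteomics: tryptic peptides with embedded (and C-terminally
# truncated) sequons plus sequon-free decoys, deamidation marks on sequon
# asparagines, per-replicate sequencing-depth variation, and
# protein-abundance trajectories drawn from five archetypes (MEF-down,
# F-class-up, ESC-specific, transient, flat). All randomness flows from a
# single seed.

ARCHETYPES <- c("early_down", "fclass_up", "esc_like", "transient", "flat")

#' Simulation settings
#'
#' Defaults describe the emulated study: 500 proteoform groups over 12
#' distinct days (0-30) in three DOX arms plus MEF/ESC/iPSC reference
#' points, three technical replicates per point, a mean per-replicate
#' depth of 400 spectral counts with lognormal variation (sdlog 0.3), a
#' planted F-class marker elevated 8-fold, and 20% sequon-free decoy
#' records.
#'
#' @param n_groups number of proteoform groups.
#' @param archetype_mix named proportions over `early_down`, `fclass_up`,
#'   `esc_like`, `transient`, `flat`; must sum to 1.
#' @param replicates technical replicates per time point.
#' @param mean_depth expected spectral counts per replicate.
#' @param depth_sdlog lognormal sdlog of per-replicate depth variation.
#' @param marker_effect fold elevation of the planted marker in F-class
#'   samples relative to its baseline.
#' @param decoy_fraction fraction of PSM records on sequon-free peptides.
#' @param noise_sdlog lognormal sdlog of group-level abundance scale.
#' @param traj_sdlog lognormal sdlog of per-(group, point) jitter around
#'   the archetype mean curve.
#' @param bad_mass_fraction fraction of true records spiked to +50 ppm
#'   mass error (rejected by the 20-ppm gate).
#' @param low_conf_fraction fraction of records given confidence below
#'   0.98 (dropped by the reader).
#' @param isoform_fraction fraction of groups carrying two isoform
#'   accessions sharing their peptides.
#' @param dispersion `NULL` for Poisson counts (default), otherwise the
#'   negative-binomial size parameter.
#' @param seed integer seed; every derived RNG stream flows from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 500,
                              archetype_mix = c(early_down = 0.3,
                                                fclass_up = 0.1,
                                                esc_like = 0.1,
                                                transient = 0.2,
                                                flat = 0.3),
                              replicates = 3, mean_depth = 400,
                              depth_sdlog = 0.3, marker_effect = 8,
                              decoy_fraction = 0.2, noise_sdlog = 0.3,
                              traj_sdlog = 0.2, bad_mass_fraction = 0.01,
                              low_conf_fraction = 0.02,
                              isoform_fraction = 0.1,
                              dispersion = NULL, seed = 1) {
  stopifnot(n_groups >= 2, replicates >= 1, mean_depth > 0,
            marker_effect >= 1, decoy_fraction >= 0, decoy_fraction < 1,
            setequal(names(archetype_mix), ARCHETYPES))
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_groups = n_groups,
                 archetype_mix = archetype_mix[ARCHETYPES],
                 replicates = replicates, mean_depth = mean_depth,
                 depth_sdlog = depth_sdlog, marker_effect = marker_effect,
                 decoy_fraction = decoy_fraction, noise_sdlog = noise_sdlog,
                 traj_sdlog = traj_sdlog,
                 bad_mass_fraction = bad_mass_fraction,
                 low_conf_fraction = low_conf_fraction,
                 isoform_fraction = isoform_fraction,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "simulation_config")
}

#' The default three-arm 30-day sampling design
#'
#' MEF at day 0; the DOX-high arm sampled on days 2-30; the DOX-low arm
#' branching at day 16 and the DOX-withdrawn arm at day 21 (both converge
#' to an ESC-like state); ESC and secondary-iPSC reference points at day
#' 30. Twelve distinct days, `replicates` technical replicates per point.
#'
#' @param replicates technical replicates per point.
#' @return validated design data frame.
#' @export
timecourse_design_default <- function(replicates = 3) {
  days <- c(0, 2, 5, 8, 11, 14, 16, 18, 21, 24, 27, 30)
  pts <- rbind(
    data.frame(condition = "MEF", day = 0),
    data.frame(condition = "DOXH", day = days[days > 0]),
    data.frame(condition = "DOXL-", day = days[days >= 16]),
    data.frame(condition = "DOXH-", day = days[days >= 21]),
    data.frame(condition = "ESC", day = 30),
    data.frame(condition = "iPSC", day = 30)
  )
  out <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    data.frame(
      sample_id = sprintf("%s_d%d_r%d", pts$condition[i], pts$day[i],
                          seq_len(replicates)),
      day = pts$day[i], condition = pts$condition[i],
      replicate = seq_len(replicates), stringsAsFactors = FALSE)
  }))
  validate_design(out)
}

# Archetype mean curves (arbitrary relative-abundance units) for one
# (condition, day) point. F-class-up curves take a peak parameter so the
# planted marker can run the same shape at higher amplitude; they rise to
# a plateau over the established F-class period (days 18-30 under
# sustained DOX-high) and fall back when DOX is lowered or withdrawn.
.archetype_mean <- function(archetype, condition, day, fclass_peak = 2) {
  fclass_at <- function(d) 0.4 + (fclass_peak - 0.4) * pmin(d / 18, 1)
  switch(archetype,
    flat = 1,
    early_down = switch(condition,
      MEF = 4,
      ESC = 3, iPSC = 3.5,
      1 + 3 * exp(-day / 0.9)),
    fclass_up = switch(condition,
      MEF = 0.4, ESC = 0.4, iPSC = 0.4,
      DOXH = fclass_at(day),
      # arms branch after the last shared day (14 and 18), so their first
      # sampled point already sits below the DOXH plateau
      `DOXL-` = fclass_at(14) + (0.6 - fclass_at(14)) * (day - 14) / 16,
      `DOXH-` = fclass_at(18) + (0.5 - fclass_at(18)) * (day - 18) / 12),
    esc_like = switch(condition,
      MEF = 0.3, DOXH = 0.4,
      `DOXL-` = 0.4 + (3.2 - 0.4) * (day - 14) / 16,
      `DOXH-` = 0.4 + (3.0 - 0.4) * (day - 18) / 12,
      ESC = 3.5, iPSC = 3.2),
    transient = switch(condition,
      ESC = 0.8, iPSC = 0.8,
      0.8 + 2.2 * exp(-((day - 10) / 5)^2)),
    stop("unknown archetype: ", archetype, call. = FALSE))
}

.assign_archetypes <- function(config) {
  n <- config$n_groups
  counts <- floor(config$archetype_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(config$archetype_mix * n - counts, decreasing = TRUE)
    counts[top[seq_len(rem)]] <- counts[top[seq_len(rem)]] + 1L
  }
  if (counts[["fclass_up"]] == 0L) {  # the marker needs its archetype
    counts[["fclass_up"]] <- 1L
    counts[[which.max(counts)]] <- counts[[which.max(counts)]] - 1L
  }
  rep(ARCHETYPES, counts)
}

#' Simulate per-point abundance trajectories with planted truth
#'
#' Each group follows its archetype's mean curve, multiplied by a
#' group-level lognormal scale and per-point lognormal jitter. One
#' F-class-up group is planted as the marker: it runs the same shape with
#' its F-class peak elevated to `marker_effect` times baseline.
#'
#' @param config a [simulation_config()].
#' @param design a design data frame; default [timecourse_design_default()].
#' @return list with `abundance` (group x point matrix, columns labelled
#'   `<condition>_d<day>`), and `truth` (list: `archetype` named vector,
#'   `marker_id`, `design`, `config`, `seed`).
#' @export
simulate_timecourse <- function(config = simulation_config(),
                                design = timecourse_design_default(
                                  config$replicates)) {
  set.seed(config$seed)
  pts <- unique(design[, c("condition", "day")])
  labels <- .point_label(pts$condition, pts$day)
  archetype <- .assign_archetypes(config)
  ids <- sprintf("G%04d", seq_len(config$n_groups))
  names(archetype) <- ids
  marker_id <- ids[which(archetype == "fclass_up")[1L]]

  scale_g <- stats::rlnorm(config$n_groups, 0, config$noise_sdlog)
  ab <- matrix(0, nrow = config$n_groups, ncol = nrow(pts),
               dimnames = list(ids, labels))
  for (g in seq_len(config$n_groups)) {
    # the marker runs the archetype shape with its elevation above baseline
    # scaled by marker_effect; marker_effect = 1 reproduces the archetype
    peak <- if (ids[g] == marker_id)
      0.4 + (2 - 0.4) * config$marker_effect else 2
    mu <- vapply(seq_len(nrow(pts)), function(j) {
      .archetype_mean(archetype[g], pts$condition[j], pts$day[j],
                      fclass_peak = peak)
    }, 0)
    jitter <- stats::rlnorm(nrow(pts), 0, config$traj_sdlog)
    ab[g, ] <- scale_g[g] * mu * jitter
  }
  truth <- list(archetype = archetype, marker_id = marker_id,
                design = design, config = config, seed = config$seed)
  list(abundance = ab, truth = truth)
}

#' Sample spectral counts from abundance trajectories
#'
#' Each replicate draws a lognormal depth around `mean_depth`; counts are
#' Poisson with mean `depth_r * relative abundance` (negative binomial
#' when `config$dispersion` is set). Reproducible: the RNG stream is
#' derived from `config$seed`.
#'
#' @param trajectories output of [simulate_timecourse()] (or its
#'   `abundance` matrix plus a design via `design`).
#' @param config the [simulation_config()] used.
#' @param design design; defaults to the truth's design.
#' @return a raw-state [count_matrix()], one column per replicate sample.
#' @export
simulate_counts <- function(trajectories, config = trajectories$truth$config,
                            design = trajectories$truth$design) {
  ab <- if (is.list(trajectories)) trajectories$abundance else trajectories
  set.seed(config$seed + 1L)
  rel <- sweep(ab, 2L, colSums(ab), `/`)
  values <- matrix(0L, nrow = nrow(ab), ncol = nrow(design),
                   dimnames = list(rownames(ab), design$sample_id))
  depth <- stats::rlnorm(nrow(design),
                         log(config$mean_depth) - config$depth_sdlog^2 / 2,
                         config$depth_sdlog)
  for (j in seq_len(nrow(design))) {
    lab <- .point_label(design$condition[j], design$day[j])
    lambda <- depth[j] * rel[, lab]
    values[, j] <- if (is.null(config$dispersion)) {
      stats::rpois(nrow(ab), lambda)
    } else {
      stats::rnbinom(nrow(ab), size = config$dispersion, mu = lambda)
    }
  }
  count_matrix(values, design, state = "raw",
               reference_total = 400)
}

.AA_NO_KR <- setdiff(AA_ALPHABET, c("K", "R"))
.AA_NO_KRN <- setdiff(.AA_NO_KR, "N")
.AA_SEQ_X <- setdiff(.AA_NO_KR, c("P", "N"))  # sequon x: not proline

.random_residues <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A tryptic peptide with one guaranteed full sequon (and no accidental N
# elsewhere, so sequon bookkeeping stays exact).
.gen_true_peptide <- function() {
  len <- sample(8:14, 1L)
  body <- strsplit(.random_residues(len, .AA_NO_KRN), "")[[1L]]
  p <- sample(2:(len - 2L), 1L)
  body[p] <- "N"
  body[p + 1L] <- sample(.AA_SEQ_X, 1L)
  body[p + 2L] <- sample(c("S", "T"), 1L)
  list(seq = paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L)),
       sequon_pos = p)
}

# Sequon-free decoy: contains no N at all.
.gen_decoy_peptide <- function() {
  len <- sample(8:14, 1L)
  paste0(.random_residues(len, .AA_NO_KRN), sample(c("K", "R"), 1L))
}

# Protein-C-terminal peptide ending in the bare start of a sequon.
.gen_truncated_peptide <- function() {
  len <- sample(7:12, 1L)
  list(seq = paste0(.random_residues(len, .AA_NO_KRN), "N"),
       sequon_pos = len + 1L)
}

#' Simulate a complete PSM-level fixture with ground truth
#'
#' Builds, per proteoform group, 1-3 tryptic peptides carrying full
#' sequons (one group gets a C-terminally truncated sequon) embedded in a
#' generated protein sequence, plus per-group sequon-free decoy peptides.
#' PSM multiplicities realize [simulate_counts()]; each record picks a
#' decoy peptide with probability `decoy_fraction`. Deamidation
#' modifications sit on the sequon asparagine of true records; observed
#' masses are theoretical within a uniform +/-10 ppm, except a labelled
#' spike at +50 ppm; a labelled fraction of records gets confidence below
#' 0.98. Every qualification edge case (proline-containing NPS motif,
#' truncated sequon, off-tolerance mass, sub-threshold confidence) occurs
#' at least once in every default fixture.
#'
#' A fraction of groups carries two isoform accessions sharing all
#' peptides, so grouping genuinely collapses isoforms.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory: writes `psm.tsv`, `proteins.fasta`,
#'   `isoform_index.tsv`, `design.tsv`, `truth.json`.
#' @return list: `psm` (record data frame with truth flag columns
#'   `is_decoy`, `bad_mass`, `low_confidence`), `fasta`, `isoform_index`,
#'   `design`, `counts` (the realized raw [count_matrix()]), `truth`.
#' @export
simulate_psm_table <- function(config = simulation_config(), dir = NULL) {
  traj <- simulate_timecourse(config)
  counts <- simulate_counts(traj, config)
  design <- traj$truth$design
  set.seed(config$seed + 2L)

  n <- config$n_groups
  ids <- rownames(traj$abundance)
  true_peps <- vector("list", n)
  decoy_peps <- character(n)
  sequon_pos <- vector("list", n)
  for (g in seq_len(n)) {
    k <- sample(1:3, 1L)
    peps <- lapply(seq_len(k), function(i) .gen_true_peptide())
    if (g == 1L) peps[[1L]] <- .gen_truncated_peptide()
    true_peps[[g]] <- vapply(peps, `[[`, "", "seq")
    sequon_pos[[g]] <- vapply(peps, `[[`, 0L, "sequon_pos")
    decoy_peps[g] <- .gen_decoy_peptide()
  }

  # proteins: peptides joined by filler segments ending K/R; isoform
  # groups get a second accession extending the first sequence
  filler <- function() paste0(.random_residues(sample(5:10, 1L), .AA_NO_KRN),
                              sample(c("K", "R"), 1L))
  fasta <- character(0)
  idx <- list()
  for (g in seq_len(n)) {
    acc <- sprintf("P%04d", g)
    gene <- sprintf("Gene%04d", g)
    parts <- c(rbind(vapply(seq_along(true_peps[[g]]),
                            function(i) filler(), ""),
                     true_peps[[g]]), filler(), decoy_peps[g])
    seqs <- paste(parts, collapse = "")
    fasta[[acc]] <- seqs
    idx[[length(idx) + 1L]] <- data.frame(accession = acc, gene = gene,
                                          primary_id = acc,
                                          stringsAsFactors = FALSE)
    if (stats::runif(1) < config$isoform_fraction) {
      acc2 <- paste0(acc, "-2")
      fasta[[acc2]] <- paste0(seqs, filler())
      idx[[length(idx) + 1L]] <- data.frame(accession = acc2, gene = gene,
                                            primary_id = acc,
                                            stringsAsFactors = FALSE)
    }
  }
  isoform_index <- do.call(rbind, idx)
  group_members <- split(isoform_index$accession, isoform_index$primary_id)
  mm <- default_mass_model()

  make_record <- function(g, sample_id, replicate_id, decoy, bad_mass,
                          low_conf) {
    if (decoy) {
      pep <- decoy_peps[g]
      mods <- ""
    } else {
      i <- sample.int(length(true_peps[[g]]), 1L)
      pep <- true_peps[[g]][i]
      mods <- sprintf("%d:%.5f:Deamidated", sequon_pos[[g]][i],
                      mm$deamidation_delta)
    }
    cpos <- which(strsplit(pep, "")[[1L]] == "C")
    if (length(cpos)) {
      cam <- sprintf("%d:%.5f:Carbamidomethyl", cpos,
                     mm$carbamidomethyl_delta)
      mods <- paste(c(if (nzchar(mods)) mods, cam), collapse = ";")
    }
    theo <- peptide_mass(pep, mods, mm)
    err <- if (bad_mass) 50e-6 else stats::runif(1, -10e-6, 10e-6)
    conf <- if (low_conf) stats::runif(1, 0.5, 0.979) else
      stats::runif(1, 0.9801, 0.9999)
    data.frame(peptide_sequence = pep, modifications = mods,
               observed_mass = theo * (1 + err), confidence = conf,
               protein_accessions = paste(group_members[[sprintf("P%04d", g)]],
                                          collapse = ";"),
               sample_id = sample_id, replicate_id = replicate_id,
               is_decoy = decoy, bad_mass = bad_mass,
               low_confidence = low_conf, stringsAsFactors = FALSE)
  }

  # peptide-level lookup: theoretical mass and modification string are
  # fixed per peptide, so records can be expanded vectorized
  pep_mods <- function(pep, deam_pos = NA) {
    mods <- character(0)
    if (!is.na(deam_pos)) {
      mods <- sprintf("%d:%.5f:Deamidated", deam_pos, mm$deamidation_delta)
    }
    cpos <- which(strsplit(pep, "")[[1L]] == "C")
    if (length(cpos)) {
      mods <- c(mods, sprintf("%d:%.5f:Carbamidomethyl", cpos,
                              mm$carbamidomethyl_delta))
    }
    paste(mods, collapse = ";")
  }
  pep_tab <- do.call(rbind, lapply(seq_len(n), function(g) {
    seqs <- c(true_peps[[g]], decoy_peps[g])
    deam <- c(sequon_pos[[g]], NA)
    mods <- vapply(seq_along(seqs), function(i) pep_mods(seqs[i], deam[i]), "")
    data.frame(g = g, seq = seqs, mods = mods,
               theo = vapply(seq_along(seqs),
                             function(i) peptide_mass(seqs[i], mods[i], mm), 0),
               is_decoy = c(rep(FALSE, length(true_peps[[g]])), TRUE),
               stringsAsFactors = FALSE)
  }))
  true_rows <- split(which(!pep_tab$is_decoy), pep_tab$g[!pep_tab$is_decoy])
  decoy_rows <- stats::setNames(which(pep_tab$is_decoy),
                                pep_tab$g[pep_tab$is_decoy])

  v <- counts$values
  g_idx <- rep(rep(seq_len(n), ncol(v)), as.vector(v))
  col_idx <- rep(seq_len(ncol(v)), colSums(v))
  n_rec <- length(g_idx)
  decoy <- stats::runif(n_rec) < config$decoy_fraction
  bad <- !decoy & stats::runif(n_rec) < config$bad_mass_fraction
  low <- stats::runif(n_rec) < config$low_conf_fraction
  pick <- integer(n_rec)
  u <- stats::runif(n_rec)
  for (i in seq_len(n_rec)) {
    rows <- true_rows[[g_idx[i]]]
    pick[i] <- if (decoy[i]) decoy_rows[[as.character(g_idx[i])]]
               else rows[ceiling(u[i] * length(rows))]
  }
  err <- ifelse(bad, 50e-6, stats::runif(n_rec, -10e-6, 10e-6))
  conf <- ifelse(low, stats::runif(n_rec, 0.5, 0.979),
                 stats::runif(n_rec, 0.9801, 0.9999))
  acc_of_group <- vapply(seq_len(n), function(g)
    paste(group_members[[sprintf("P%04d", g)]], collapse = ";"), "")
  rid_of_col <- as.character(design$replicate[match(colnames(v),
                                                    design$sample_id)])
  psm <- data.frame(
    peptide_sequence = pep_tab$seq[pick],
    modifications = pep_tab$mods[pick],
    observed_mass = pep_tab$theo[pick] * (1 + err),
    confidence = conf,
    protein_accessions = acc_of_group[g_idx],
    sample_id = colnames(v)[col_idx],
    replicate_id = rid_of_col[col_idx],
    is_decoy = decoy, bad_mass = bad, low_confidence = low,
    stringsAsFactors = FALSE)

  # guaranteed edge cases (only for the spikes actually switched on),
  # appended deterministically on the first sample
  s1 <- design$sample_id[1L]
  r1 <- as.character(design$replicate[1L])
  if (config$bad_mass_fraction > 0) {
    psm <- rbind(psm, make_record(1L, s1, r1, decoy = FALSE,
                                  bad_mass = TRUE, low_conf = FALSE))
  }
  if (config$low_conf_fraction > 0) {
    psm <- rbind(psm, make_record(1L, s1, r1, decoy = FALSE,
                                  bad_mass = FALSE, low_conf = TRUE))
  }
  if (config$decoy_fraction > 0) {
    # proline-motif peptide: NPS is not a sequon
    nps <- paste0(.random_residues(6, .AA_NO_KRN), "NPS",
                  .random_residues(3, .AA_NO_KRN), "K")
    nps_rec <- make_record(1L, s1, r1, decoy = TRUE, bad_mass = FALSE,
                           low_conf = FALSE)
    nps_rec$peptide_sequence <- nps
    nps_rec$modifications <- ""
    nps_rec$observed_mass <- peptide_mass(nps, NULL, mm)
    fasta[["P0001"]] <- paste0(fasta[["P0001"]], nps)
    psm <- rbind(psm, nps_rec)
  }
  rownames(psm) <- NULL

  truth <- traj$truth
  truth$counts_seed <- config$seed + 1L
  truth$primary_id <- stats::setNames(sprintf("P%04d", seq_len(n)), ids)
  truth$group_peptides <- stats::setNames(true_peps, ids)
  truth$decoy_peptides <- stats::setNames(decoy_peps, ids)
  truth$n_records <- nrow(psm)
  truth$n_expected_retained <- sum(!psm$is_decoy & !psm$bad_mass &
                                     !psm$low_confidence)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(psm[, 1:7], file.path(dir, "psm.tsv"))
    write_fasta(fasta, file.path(dir, "proteins.fasta"))
    utils::write.table(isoform_index, file.path(dir, "isoform_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_design(design, file.path(dir, "design.tsv"))
    jsonlite::write_json(
      list(seed = config$seed, marker_id = truth$marker_id,
           archetype = as.list(truth$archetype),
           n_records = truth$n_records,
           n_expected_retained = truth$n_expected_retained),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(psm = psm, fasta = fasta, isoform_index = isoform_index,
       design = design, counts = counts, truth = truth)
}
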