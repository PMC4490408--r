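noiseless <- function(...) {
  simulation_config(noise_sdlog = 1e-9, traj_sdlog = 1e-9, ...)
}

test_that("archetype curves realize their defining features", {
  cfg <- noiseless(n_groups = 50, seed = 2)
  sim <- simulate_timecourse(cfg)
  ab <- sim$abundance
  arch <- sim$truth$archetype

  ed <- ab[arch == "early_down", , drop = FALSE]
  expect_true(all(ed[, "DOXH_d2"] <= 0.5 * ed[, "MEF_d0"] + 1e-6))

  fc <- ab[arch == "fclass_up" & rownames(ab) != sim$truth$marker_id, ,
           drop = FALSE]
  doxh <- grep("^DOXH_", colnames(ab), value = TRUE)
  expect_true(all(apply(fc, 1L, function(r) {
    names(which.max(r[doxh])) %in% c("DOXH_d18", "DOXH_d21", "DOXH_d24",
                                     "DOXH_d27", "DOXH_d30")
  })))
  # withdrawal arms fall back toward ESC-like levels
  expect_true(all(fc[, "DOXL-_d30"] < fc[, "DOXH_d30"]))
  expect_true(all(fc[, "DOXH-_d30"] < fc[, "DOXH_d30"]))
})

test_that("an all-flat mix yields trajectories constant in expectation", {
  cfg <- noiseless(n_groups = 20,
                   archetype_mix = c(early_down = 0, fclass_up = 0,
                                     esc_like = 0, transient = 0, flat = 1),
                   seed = 5)
  sim <- simulate_timecourse(cfg)
  ranges <- apply(sim$abundance, 1L, function(r) diff(range(r)))
  # one fclass group is forced to host the marker; all others are flat
  expect_lte(sum(ranges > 1e-6), 1L)
})

test_that("marker_effect = 1 leaves the marker on its archetype curve", {
  cfg <- noiseless(n_groups = 30, marker_effect = 1, seed = 8)
  sim <- simulate_timecourse(cfg)
  mk <- sim$truth$marker_id
  others <- names(sim$truth$archetype)[sim$truth$archetype == "fclass_up"]
  others <- setdiff(others, mk)
  # same shape: trajectories proportional to any other fclass group
  ratio <- sim$abundance[mk, ] / sim$abundance[others[1L], ]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("counts are Poisson around depth-scaled relative abundance", {
  cfg <- simulation_config(n_groups = 100, depth_sdlog = 1e-9, seed = 4)
  sim <- simulate_timecourse(cfg)
  cm <- simulate_counts(sim)
  expect_true(all(cm$values == round(cm$values)))
  # expected column total = depth; Poisson s.e. per column = 20
  totals <- colSums(cm$values)
  expect_lt(abs(mean(totals) - 400), 3 * 20 / sqrt(length(totals)))

  # zero abundance gives zero counts always
  sim0 <- sim
  sim0$abundance["G0001", ] <- 0
  cm0 <- simulate_counts(sim0, cfg)
  expect_true(all(cm0$values["G0001", ] == 0))

  # identical seeds give identical matrices
  expect_identical(simulate_counts(sim, cfg)$values, cm$values)
})

test_that("the PSM fixture honours its truth bookkeeping", {
  cfg <- simulation_config(n_groups = 40, seed = 17)
  fix <- simulate_psm_table(cfg)
  psm <- fix$psm
  # reader threshold + qualification recover exactly the clean records
  readable <- psm[psm$confidence >= 0.98, ]
  q <- qualify_psms(readable[, 1:7])
  expect_equal(nrow(q$retained),
               sum(!psm$is_decoy & !psm$bad_mass & !psm$low_confidence))
  # decoy share of records is near its nominal rate
  expect_lt(abs(mean(psm$is_decoy) - cfg$decoy_fraction), 0.03)

  # every qualification edge case occurs in the default fixture
  expect_true(any(psm$bad_mass))
  expect_true(any(psm$low_confidence))
  expect_true(any(grepl("NPS", psm$peptide_sequence)))
  expect_true(any(grepl("N$", psm$peptide_sequence[!psm$is_decoy])))

  # rejection reasons match the planted defects
  expect_setequal(unique(q$rejected$reason),
                  c("no_sequon", "mass_out_of_tolerance"))
})

test_that("a clean fixture qualifies completely", {
  cfg <- simulation_config(n_groups = 15, decoy_fraction = 0,
                           bad_mass_fraction = 0, low_conf_fraction = 0,
                           seed = 9)
  fix <- simulate_psm_table(cfg)
  q <- qualify_psms(fix$psm[, 1:7])
  expect_equal(nrow(q$rejected), 0L)
})

test_that("grouping the fixture reproduces the planted partition", {
  cfg <- simulation_config(n_groups = 40, seed = 21)
  fix <- simulate_psm_table(cfg)
  q <- qualify_psms(fix$psm[fix$psm$confidence >= 0.98, 1:7])
  g <- build_groups(map_peptides(unique(q$retained$peptide_sequence),
                                 fix$fasta),
                    fix$isoform_index)
  # every group with retained evidence appears, under its planted primary id
  expect_setequal(g$primary_id,
                  sort(unique(sub(";.*$", "", q$retained$protein_accessions))))
  # peptides attached to each group are that group's planted peptides
  for (i in seq_len(nrow(g))) {
    pid <- g$primary_id[i]
    gid <- names(fix$truth$primary_id)[fix$truth$primary_id == pid]
    expect_true(all(g$peptides[[i]] %in% fix$truth$group_peptides[[gid]]))
  }
})

test_that("fixture files round-trip from disk", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_groups = 12, seed = 3)
  fix <- simulate_psm_table(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "psm.tsv", "proteins.fasta", "isoform_index.tsv", "design.tsv",
    "truth.json")))))
  psm <- read_psm_table(file.path(dir, "psm.tsv"), confidence_threshold = 0)
  expect_equal(nrow(psm), nrow(fix$psm))
  db <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_identical(db, fix$fasta)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$marker_id, fix$truth$marker_id)
})

test_that("qualify-group-tally reproduces the simulated counts", {
  cors <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_groups = 120, seed = s)
    fix <- simulate_psm_table(cfg)
    q <- qualify_psms(fix$psm[fix$psm$confidence >= 0.98, 1:7])
    g <- build_groups(map_peptides(unique(q$retained$peptide_sequence),
                                   fix$fasta), fix$isoform_index)
    raw <- tally(q$retained, g, fix$design)
    map <- fix$truth$primary_id
    common <- intersect(rownames(raw$values), unname(map))
    sim_v <- fix$counts$values[names(map)[match(common, map)], , drop = FALSE]
    cor(as.vector(raw$values[common, ]), as.vector(sim_v))
  }, 0)
  expect_true(all(cors > 0.95))
})
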