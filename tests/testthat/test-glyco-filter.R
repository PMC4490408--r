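test_that("sequon detection covers full, proline-excluded and truncated forms", {
  hit <- find_sequons("GNASK")
  expect_equal(hit$position, 2L)
  expect_equal(hit$kind, "full")

  expect_equal(nrow(find_sequons("GNPSK")), 0L)  # x = P excluded

  trunc <- find_sequons("GGKN")
  expect_equal(trunc$position, 4L)
  expect_equal(trunc$kind, "truncated_N")

  # C-terminal N,x with x != P
  nx <- find_sequons("GGKNA")
  expect_true(any(nx$kind == "truncated_Nx" & nx$position == 4L))
  expect_false(any(find_sequons("GGKNP")$kind == "truncated_Nx"))

  # overlapping full matches are all reported
  expect_equal(find_sequons("NNSS")$position[find_sequons("NNSS")$kind == "full"],
               c(1L, 2L))

  # truncated matches can be switched off
  expect_equal(nrow(find_sequons("GGKN", allow_truncated = FALSE)), 0L)

  for (aa in setdiff(AA20, "N")) {
    expect_equal(nrow(find_sequons(aa)), 0L)
  }
  expect_error(find_sequons("GNXSK"), "invalid residue")
})

test_that("sequon scan agrees with the regex oracle on random peptides", {
  set.seed(42)
  for (i in 1:300) {
    pep <- random_peptide(sample(5:40, 1))
    got <- find_sequons(pep)
    want <- oracle_sequons(pep)
    expect_equal(got[order(got$position, got$kind), ],
                 want[order(want$position, want$kind), ],
                 ignore_attr = TRUE, label = pep)
  }
})

test_that("peptide masses match monoisotopic chemistry", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  # deamidated Asn is chemically Asp
  expect_equal(peptide_mass("N", "1:0.98402:Deamidated"), peptide_mass("D"),
               tolerance = 1e-3)
  expect_equal(peptide_mass("GNASK", NULL), peptide_mass("GNASK", ""))
  expect_error(peptide_mass("GASK", "1:0.98402:Deamidated"),
               "non-asparagine")
  expect_error(peptide_mass("GNASK", "9:0.98402:Deamidated"),
               "outside peptide length")
})

test_that("ppm error is symmetric, zero at identity, linear in deviation", {
  expect_equal(ppm_error(1000.02, 1000), 20)
  expect_equal(ppm_error(999.98, 1000), 20)
  expect_equal(ppm_error(123.456, 123.456), 0)
  expect_error(ppm_error(10, 0), "positive")
})

test_that("qualification applies sequon, deamidation and mass rules in order", {
  mm <- default_mass_model()
  good <- toy_psm()  # sequon + deamidation on it + exact mass
  no_deam <- toy_psm(modifications = "",
                     observed_mass = peptide_mass("GNASK"))
  theo <- peptide_mass("GNASK", "2:0.98402:Deamidated")
  off_mass <- toy_psm(observed_mass = theo * (1 + 25e-6))
  no_seq <- toy_psm(peptide_sequence = "GAASK", modifications = "",
                    observed_mass = peptide_mass("GAASK"))

  res <- qualify_psms(rbind(good, no_deam, off_mass, no_seq))
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$rejected$reason,
               c("no_deamidation", "mass_out_of_tolerance", "no_sequon"))
  # reasons are ordered: a record failing everything reports no_sequon
  multi <- toy_psm(peptide_sequence = "GAASK", modifications = "",
                   observed_mass = 9999)
  expect_equal(qualify_psms(multi)$rejected$reason, "no_sequon")
  # retained + rejected partition the input
  expect_equal(nrow(res$retained) + nrow(res$rejected), 4L)
})

test_that("deamidation must sit on a sequon Asn unless relaxed", {
  # two Asn: position 2 in a sequon, position 6 not
  pep <- "GNASKNAR"
  off_site <- toy_psm(peptide_sequence = pep,
                      modifications = "6:0.98402:Deamidated",
                      observed_mass = peptide_mass(pep,
                                                   "6:0.98402:Deamidated"))
  strict <- qualify_psms(off_site)
  expect_equal(strict$rejected$reason, "no_deamidation")
  relaxed <- qualify_psms(off_site,
                          config = filter_config(deamidation_on_sequon = FALSE))
  expect_equal(nrow(relaxed$retained), 1L)
})

test_that("qualification is idempotent and monotone in the tolerance", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    pep <- random_peptide(sample(6:15, 1))
    sq <- find_sequons(pep)
    mods <- if (nrow(sq)) sprintf("%d:0.98402:Deamidated", sq$position[1L])
            else ""
    mods <- tryCatch({
      as_modifications(mods)
      if (nzchar(mods) &&
          substring(pep, sq$position[1L], sq$position[1L]) == "N") mods
      else ""
    }, error = function(e) "")
    theo <- peptide_mass(pep, mods)
    toy_psm(peptide_sequence = pep, modifications = mods,
            observed_mass = theo * (1 + runif(1, -30e-6, 30e-6)))
  }))
  res <- qualify_psms(recs)
  again <- qualify_psms(res$retained)
  expect_equal(nrow(again$retained), nrow(res$retained))
  expect_equal(nrow(again$rejected), 0L)

  sizes <- vapply(c(5, 10, 20, 40, Inf), function(tol) {
    nrow(qualify_psms(recs, config = filter_config(ppm_tolerance = tol))$retained)
  }, 0L)
  expect_true(all(diff(sizes) >= 0))

  # with deamidation off and infinite tolerance, sequon presence decides
  all_seq <- qualify_psms(recs, config = filter_config(
    ppm_tolerance = Inf, require_deamidation = FALSE))
  has_sequon <- vapply(recs$peptide_sequence,
                       function(p) nrow(find_sequons(p)) > 0, NA)
  expect_equal(nrow(all_seq$retained), sum(has_sequon))
})
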