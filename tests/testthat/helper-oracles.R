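# Independent oracles and small fixture builders used across tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Regex-based sequon oracle, an independent route from the window scan:
# full sequons via lookahead, truncated starts via suffix patterns.
oracle_sequons <- function(seq, allow_truncated = TRUE) {
  pos <- integer(0)
  kind <- character(0)
  m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    pos <- as.integer(m)
    kind <- rep("full", length(m))
  }
  if (allow_truncated) {
    n <- nchar(seq)
    if (substring(seq, n, n) == "N") {
      pos <- c(pos, n)
      kind <- c(kind, "truncated_N")
    }
    if (n >= 2L && grepl("N[^P]$", seq)) {
      pos <- c(pos, n - 1L)
      kind <- c(kind, "truncated_Nx")
    }
  }
  data.frame(position = pos, kind = kind, stringsAsFactors = FALSE)
}

# Two-pass set-arithmetic oracle for the down-then-up overlap.
oracle_overlap <- function(values, early, late, theta = 2, c = 0.5) {
  up <- character(0)
  down <- character(0)
  for (g in rownames(values)) {
    r_late <- (values[g, late[2L]] + c) / (values[g, late[1L]] + c)
    r_early <- (values[g, early[2L]] + c) / (values[g, early[1L]] + c)
    if (r_late >= theta) up <- c(up, g)
    if (r_early <= 1 / theta) down <- c(down, g)
  }
  if (!length(up)) stop("empty late-up set")
  100 * length(intersect(up, down)) / length(up)
}

# Adjusted Rand index from the pair-counting formula.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# A minimal averaged count matrix with an explicit per-point design.
toy_averaged <- function(values, days, conditions) {
  design <- data.frame(
    sample_id = colnames(values), day = as.integer(days),
    condition = conditions, replicate = 1L, stringsAsFactors = FALSE)
  count_matrix(values, design, state = "averaged", mode = "rationale")
}

# A valid PSM record row; fields overridable.
toy_psm <- function(peptide_sequence = "GNASK",
                    modifications = "2:0.98402:Deamidated",
                    observed_mass = NULL, confidence = 0.99,
                    protein_accessions = "P1", sample_id = "s1",
                    replicate_id = "1") {
  if (is.null(observed_mass)) {
    observed_mass <- peptide_mass(peptide_sequence, modifications)
  }
  data.frame(peptide_sequence = peptide_sequence,
             modifications = modifications, observed_mass = observed_mass,
             confidence = confidence,
             protein_accessions = protein_accessions,
             sample_id = sample_id, replicate_id = replicate_id,
             stringsAsFactors = FALSE)
}

write_tsv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}
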