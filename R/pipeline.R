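# End-to-end pipeline: simulate -> qualify -> group -> quantify ->
# discover, with a flat key-value config, structured per-stage logging and
# a manifest recording inputs, parameters, seed and output checksums.

.default_run_config <- function() {
  list(seed = 1, n_groups = 500, replicates = 3, mean_depth = 400,
       marker_effect = 8, decoy_fraction = 0.2,
       confidence_threshold = 0.98, ppm_tolerance = 20,
       normalization_mode = "rationale", reference_total = 400,
       theta = 2, pseudocount = 0.5, k = 10, restarts = 25,
       out_dir = "csc_run")
}

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line (a TOML-dialect subset); `#` starts a
#' comment; unknown keys are rejected. Values are coerced to the type of
#' the corresponding default.
#'
#' @param path config file path.
#' @return full config list (file values over defaults).
#' @export
read_run_config <- function(path) {
  defaults <- .default_run_config()
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(gsub('^"|"$', "", trimws(kv[2L])))
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    cfg[[key]] <- if (is.numeric(defaults[[key]])) as.numeric(val) else val
  }
  cfg
}

.stage <- function(name, expr, log_level = "info") {
  if (log_level != "quiet") {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
  }
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline on synthetic data
#'
#' Chains simulate -> qualify -> group -> tally -> normalize -> average ->
#' discover, writing every intermediate table plus a `manifest.json`
#' (parameters, seed, per-file MD5 checksums) to the output directory.
#' Byte-identical outputs for identical configs.
#'
#' @param config a config list (see [read_run_config()]), a config file
#'   path, or `NULL` for the defaults.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param log_level `"info"` or `"quiet"`.
#' @return invisibly, a list with the fit, the matrices and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL,
                         log_level = "info") {
  cfg <- if (is.null(config)) .default_run_config()
         else if (is.character(config)) read_run_config(config)
         else utils::modifyList(.default_run_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_cfg <- simulation_config(n_groups = cfg$n_groups,
                               replicates = cfg$replicates,
                               mean_depth = cfg$mean_depth,
                               marker_effect = cfg$marker_effect,
                               decoy_fraction = cfg$decoy_fraction,
                               seed = cfg$seed)
  fixture_dir <- file.path(cfg$out_dir, "fixtures")
  sim <- .stage("simulate",
                simulate_psm_table(sim_cfg, dir = fixture_dir), log_level)

  psm <- .stage("read_psm",
                read_psm_table(file.path(fixture_dir, "psm.tsv"),
                               confidence_threshold = cfg$confidence_threshold),
                log_level)
  qual <- .stage("qualify",
                 qualify_psms(psm,
                              config = filter_config(
                                ppm_tolerance = cfg$ppm_tolerance)),
                 log_level)
  write_psm_table(qual$retained, file.path(cfg$out_dir, "retained.tsv"))
  rej <- qual$rejected
  utils::write.table(rej[, c("peptide_sequence", "sample_id", "reason")],
                     file.path(cfg$out_dir, "rejects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fasta <- read_fasta(file.path(fixture_dir, "proteins.fasta"))
  idx <- read_isoform_index(file.path(fixture_dir, "isoform_index.tsv"))
  groups <- .stage("group", {
    pm <- map_peptides(unique(qual$retained$peptide_sequence), fasta)
    build_groups(pm, idx)
  }, log_level)
  write_groups(groups, file.path(cfg$out_dir, "groups.tsv"))

  design <- read_design(file.path(fixture_dir, "design.tsv"))
  raw <- .stage("tally", tally(qual$retained, groups, design), log_level)
  norm <- .stage("normalize",
                 normalize_counts(raw, mode = cfg$normalization_mode,
                                  reference_total = cfg$reference_total),
                 log_level)
  avg <- .stage("average", average_replicates(norm), log_level)
  write_count_matrix(raw, file.path(cfg$out_dir, "counts_raw.tsv"))
  write_count_matrix(avg, file.path(cfg$out_dir, "counts_averaged.tsv"))

  if (cfg$k > nrow(avg$values)) {
    stop("stage 'cluster' failed: K (", cfg$k,
         ") exceeds the number of quantified groups (", nrow(avg$values),
         ")", call. = FALSE)
  }
  fit <- .stage("discover",
                discover_markers(avg, K = cfg$k, seed = cfg$seed,
                                 restarts = cfg$restarts), log_level)
  rank_path <- file.path(cfg$out_dir, "markers_ranked.tsv")
  utils::write.table(as.data.frame(fit$ranking), rank_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(primary_id = names(fit$clusters$cluster),
               cluster = fit$clusters$cluster),
    file.path(cfg$out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(fit$pca$scores),
               round(fit$pca$scores, 10)),
    file.path(cfg$out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  outputs <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("cscMarker")),
    parameters = cfg,
    seed = cfg$seed,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$checksums) <- sub(paste0("^", cfg$out_dir, "/?"), "",
                                   names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, raw = raw, averaged = avg, groups = groups,
                 truth = sim$truth, manifest = manifest,
                 out_dir = cfg$out_dir))
}
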