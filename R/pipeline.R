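# End-to-end orchestration: simulate -> normalize -> classify -> integrate
# -> report. Every stage reads and writes plain-text files inside one run
# directory, records its record counts, and reconciles in = out + excluded.

run_paths <- function(dir) {
  list(config = file.path(dir, "config.yaml"),
       spots = file.path(dir, "spots.tsv"),
       manifest = file.path(dir, "manifest.tsv"),
       proteins = file.path(dir, "proteins.tsv"),
       complexes = file.path(dir, "complexes.tsv"),
       msms = file.path(dir, "msms.tsv"),
       rna = file.path(dir, "rna.tsv"),
       signals = file.path(dir, "signals.tsv"),
       detection = file.path(dir, "detection.tsv"),
       matrix = file.path(dir, "signal_matrix.tsv"),
       states = file.path(dir, "states.tsv"),
       pairs = file.path(dir, "co_complex_pairs.tsv"),
       merged = file.path(dir, "merged_table.tsv"),
       overlap = file.path(dir, "overlap_report.json"),
       report = file.path(dir, "run_report.json"))
}

stage_record <- function(stage, n_in, n_out, n_excluded, flags = character(0)) {
  if (n_in != n_out + n_excluded) {
    secmap_stop("secmap_integrity_error",
                sprintf("stage '%s' counts do not reconcile: %d != %d + %d",
                        stage, n_in, n_out, n_excluded))
  }
  list(stage = stage, n_in = n_in, n_out = n_out, n_excluded = n_excluded,
       qc_flags = as.character(flags))
}

#' Simulate stage: write truth, spot table and omics tables
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Stage record (counts + QC flags), invisibly.
#' @export
secmap_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- run_paths(dir)
  truth <- generate_proteome(config)
  elu <- simulate_elution(truth)
  merged <- merge_elution(elu)
  spots <- simulate_array(merged, truth$antibodies, config)
  omics <- simulate_omics(truth)
  write_run_config(config, p$config)
  write_spot_table(spots, p$spots)
  write_tsv(truth$antibodies, p$manifest)
  write_tsv(truth$proteins, p$proteins)
  write_tsv(truth$complexes, p$complexes)
  write_tsv(omics$msms, p$msms)
  write_tsv(omics$rna, p$rna)
  message(sprintf("[simulate] %d proteins -> %d spots, %d msms rows, %d rna rows",
                  nrow(truth$proteins), nrow(spots), nrow(omics$msms),
                  nrow(omics$rna)))
  invisible(stage_record("simulate", nrow(spots), nrow(spots), 0L))
}

#' Normalize stage: spot table to normalized signals and signal matrix
#'
#' @param dir run directory holding \code{spots.tsv} and \code{manifest.tsv}.
#' @param threshold detection threshold (strict >, default 0.5).
#' @return Stage record, invisibly.
#' @export
secmap_normalize <- function(dir, threshold = 0.5) {
  p <- run_paths(dir)
  spots <- read_spot_table(p$spots)
  manifest <- read_tsv_checked(p$manifest, c("antibody_id", "protein_id"))
  norm <- normalize_spots(spots)
  detection <- detection_calls(norm, manifest, threshold)
  fsm <- build_signal_matrix(norm, manifest, detection, threshold)
  write_tsv(norm$signals, p$signals)
  write_tsv(detection, p$detection)
  long <- as.data.frame.table(unclass(fsm), stringsAsFactors = FALSE)
  names(long) <- c("protein_id", "fraction_id", "protocol_id", "signal")
  long$fraction_id <- as.integer(long$fraction_id)
  write_tsv(long, p$matrix)
  n_sig <- nrow(norm$signals)
  excluded <- nrow(spots) - n_sig
  flags <- if (length(norm$failed_subarrays)) {
    sprintf("failed_subarray:%s", norm$failed_subarrays)
  } else character(0)
  message(sprintf("[normalize] %d spots -> %d signals (%d excluded; %d failed subarrays)",
                  nrow(spots), n_sig, excluded, length(norm$failed_subarrays)))
  invisible(stage_record("normalize", nrow(spots), n_sig, excluded, flags))
}

read_signal_matrix <- function(path) {
  long <- read_tsv_checked(path, c("protein_id", "fraction_id", "protocol_id",
                                   "signal"))
  proteins <- sort(unique(long$protein_id))
  fractions <- sort(unique(long$fraction_id))
  chans <- sort(unique(long$protocol_id))
  arr <- array(0, dim = c(length(proteins), length(fractions), length(chans)),
               dimnames = list(proteins, fractions, chans))
  arr[cbind(match(long$protein_id, proteins),
            match(long$fraction_id, fractions),
            match(long$protocol_id, chans))] <- long$signal
  class(arr) <- "fraction_signal_matrix"
  arr
}

#' Classify stage: state calls and co-complex candidate pairs
#'
#' @param dir run directory holding \code{signal_matrix.tsv} and
#'   \code{proteins.tsv} (needs \code{protein_id} and
#'   \code{theoretical_mw} or \code{theoretical_fraction}).
#' @param scheme fraction scheme name or object.
#' @param peak_threshold relative peak threshold.
#' @return Stage record, invisibly.
#' @export
secmap_classify <- function(dir, scheme = "8-range", peak_threshold = 0.5) {
  p <- run_paths(dir)
  fsm <- read_signal_matrix(p$matrix)
  proteins <- read_tsv_checked(p$proteins, c("protein_id"))
  states <- call_states(fsm, proteins, as_fraction_scheme(scheme),
                        peak_threshold)
  pairs <- co_complex_candidates(states)
  write_tsv(states, p$states)
  write_tsv(pairs, p$pairs)
  n_nd <- sum(states$state == "not_detected")
  message(sprintf("[classify] %d protein x channel calls (%d not_detected), %d candidate pairs",
                  nrow(states), n_nd, nrow(pairs)))
  invisible(stage_record("classify", nrow(states), nrow(states), 0L))
}

#' Integrate stage: merge SEC-MAP, LC-MS/MS and RNA-seq evidence
#'
#' @param dir run directory holding \code{signal_matrix.tsv},
#'   \code{detection.tsv}, \code{manifest.tsv}, \code{msms.tsv},
#'   \code{rna.tsv}.
#' @param outlier_z robust-fit outlier cutoff.
#' @return Stage record, invisibly.
#' @export
secmap_integrate <- function(dir, outlier_z = 3) {
  p <- run_paths(dir)
  fsm <- read_signal_matrix(p$matrix)
  detection <- read_tsv_checked(p$detection, c("protein_id", "protocol_id",
                                               "detected"))
  manifest <- read_tsv_checked(p$manifest, c("antibody_id", "protein_id"))
  omics <- read_omics_tables(p$msms, p$rna)
  qas <- qas_values(fsm)
  merged <- merge_omics(qas, omics$msms, omics$rna, outlier_z)
  detected <- unique(detection$protein_id[as.logical(detection$detected)])
  report <- compile_overlap_report(
    secmap_detected = detected,
    msms_detected = omics$msms$protein_id[omics$msms$peptide_count >= 1],
    rna_detected = unique(omics$rna$protein_id[omics$rna$fpkm > 0]),
    panel = unique(manifest$protein_id))
  write_tsv(merged, p$merged)
  jsonlite::write_json(list(sizes = as.list(report$sizes),
                            pairwise = report$pairwise,
                            venn = as.list(report$venn)),
                       p$overlap, auto_unbox = TRUE, digits = NA)
  n_in <- length(unique(c(names(qas), omics$msms$protein_id,
                          omics$rna$protein_id)))
  flags <- if (any(merged$fpkm_tie)) {
    sprintf("fpkm_tie:%s", merged$protein_id[merged$fpkm_tie])
  } else character(0)
  message(sprintf("[integrate] %d proteins merged; %d fully observed",
                  nrow(merged), sum(merged$fully_observed)))
  invisible(stage_record("integrate", n_in, nrow(merged), 0L, flags))
}

#' Run the whole pipeline deterministically under one seed
#'
#' Chains simulate, normalize, classify and integrate inside \code{dir} and
#' writes \code{run_report.json} with per-stage record counts and QC flags.
#' A fixed config (seed included) produces byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param dir run directory.
#' @param peak_threshold,detection_threshold,outlier_z stage thresholds.
#' @return The run report (list), invisibly.
#' @export
secmap_run <- function(config, dir, detection_threshold = 0.5,
                       peak_threshold = 0.5, outlier_z = 3) {
  stages <- list(
    secmap_simulate(config, dir),
    secmap_normalize(dir, detection_threshold),
    secmap_classify(dir, config$scheme, peak_threshold),
    secmap_integrate(dir, outlier_z)
  )
  report <- list(package_version = as.character(utils::packageVersion("secmapr")),
                 seed = config$seed,
                 scheme = if (is.character(config$scheme)) config$scheme else "custom",
                 stages = stages)
  jsonlite::write_json(report, run_paths(dir)$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
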