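#' Simulation configuration
#'
#' Bundles every knob of the forward simulator. Defaults describe the study
#' conditions emulated throughout the package: a 162-protein panel probed by
#' 205 antibodies, 10 multi-protein complexes, 5 replicate spots per antibody
#' per subarray, and array noise typical of fluorescence readouts.
#'
#' @param n_proteins number of proteins in the panel (default 162).
#' @param n_complexes number of multi-protein complexes (default 10).
#' @param n_antibodies total antibodies across the panel (default 205); every
#'   protein receives at least one.
#' @param seed integer RNG seed; a fixed seed makes every simulator output
#'   bit-reproducible.
#' @param protocols extraction protocols to simulate, a subset of
#'   \code{"#1"}..\code{"#9"}. Protocols #7-#9 yield compartment-resolved
#'   channels.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   spot noise (default 0.2).
#' @param background_level,background_sd additive Gaussian subarray
#'   background (truncated at 0), in fluorescence a.u.
#' @param biotin_control_level intensity of the biotin positive-control
#'   spots, the normalization denominator.
#' @param mm_background_level assay background contributed by the MasterMix
#'   itself (present in every sample-carrying spot and in MM-only spots).
#' @param n_replicate_spots replicate spots per antibody per subarray
#'   (default 5).
#' @param n_mm_lots number of MasterMix lots the antibodies are printed from.
#' @param abundance_lognormal_params,lfq_lognormal_params,fpkm_lognormal_params
#'   \code{c(meanlog, sdlog)} of the respective lognormal marginals.
#' @param rho_abundance_fpkm target correlation between log LFQ and log FPKM
#'   in \code{[-1, 1]} (default 0.6, typical of proteome-transcriptome
#'   comparisons).
#' @param peak_sd chromatographic spread: SD of the Gaussian elution peak in
#'   collected-fraction units (default 0.6).
#' @param multi_gene_rate share of proteins mapped to a second gene id.
#' @param zero_peptide_rate,zero_fpkm_rate share of proteins forced to
#'   peptide count 0 / FPKM 0, exercising the fully-observed logic.
#' @param p_complexed_partial probability that a complex member keeps a 0.5
#'   monomer share (otherwise fully complexed).
#' @param p_degraded probability that an eligible protein carries a degraded
#'   (hydrolyzed) species.
#' @param scheme fraction scheme name or object (default \code{"8-range"}).
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_proteins = 162L,
                       n_complexes = 10L,
                       n_antibodies = 205L,
                       seed = 1L,
                       protocols = c("#1", "#8"),
                       noise_cv = 0.2,
                       background_level = 200,
                       background_sd = 20,
                       biotin_control_level = 30000,
                       mm_background_level = 500,
                       n_replicate_spots = 5L,
                       n_mm_lots = 4L,
                       abundance_lognormal_params = c(meanlog = log(2e4), sdlog = 0.6),
                       lfq_lognormal_params = c(meanlog = log(1e7), sdlog = 1.5),
                       fpkm_lognormal_params = c(meanlog = log(10), sdlog = 1.5),
                       rho_abundance_fpkm = 0.6,
                       peak_sd = 0.6,
                       multi_gene_rate = 0.1,
                       zero_peptide_rate = 0.05,
                       zero_fpkm_rate = 0.03,
                       p_complexed_partial = 0.4,
                       p_degraded = 0.3,
                       scheme = "8-range") {
  if (!is_count(n_proteins) || n_proteins < 1) {
    secmap_stop("secmap_config_error", "n_proteins must be a positive integer")
  }
  if (!is_count(n_complexes)) {
    secmap_stop("secmap_config_error", "n_complexes must be a nonnegative integer")
  }
  if (!is_count(n_antibodies) || n_antibodies < n_proteins) {
    secmap_stop("secmap_config_error",
                "n_antibodies must be an integer >= n_proteins (every protein needs one)")
  }
  if (!is_count(abs(seed))) {
    secmap_stop("secmap_config_error", "seed must be an integer")
  }
  known <- names(protocol_models())
  if (!all(protocols %in% known)) {
    secmap_stop("secmap_config_error",
                sprintf("unknown protocol(s): %s",
                        paste(setdiff(protocols, known), collapse = ", ")))
  }
  for (nm in c("noise_cv", "background_level", "background_sd",
               "biotin_control_level", "mm_background_level", "peak_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      secmap_stop("secmap_config_error",
                  sprintf("'%s' must be a single nonnegative number", nm))
    }
  }
  if (biotin_control_level <= 0 || peak_sd <= 0) {
    secmap_stop("secmap_config_error",
                "biotin_control_level and peak_sd must be > 0")
  }
  if (!is.numeric(rho_abundance_fpkm) || length(rho_abundance_fpkm) != 1L ||
      rho_abundance_fpkm < -1 || rho_abundance_fpkm > 1) {
    secmap_stop("secmap_config_error", "rho_abundance_fpkm must be in [-1, 1]")
  }
  if (!is_count(n_replicate_spots) || n_replicate_spots < 1) {
    secmap_stop("secmap_config_error", "n_replicate_spots must be >= 1")
  }
  if (!is_count(n_mm_lots) || n_mm_lots < 1) {
    secmap_stop("secmap_config_error", "n_mm_lots must be >= 1")
  }
  for (nm in c("multi_gene_rate", "zero_peptide_rate", "zero_fpkm_rate",
               "p_complexed_partial", "p_degraded")) {
    stopifnot_scalar_prob(get(nm), nm)
  }
  for (nm in c("abundance_lognormal_params", "lfq_lognormal_params",
               "fpkm_lognormal_params")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v)) || v[2L] < 0) {
      secmap_stop("secmap_config_error",
                  sprintf("'%s' must be c(meanlog, sdlog) with sdlog >= 0", nm))
    }
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_complexes = as.integer(n_complexes),
         n_antibodies = as.integer(n_antibodies),
         seed = as.integer(seed),
         protocols = protocols,
         noise_cv = noise_cv,
         background_level = background_level,
         background_sd = background_sd,
         biotin_control_level = biotin_control_level,
         mm_background_level = mm_background_level,
         n_replicate_spots = as.integer(n_replicate_spots),
         n_mm_lots = as.integer(n_mm_lots),
         abundance_lognormal_params = abundance_lognormal_params,
         lfq_lognormal_params = lfq_lognormal_params,
         fpkm_lognormal_params = fpkm_lognormal_params,
         rho_abundance_fpkm = rho_abundance_fpkm,
         peak_sd = peak_sd,
         multi_gene_rate = multi_gene_rate,
         zero_peptide_rate = zero_peptide_rate,
         zero_fpkm_rate = zero_fpkm_rate,
         p_complexed_partial = p_complexed_partial,
         p_degraded = p_degraded,
         scheme = scheme),
    class = "sim_config"
  )
}

#' Extraction protocol models
#'
#' Models the nine lysis-buffer procedures as per-compartment extraction
#' efficiencies, a biotin-labeling efficiency (urea-containing buffers #2 and
#' #3 are penalized because urea interferes with NHS-biotin conjugation), and
#' whether the protocol resolves subcellular fractions (#7 yields Cyt and
#' Mem; #8 and #9 yield all four compartments).
#'
#' @return Named list of protocol models; each has \code{protocol_id},
#'   \code{extraction_efficiency} (named vector over Cyt, Mem, Org, Nuc),
#'   \code{labeling_efficiency} and \code{yields_subfractions}.
#' @export
protocol_models <- function() {
  eff <- function(cyt, mem, org, nuc) c(Cyt = cyt, Mem = mem, Org = org, Nuc = nuc)
  mk <- function(id, efficiency, labeling, sub = FALSE) {
    list(protocol_id = id,
         extraction_efficiency = efficiency,
         labeling_efficiency = labeling,
         yields_subfractions = sub)
  }
  list(
    "#1" = mk("#1", eff(0.95, 0.85, 0.85, 0.90), 0.95),
    "#2" = mk("#2", eff(0.85, 0.80, 0.80, 0.85), 0.35),  # 9 M urea
    "#3" = mk("#3", eff(0.85, 0.80, 0.80, 0.85), 0.30),  # 7 M urea + thiourea
    "#4" = mk("#4", eff(0.60, 0.50, 0.55, 0.55), 0.95),
    "#5" = mk("#5", eff(0.70, 0.95, 0.70, 0.70), 0.95),
    "#6" = mk("#6", eff(0.55, 0.50, 0.55, 0.55), 0.95),
    "#7" = mk("#7", eff(0.85, 0.80, 0.00, 0.00), 0.95, sub = TRUE),
    "#8" = mk("#8", eff(0.85, 0.75, 0.80, 0.80), 0.95, sub = TRUE),
    "#9" = mk("#9", eff(0.85, 0.70, 0.75, 0.80), 0.95, sub = TRUE)
  )
}

#' Channels measured by a set of protocols
#'
#' Total-lysate protocols contribute one channel named after the protocol;
#' subcellular protocols contribute one channel per compartment with nonzero
#' extraction efficiency, named \code{"#8/Cyt"} etc.
#' @param protocols character vector of protocol ids.
#' @return Data frame with columns \code{channel}, \code{protocol_id},
#'   \code{compartment} (NA for total lysates).
#' @export
protocol_channels <- function(protocols) {
  models <- protocol_models()
  rows <- lapply(protocols, function(p) {
    m <- models[[p]]
    if (m$yields_subfractions) {
      comps <- names(m$extraction_efficiency)[m$extraction_efficiency > 0]
      data.frame(channel = paste(p, comps, sep = "/"),
                 protocol_id = p, compartment = comps)
    } else {
      data.frame(channel = p, protocol_id = p, compartment = NA_character_)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "secmapr simulation config: %d proteins, %d complexes, %d antibodies\n",
    x$n_proteins, x$n_complexes, x$n_antibodies))
  cat(sprintf("protocols: %s; noise_cv = %g; seed = %d\n",
              paste(x$protocols, collapse = ", "), x$noise_cv, x$seed))
  invisible(x)
}
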