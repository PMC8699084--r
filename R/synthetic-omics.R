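#' Simulate LC-MS/MS and RNA-seq summary tables
#'
#' Generates a label-free quantification (LFQ) table and an RNA-seq FPKM
#' table whose log values carry a requested cross-correlation. Log LFQ is a
#' monotone transform of the simulated protein abundance; log FPKM is drawn
#' as \code{rho * z + sqrt(1 - rho^2) * noise} around the standardized log
#' abundance, so the empirical correlation of log LFQ with log FPKM
#' approaches \code{rho_abundance_fpkm}. Per-compartment LFQ splits the total
#' across the protein's true localizations. A configurable share of proteins
#' is mapped to a second gene id (with lower FPKM, exercising the
#' highest-FPKM selection rule) and small shares are forced to peptide count
#' 0 / FPKM 0 to exercise the fully-observed logic.
#'
#' @param truth a [generate_proteome()] result.
#' @param config a [sim_config()]; defaults to the one stored in \code{truth}.
#' @return List with data frames \code{msms} (\code{protein_id},
#'   \code{peptide_count}, \code{lfq_cyt}, \code{lfq_mem}, \code{lfq_org},
#'   \code{lfq_nuc}) and \code{rna} (\code{gene_id}, \code{protein_id},
#'   \code{fpkm}).
#' @export
simulate_omics <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "secmap_truth"))
  rho <- config$rho_abundance_fpkm
  if (rho < -1 || rho > 1) {
    secmap_stop("secmap_config_error", "rho_abundance_fpkm must be in [-1, 1]")
  }
  withr::with_seed(config$seed + 2L, {
    pr <- truth$proteins
    n <- nrow(pr)
    z <- as.numeric(scale(log(pr$abundance)))
    if (anyNA(z)) z <- rep(0, n)  # single-protein degenerate case

    lfq_total <- exp(config$lfq_lognormal_params[1L] +
                       config$lfq_lognormal_params[2L] * z)
    z_fpkm <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    fpkm <- exp(config$fpkm_lognormal_params[1L] +
                  config$fpkm_lognormal_params[2L] * z_fpkm)

    peptide_count <- stats::rpois(n, lambda = 8 * exp(0.6 * z))
    peptide_count[stats::runif(n) < config$zero_peptide_rate] <- 0L
    fpkm[stats::runif(n) < config$zero_fpkm_rate] <- 0

    # split total LFQ across true localizations (jittered proportions)
    comps <- c("Cyt", "Mem", "Org", "Nuc")
    lfq <- matrix(0, n, 4L, dimnames = list(NULL, comps))
    loc_list <- strsplit(pr$localizations, ";", fixed = TRUE)
    for (i in seq_len(n)) {
      locs <- loc_list[[i]]
      w <- stats::runif(length(locs), 0.5, 1.5)
      lfq[i, locs] <- lfq_total[i] * w / sum(w)
    }
    msms <- data.frame(protein_id = pr$protein_id,
                       peptide_count = peptide_count,
                       lfq_cyt = lfq[, "Cyt"], lfq_mem = lfq[, "Mem"],
                       lfq_org = lfq[, "Org"], lfq_nuc = lfq[, "Nuc"])

    rna <- data.frame(gene_id = sprintf("ENSG%08d", seq_len(n)),
                      protein_id = pr$protein_id,
                      fpkm = fpkm)
    extra <- which(stats::runif(n) < config$multi_gene_rate)
    if (length(extra)) {
      rna2 <- data.frame(
        gene_id = sprintf("ENSG%08d", n + extra),
        protein_id = pr$protein_id[extra],
        fpkm = fpkm[extra] * stats::runif(length(extra), 0.1, 0.9))
      rna <- rbind(rna, rna2)
    }
    list(msms = msms, rna = rna)
  })
}
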