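#' Simulate a ground-truth proteome, complexes and antibody panel
#'
#' Forward-simulates the truth tables every downstream stage is validated
#' against: proteins with known MW, subcellular localizations, abundance and
#' assembly state (monomer / complexed / hydrolyzed shares); multi-protein
#' complexes; and an antibody panel where every protein is targeted by at
#' least one antibody.
#'
#' Complex membership is restricted to proteins whose theoretical fraction is
#' 3 or higher, with the complex MW placed in the top range, so a complexed
#' species always pools at least two merged fractions above (numerically
#' smaller than) its members' theoretical fractions. Likewise the degraded
#' species MW is drawn from \code{[11, min(0.5 MW, top of the range two
#' fractions below)]} so hydrolysis products stay resolvable from the
#' monomer after pooling. Species shares are 1 or 0.5, so under zero noise
#' every true species survives the relative peak threshold and state
#' recovery is exact by construction.
#'
#' @param config a [sim_config()].
#' @return List of class \code{secmap_truth} with data frames
#'   \code{proteins}, \code{complexes}, \code{antibodies}.
#' @export
generate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  scheme <- as_fraction_scheme(config$scheme)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    protein_id <- sprintf("PROT%04d", seq_len(n))
    theoretical_mw <- 10^stats::runif(n, log10(12), log10(460))
    theoretical_fraction <- assign_theoretical_fraction(theoretical_mw, scheme,
                                                        warn = FALSE)
    compartments <- c("Cyt", "Mem", "Org", "Nuc")
    n_loc <- sample(1:4, n, replace = TRUE, prob = c(0.50, 0.30, 0.15, 0.05))
    localizations <- vapply(n_loc, function(k) {
      paste(compartments[sort(sample.int(4L, k))], collapse = ";")
    }, character(1))
    abundance <- stats::rlnorm(n, config$abundance_lognormal_params[1L],
                               config$abundance_lognormal_params[2L])

    # -- complexes: members need theoretical fraction >= 2 so that the
    #    complex (top MW range -> merged fraction 1) sits strictly above them
    complex_id <- rep(NA_character_, n)
    complexed_fraction <- numeric(n)
    complexes <- data.frame(complex_id = character(0), members = character(0),
                            complex_mw = numeric(0))
    if (config$n_complexes > 0) {
      eligible <- which(theoretical_fraction >= 3L)
      cx_rows <- vector("list", config$n_complexes)
      for (j in seq_len(config$n_complexes)) {
        if (length(eligible) < 2L) {
          secmap_stop("secmap_config_error",
                      "not enough small proteins left to form the requested complexes")
        }
        size <- min(sample(2:4, 1L), length(eligible))
        members <- sample(eligible, size)
        eligible <- setdiff(eligible, members)
        cid <- sprintf("CPLX%02d", j)
        complex_id[members] <- cid
        complexed_fraction[members] <-
          ifelse(stats::runif(size) < config$p_complexed_partial, 0.5, 1)
        mw_cx <- min(max(sum(theoretical_mw[members]), 166), 473)
        cx_rows[[j]] <- data.frame(
          complex_id = cid,
          members = paste(protein_id[sort(members)], collapse = ";"),
          complex_mw = mw_cx)
      }
      complexes <- do.call(rbind, cx_rows)
    }

    # -- degradation: needs headroom below the theoretical fraction
    n_frac <- nrow(scheme)
    degraded_fraction <- numeric(n)
    degraded_mw <- rep(NA_real_, n)
    can_degrade <- theoretical_fraction <= n_frac - 2L &
      0.5 * theoretical_mw > scheme$mw_low[n_frac] &
      complexed_fraction < 1
    pick <- can_degrade & stats::runif(n) < config$p_degraded
    for (i in which(pick)) {
      degraded_fraction[i] <- if (complexed_fraction[i] > 0) 0.5 else
        sample(c(1, 0.5), 1L, prob = c(0.3, 0.7))
      # two merged fractions below the theoretical one, so the degraded
      # peak is resolvable from the monomer peak after pooling
      upper <- min(0.5 * theoretical_mw[i],
                   scheme$mw_high[theoretical_fraction[i] + 2L])
      degraded_mw[i] <- stats::runif(1L, scheme$mw_low[n_frac], upper)
    }
    monomer_fraction <- 1 - complexed_fraction - degraded_fraction
    stopifnot(all(monomer_fraction > -1e-12))
    monomer_fraction <- pmax(monomer_fraction, 0)

    parts <- cbind(monomer = monomer_fraction > 0,
                   complexed = complexed_fraction > 0,
                   hydrolyzed = degraded_fraction > 0)
    true_state <- apply(parts, 1L, function(p) {
      if (all(p)) "mixed" else paste(colnames(parts)[p], collapse = "+")
    })

    proteins <- data.frame(
      protein_id = protein_id,
      theoretical_mw = theoretical_mw,
      theoretical_fraction = as.integer(theoretical_fraction),
      localizations = localizations,
      abundance = abundance,
      complex_id = complex_id,
      complexed_fraction = complexed_fraction,
      degraded_fraction = degraded_fraction,
      degraded_mw = degraded_mw,
      monomer_fraction = monomer_fraction,
      true_state = true_state
    )

    # -- antibody panel: one antibody per protein, extras spread at random
    n_ab <- config$n_antibodies
    target_idx <- c(seq_len(n),
                    sample.int(n, n_ab - n, replace = n_ab - n > n))
    antibodies <- data.frame(
      antibody_id = sprintf("AB%03d", seq_len(n_ab)),
      protein_id = protein_id[target_idx],
      mm_id = sprintf("MM%d", (seq_len(n_ab) - 1L) %% config$n_mm_lots + 1L),
      clone_type = sample(c("monoclonal", "polyclonal"), n_ab,
                          replace = TRUE, prob = c(0.7, 0.3)),
      epitope_class = sample(c("native", "phospho", "isoform"), n_ab,
                             replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      affinity_factor = stats::rlnorm(n_ab, 0, 0.3),
      n_replicate_spots = config$n_replicate_spots
    )

    structure(list(proteins = proteins, complexes = complexes,
                   antibodies = antibodies, config = config),
              class = "secmap_truth")
  })
}

#' @export
print.secmap_truth <- function(x, ...) {
  cat(sprintf(
    "secmapr ground truth: %d proteins (%d in %d complexes), %d antibodies\n",
    nrow(x$proteins), sum(!is.na(x$proteins$complex_id)),
    nrow(x$complexes), nrow(x$antibodies)))
  invisible(x)
}
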