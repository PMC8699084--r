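#' Simulate true SEC elution profiles
#'
#' Places each species (monomer at the protein's MW, complexed at the complex
#' MW, degraded at a low MW) as a Gaussian peak on the 24-collected-fraction
#' axis, discretized by integration over fraction boundaries, and scales each
#' protein's total signal to abundance x extraction efficiency x labeling
#' efficiency for every measured channel. The per-protein kernel is
#' renormalized over the 24 fractions so total signal is conserved.
#'
#' With \code{calibration = NULL} (default) the peak position comes from a
#' scheme-consistent piecewise log-linear mapping, so a species always pools
#' into its theoretical merged fraction; supplying a fitted
#' [fit_calibration()] object uses its log-linear line instead (MWs outside
#' the calibrated range are clamped to the terminal fractions with a
#' warning).
#'
#' @param truth a [generate_proteome()] result.
#' @param config a [sim_config()]; defaults to the one stored in
#'   \code{truth}.
#' @param calibration optional \code{mw_calibration} used to map MW to
#'   elution position.
#' @return Object of class \code{secmap_elution}: list with \code{profiles}
#'   (3-d array protein x 24 collected fractions x channel), \code{channels}
#'   (see [protocol_channels()]) and \code{species} (long table of the
#'   simulated species with MW, position, share).
#' @export
simulate_elution <- function(truth, config = truth$config, calibration = NULL) {
  stopifnot(inherits(truth, "secmap_truth"))
  scheme <- as_fraction_scheme(config$scheme)
  proteins <- truth$proteins
  models <- protocol_models()
  channels <- protocol_channels(config$protocols)

  position_of <- function(mw) {
    if (is.null(calibration)) scheme_elution_position(mw, scheme)
    else predict_position(calibration, mw)
  }

  # species table: one row per (protein, species)
  sp <- list()
  add <- function(pid, kind, mw, share) {
    if (share > 0) sp[[length(sp) + 1L]] <<-
        data.frame(protein_id = pid, species = kind, mw = mw, share = share)
  }
  cx_mw <- stats::setNames(truth$complexes$complex_mw, truth$complexes$complex_id)
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    add(p$protein_id, "monomer", p$theoretical_mw, p$monomer_fraction)
    if (!is.na(p$complex_id)) {
      add(p$protein_id, "complexed", unname(cx_mw[p$complex_id]),
          p$complexed_fraction)
    }
    if (p$degraded_fraction > 0) {
      add(p$protein_id, "hydrolyzed", p$degraded_mw, p$degraded_fraction)
    }
  }
  species <- do.call(rbind, sp)
  species$position <- position_of(species$mw)

  # discretized, renormalized Gaussian kernel per species (rows sum to share)
  edges <- seq(0.5, 24.5, by = 1)
  kmat <- t(vapply(seq_len(nrow(species)), function(j) {
    w <- diff(stats::pnorm(edges, mean = species$position[j], sd = config$peak_sd))
    w / sum(w) * species$share[j]
  }, numeric(24L)))

  # per-protein shape over 24 fractions (shares already partition 1)
  shape <- rowsum(kmat, group = species$protein_id)  # sorted by protein_id
  shape <- shape[proteins$protein_id, , drop = FALSE]

  # channel weights: abundance x extraction x labeling
  loc_list <- strsplit(proteins$localizations, ";", fixed = TRUE)
  weight <- sapply(seq_len(nrow(channels)), function(ci) {
    ch <- channels[ci, ]
    m <- models[[ch$protocol_id]]
    eff <- m$extraction_efficiency
    vapply(seq_len(nrow(proteins)), function(i) {
      locs <- loc_list[[i]]
      sh <- 1 / length(locs)
      e <- if (is.na(ch$compartment)) {
        sum(sh * eff[locs])
      } else if (ch$compartment %in% locs) {
        sh * eff[[ch$compartment]]
      } else 0
      proteins$abundance[i] * e * m$labeling_efficiency
    }, numeric(1))
  })
  weight <- matrix(weight, nrow = nrow(proteins))

  profiles <- array(0, dim = c(nrow(proteins), 24L, nrow(channels)),
                    dimnames = list(proteins$protein_id, NULL, channels$channel))
  for (ci in seq_len(nrow(channels))) {
    profiles[, , ci] <- shape * weight[, ci]
  }

  structure(list(profiles = profiles, channels = channels, species = species,
                 scheme = scheme),
            class = "secmap_elution")
}

#' Pool simulated elution profiles into merged fractions
#'
#' @param elution a [simulate_elution()] result.
#' @param scheme fraction scheme (defaults to the one used for simulation).
#' @return 3-d array protein x merged fraction x channel.
#' @export
merge_elution <- function(elution, scheme = elution$scheme) {
  stopifnot(inherits(elution, "secmap_elution"))
  scheme <- as_fraction_scheme(scheme)
  dims <- dim(elution$profiles)
  out <- array(0, dim = c(dims[1L], nrow(scheme), dims[3L]),
               dimnames = list(dimnames(elution$profiles)[[1L]],
                               scheme$fraction,
                               dimnames(elution$profiles)[[3L]]))
  for (ci in seq_len(dims[3L])) {
    out[, , ci] <- merge_fractions(elution$profiles[, , ci, drop = TRUE], scheme)
  }
  out
}
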