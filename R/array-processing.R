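#' Estimate the subarray background constant
#'
#' The background population of a subarray is its MasterMix-only spots (the
#' antibody-free printing-mix spots). \code{k} is the median of their raw
#' median intensities and \code{two_sigma_k} twice their standard deviation;
#' both enter the background-subtraction formula additively.
#'
#' @param spots data frame of spot records of ONE subarray (columns
#'   \code{delta_median}, \code{is_mm_only}; optionally \code{subarray_id}).
#' @return List with \code{subarray_id}, \code{k}, \code{two_sigma_k},
#'   \code{n_background_spots}.
#' @export
estimate_background <- function(spots) {
  sub_id <- if ("subarray_id" %in% names(spots) && nrow(spots) > 0) {
    spots$subarray_id[1L]
  } else NA_character_
  bg <- spots$delta_median[spots$is_mm_only]
  if (length(bg) < 3L) {
    secmap_stop("secmap_background_error",
                sprintf("subarray '%s' has %d background (MM-only) spots; need >= 3",
                        sub_id, length(bg)))
  }
  sd_bg <- stats::sd(bg)
  list(subarray_id = sub_id,
       k = stats::median(bg),
       two_sigma_k = 2 * sd_bg,
       n_background_spots = length(bg))
}

#' Background-corrected spot intensity
#'
#' \deqn{\tau_i = (\tilde\delta - k) - 2\sigma_k}
#'
#' applied exactly as written; negative values are retained (they flag
#' non-signal and are floored only when the final signal matrix is built).
#'
#' @param delta_median raw median spot intensity (vectorized).
#' @param bg an [estimate_background()] result.
#' @return Numeric tau values.
#' @export
subtract_background <- function(delta_median, bg) {
  (delta_median - bg$k) - bg$two_sigma_k
}

#' MasterMix-corrected spot intensity
#'
#' \deqn{S_i = \tau_i - (\tilde\delta_{MM}^{max} + 0.05\,\tilde\delta_{MM}^{max})}
#'
#' i.e. the maximum of the MasterMix spot medians inflated by 5\% is
#' subtracted. A negative MM maximum is treated as 0 (no MM effect), which
#' keeps \code{s <= tau}.
#'
#' @param tau background-corrected intensities (vectorized).
#' @param mm_medians median intensities of the MasterMix-only spots of the
#'   antibody's MM lot (same correction state as \code{tau}).
#' @return Numeric s values.
#' @export
mm_correct <- function(tau, mm_medians) {
  if (length(mm_medians) < 1L || all(is.na(mm_medians))) {
    secmap_stop("secmap_mm_error", "no MasterMix spots available for correction")
  }
  mm_max <- max(max(mm_medians, na.rm = TRUE), 0)
  tau - (mm_max + mm_max * 0.05)
}

#' Biotin-normalized spot signal
#'
#' Divides the MM-corrected signal by the biotin positive-control reference
#' of the same subarray (the median biotin-control intensity carried through
#' the same two corrections). A non-positive reference is a subarray QC
#' failure.
#'
#' @param s MM-corrected intensities (vectorized).
#' @param biotin_reference positive scalar reference.
#' @return Dimensionless normalized signal.
#' @export
biotin_normalize <- function(s, biotin_reference) {
  if (!is.numeric(biotin_reference) || length(biotin_reference) != 1L ||
      !is.finite(biotin_reference) || biotin_reference <= 0) {
    secmap_stop("secmap_qc_error",
                "biotin reference must be a positive scalar (subarray QC failure)")
  }
  s / biotin_reference
}

#' Normalize a full spot table
#'
#' Runs the three correction steps per subarray: background estimation from
#' the MM-only spots, background subtraction, per-MM-lot MasterMix
#' correction (using the MM spots' background-corrected medians), and biotin
#' normalization. Subarrays whose biotin reference is not positive are
#' excluded and reported in the QC table.
#'
#' @param spots spot table as produced by [simulate_array()] or read with
#'   [read_spot_table()].
#' @return List of class \code{secmap_signals}: \code{signals} (long data
#'   frame with \code{antibody_id}, \code{mm_id}, \code{replicate_index},
#'   \code{fraction_id}, \code{protocol_id}, \code{subarray_id}, \code{tau},
#'   \code{s}, \code{s_norm}), \code{background} (per-subarray k and
#'   2 sigma_k), and \code{failed_subarrays}.
#' @export
normalize_spots <- function(spots) {
  dup <- duplicated(spots[!spots$is_mm_only & !spots$is_biotin_control,
                          c("antibody_id", "fraction_id", "protocol_id",
                            "replicate_index")])
  if (any(dup)) {
    secmap_stop("secmap_integrity_error",
                "duplicate (antibody, fraction, protocol, replicate) spot keys")
  }
  out <- list(); bg_rows <- list(); failed <- character(0)
  for (sub_id in unique(spots$subarray_id)) {
    sub <- spots[spots$subarray_id == sub_id, , drop = FALSE]
    bg <- estimate_background(sub)
    sub$tau <- subtract_background(sub$delta_median, bg)
    mm_tau <- split(sub$tau[sub$is_mm_only], sub$mm_id[sub$is_mm_only])
    sub$s <- NA_real_
    for (lot in names(mm_tau)) {
      idx <- !is.na(sub$mm_id) & sub$mm_id == lot & !sub$is_mm_only
      sub$s[idx] <- mm_correct(sub$tau[idx], mm_tau[[lot]])
    }
    # biotin controls: corrected against the pooled MM spots
    bio_idx <- sub$is_biotin_control
    if (!any(bio_idx)) {
      secmap_stop("secmap_schema_error",
                  sprintf("subarray '%s' has no biotin control spots", sub_id))
    }
    sub$s[bio_idx] <- mm_correct(sub$tau[bio_idx], sub$tau[sub$is_mm_only])
    biotin_ref <- stats::median(sub$s[bio_idx])
    bg_rows[[sub_id]] <- data.frame(subarray_id = sub_id, k = bg$k,
                                    two_sigma_k = bg$two_sigma_k,
                                    biotin_reference = biotin_ref)
    if (!is.finite(biotin_ref) || biotin_ref <= 0) {
      failed <- c(failed, sub_id)
      next
    }
    keep <- !sub$is_mm_only & !sub$is_biotin_control
    sig <- sub[keep, c("antibody_id", "mm_id", "replicate_index",
                       "fraction_id", "protocol_id", "subarray_id",
                       "tau", "s")]
    sig$s_norm <- biotin_normalize(sig$s, biotin_ref)
    out[[sub_id]] <- sig
  }
  signals <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(signals)) rownames(signals) <- NULL
  structure(list(signals = signals,
                 background = do.call(rbind, c(bg_rows, list(make.row.names = FALSE))),
                 failed_subarrays = failed),
            class = "secmap_signals")
}

#' Detection call from per-antibody signals
#'
#' An antibody "displays signal" when its replicate-median normalized signal
#' is > 0; a protein is detected when strictly more than \code{threshold}
#' (default 50\%) of its spotted antibodies display signal.
#'
#' @param antibody_values numeric vector, one replicate-median normalized
#'   signal per antibody of the protein.
#' @param threshold detection threshold on the supporting-antibody fraction
#'   (strict inequality; default 0.5).
#' @return List with \code{detected} and \code{supporting_antibody_fraction}.
#' @export
call_detected <- function(antibody_values, threshold = 0.5) {
  if (length(antibody_values) < 1L) {
    secmap_stop("secmap_panel_error", "protein has no spotted antibodies")
  }
  frac <- mean(antibody_values > 0)
  list(detected = frac > threshold, supporting_antibody_fraction = frac)
}

#' Per-protein detection calls across a normalized signal table
#'
#' Aggregates replicates (median per antibody across fractions' maxima) and
#' applies the strict >50\% spotted-antibody rule per protein and protocol
#' channel.
#'
#' @param normalized a [normalize_spots()] result.
#' @param antibodies panel manifest (columns \code{antibody_id},
#'   \code{protein_id}).
#' @param threshold see [call_detected()].
#' @return Data frame with \code{protein_id}, \code{protocol_id},
#'   \code{detected}, \code{supporting_antibody_fraction}.
#' @export
detection_calls <- function(normalized, antibodies, threshold = 0.5) {
  sig <- normalized$signals
  sig$protein_id <- antibodies$protein_id[match(sig$antibody_id,
                                                antibodies$antibody_id)]
  if (anyNA(sig$protein_id)) {
    secmap_stop("secmap_panel_error",
                "spot table contains antibodies missing from the panel manifest")
  }
  # replicate-median per (antibody, fraction, channel), then per-antibody
  # maximum across fractions: "displays signal" anywhere on the gradient
  med <- stats::aggregate(s_norm ~ antibody_id + protein_id + fraction_id +
                            protocol_id, data = sig, FUN = stats::median)
  ab_max <- stats::aggregate(s_norm ~ antibody_id + protein_id + protocol_id,
                             data = med, FUN = max)
  rows <- list()
  for (key in unique(paste(ab_max$protein_id, ab_max$protocol_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    vals <- ab_max$s_norm[ab_max$protein_id == parts[1L] &
                            ab_max$protocol_id == parts[2L]]
    cd <- call_detected(vals, threshold)
    rows[[key]] <- data.frame(protein_id = parts[1L], protocol_id = parts[2L],
                              detected = cd$detected,
                              supporting_antibody_fraction =
                                cd$supporting_antibody_fraction)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the protein x fraction x protocol signal matrix
#'
#' Entries are the median over a protein's antibodies of the replicate-median
#' normalized signal, floored at 0. Proteins failing the detection filter in
#' a protocol channel are zeroed there.
#'
#' @param normalized a [normalize_spots()] result.
#' @param antibodies panel manifest.
#' @param detection optional [detection_calls()] result used to filter; when
#'   NULL the filter is computed internally.
#' @param threshold detection threshold.
#' @return Object of class \code{fraction_signal_matrix}: 3-d array protein x
#'   fraction x protocol channel with attribute \code{detection}.
#' @export
build_signal_matrix <- function(normalized, antibodies, detection = NULL,
                                threshold = 0.5) {
  if (is.null(detection)) {
    detection <- detection_calls(normalized, antibodies, threshold)
  }
  sig <- normalized$signals
  sig$protein_id <- antibodies$protein_id[match(sig$antibody_id,
                                                antibodies$antibody_id)]
  med <- stats::aggregate(s_norm ~ antibody_id + protein_id + fraction_id +
                            protocol_id, data = sig, FUN = stats::median)
  prot <- stats::aggregate(s_norm ~ protein_id + fraction_id + protocol_id,
                           data = med, FUN = stats::median)
  proteins <- sort(unique(antibodies$protein_id))
  fractions <- sort(unique(sig$fraction_id))
  chans <- sort(unique(sig$protocol_id))
  arr <- array(0, dim = c(length(proteins), length(fractions), length(chans)),
               dimnames = list(proteins, fractions, chans))
  idx <- cbind(match(prot$protein_id, proteins),
               match(prot$fraction_id, fractions),
               match(prot$protocol_id, chans))
  arr[idx] <- pmax(prot$s_norm, 0)
  for (i in seq_len(nrow(detection))) {
    if (!detection$detected[i]) {
      arr[detection$protein_id[i], , detection$protocol_id[i]] <- 0
    }
  }
  structure(arr, detection = detection, class = "fraction_signal_matrix")
}
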