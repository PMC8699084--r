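#' Find elution peaks in a merged fraction profile
#'
#' A fraction is a peak when its signal is at least \code{threshold} times
#' the row maximum and is a local maximum or plateau (not smaller than either
#' neighbour). An all-zero profile has no peaks.
#'
#' @param x nonnegative numeric vector, one value per merged fraction.
#' @param threshold relative peak threshold (default 0.5 of the row maximum).
#' @return Integer vector of peak fraction ids (possibly empty).
#' @export
find_peaks <- function(x, threshold = 0.5) {
  if (any(x < 0)) {
    secmap_stop("secmap_config_error", "fraction profile must be nonnegative")
  }
  m <- max(x)
  if (m <= 0) return(integer(0))
  n <- length(x)
  left <- c(-Inf, x[-n])
  right <- c(x[-1L], -Inf)
  unname(which(x >= threshold * m & x >= left & x >= right & x > 0))
}

#' Classify a protein's assembly state
#'
#' Fraction 1 holds the largest molecular weights, so a peak at a fraction id
#' smaller than the theoretical one means the protein elutes above its
#' monomer MW (complexed); a larger id means below (hydrolyzed); the
#' theoretical fraction itself means the protein is found alone (monomer).
#' Multiple peaks produce compound states; all three kinds together give
#' \code{"mixed"}; no peaks give \code{"not_detected"}.
#'
#' @param peaks integer vector of observed peak fraction ids.
#' @param theoretical theoretical fraction id of the protein's monomer MW.
#' @param n_fractions number of merged fractions (default 8).
#' @return State string, one of \code{monomer}, \code{complexed},
#'   \code{hydrolyzed}, \code{monomer+complexed}, \code{monomer+hydrolyzed},
#'   \code{complexed+hydrolyzed}, \code{mixed}, \code{not_detected}.
#' @export
classify_state <- function(peaks, theoretical, n_fractions = 8L) {
  if (length(theoretical) != 1L || !theoretical %in% seq_len(n_fractions)) {
    secmap_stop("secmap_config_error", "theoretical fraction out of range")
  }
  if (length(peaks) == 0L) return("not_detected")
  if (!all(peaks %in% seq_len(n_fractions))) {
    secmap_stop("secmap_config_error", "peak fraction ids out of range")
  }
  has <- c(monomer = any(peaks == theoretical),
           complexed = any(peaks < theoretical),
           hydrolyzed = any(peaks > theoretical))
  if (all(has)) return("mixed")
  paste(names(has)[has], collapse = "+")
}

#' State calls for every protein and protocol channel
#'
#' Runs [find_peaks()] and [classify_state()] over a
#' [build_signal_matrix()] result.
#'
#' @param fsm a \code{fraction_signal_matrix}.
#' @param proteins data frame with \code{protein_id} and either
#'   \code{theoretical_fraction} or \code{theoretical_mw} (assigned via
#'   \code{scheme}).
#' @param scheme fraction scheme used when only MWs are given.
#' @param peak_threshold relative peak threshold.
#' @return Data frame with \code{protein_id}, \code{protocol_id},
#'   \code{theoretical_fraction}, \code{peaks} (semicolon string) and
#'   \code{state}.
#' @export
call_states <- function(fsm, proteins, scheme = fraction_scheme_8(),
                        peak_threshold = 0.5) {
  scheme <- as_fraction_scheme(scheme)
  if (!"theoretical_fraction" %in% names(proteins)) {
    proteins$theoretical_fraction <-
      assign_theoretical_fraction(proteins$theoretical_mw, scheme, warn = FALSE)
  }
  ids <- dimnames(fsm)[[1L]]
  chans <- dimnames(fsm)[[3L]]
  n_frac <- dim(fsm)[2L]
  th <- proteins$theoretical_fraction[match(ids, proteins$protein_id)]
  if (anyNA(th)) {
    secmap_stop("secmap_panel_error",
                "signal matrix contains proteins missing from the protein table")
  }
  rows <- vector("list", length(ids) * length(chans))
  r <- 0L
  for (ch in chans) {
    for (i in seq_along(ids)) {
      pk <- find_peaks(fsm[i, , ch], peak_threshold)
      r <- r + 1L
      rows[[r]] <- data.frame(
        protein_id = ids[i], protocol_id = ch,
        theoretical_fraction = th[i],
        peaks = paste(pk, collapse = ";"),
        state = classify_state(pk, th[i], n_frac))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate co-complex pairs
#'
#' Two proteins are co-complex candidates when, within the same protocol
#' channel, both show a "complexed" peak (a peak strictly above, i.e. at a
#' smaller fraction id than, their own theoretical fraction) in the same
#' merged fraction.
#'
#' @param states a [call_states()] result.
#' @return Data frame edge list with \code{protein_a}, \code{protein_b}
#'   (lexicographically ordered), \code{protocol_id},
#'   \code{shared_fraction}; one row per (pair, channel, fraction).
#' @export
co_complex_candidates <- function(states) {
  if (nrow(states) < 2L) {
    secmap_stop("secmap_config_error", "need at least 2 classified proteins")
  }
  rows <- list()
  for (ch in unique(states$protocol_id)) {
    st <- states[states$protocol_id == ch, , drop = FALSE]
    cx <- list()
    for (i in seq_len(nrow(st))) {
      if (st$peaks[i] == "") next
      pk <- as.integer(strsplit(st$peaks[i], ";", fixed = TRUE)[[1L]])
      above <- pk[pk < st$theoretical_fraction[i]]
      for (f in above) {
        cx[[length(cx) + 1L]] <- data.frame(protein_id = st$protein_id[i],
                                            fraction = f)
      }
    }
    if (!length(cx)) next
    cx <- do.call(rbind, cx)
    for (f in unique(cx$fraction)) {
      members <- sort(cx$protein_id[cx$fraction == f])
      if (length(members) < 2L) next
      pairs <- utils::combn(members, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = pairs[1L, ], protein_b = pairs[2L, ],
        protocol_id = ch, shared_fraction = f)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      protocol_id = character(0), shared_fraction = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
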