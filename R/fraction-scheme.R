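#' SEC fraction pooling schemes
#'
#' A fraction scheme describes how the 24 collected SEC aliquots are pooled
#' into merged fractions and which molecular-weight (MW) range each merged
#' fraction covers. Fraction 1 elutes first and therefore holds the largest
#' species; MW ranges decrease strictly with fraction id.
#'
#' @param fraction integer ids 1..n, in elution order.
#' @param mw_low,mw_high lower/upper MW bounds (kDa) of each merged fraction.
#' @param pooling integer vector of length 24 mapping each collected fraction
#'   to a merged fraction id; must partition 1..24 so that pooled mass is
#'   conserved.
#' @return An object of class \code{fraction_scheme}: a data frame with
#'   columns \code{fraction}, \code{mw_low}, \code{mw_high} and a
#'   \code{pooling} attribute.
#' @seealso [fraction_scheme_8()], [fraction_scheme_5()],
#'   [merge_fractions()], [assign_theoretical_fraction()]
#' @export
fraction_scheme <- function(fraction, mw_low, mw_high, pooling) {
  n <- length(fraction)
  if (length(mw_low) != n || length(mw_high) != n) {
    secmap_stop("secmap_scheme_error", "fraction/mw_low/mw_high lengths differ")
  }
  if (!identical(as.integer(fraction), seq_len(n))) {
    secmap_stop("secmap_scheme_error", "fraction ids must be 1..n in order")
  }
  if (any(mw_low <= 0) || any(mw_high <= mw_low)) {
    secmap_stop("secmap_scheme_error", "each MW range needs 0 < mw_low < mw_high")
  }
  # ranges must be strictly decreasing and non-overlapping in elution order
  if (n > 1 && any(mw_high[-1] >= mw_low[-n])) {
    secmap_stop("secmap_scheme_error",
                "MW ranges must decrease strictly with fraction id")
  }
  pooling <- as.integer(pooling)
  if (length(pooling) != 24L || anyNA(pooling) ||
      !all(sort(unique(pooling)) == seq_len(n)) ||
      is.unsorted(pooling)) {
    secmap_stop("secmap_scheme_error",
                "pooling must map the 24 collected fractions onto 1..n in order")
  }
  out <- data.frame(fraction = as.integer(fraction),
                    mw_low = as.numeric(mw_low),
                    mw_high = as.numeric(mw_high))
  attr(out, "pooling") <- pooling
  class(out) <- c("fraction_scheme", "data.frame")
  out
}

#' Default 8-range fraction scheme
#'
#' The standard scheme: 24 collected fractions pooled in consecutive triples
#' into 8 merged fractions with MW ranges 166-473, 121-142, 74-103, 54-63,
#' 33-46, 24-28, 17-21 and 11-15 kDa.
#' @return A [fraction_scheme()] with 8 merged fractions.
#' @export
fraction_scheme_8 <- function() {
  fraction_scheme(
    fraction = 1:8,
    mw_low = c(166, 121, 74, 54, 33, 24, 17, 11),
    mw_high = c(473, 142, 103, 63, 46, 28, 21, 15),
    pooling = rep(1:8, each = 3L)
  )
}

#' Alternative 5-range fraction scheme
#'
#' Coarser pooling used when evaluating biotin-conjugation effects across the
#' MW range: 142-437, 74-121, 46-63, 26-39 and 11-24 kDa.
#' @return A [fraction_scheme()] with 5 merged fractions.
#' @export
fraction_scheme_5 <- function() {
  fraction_scheme(
    fraction = 1:5,
    mw_low = c(142, 74, 46, 26, 11),
    mw_high = c(437, 121, 63, 39, 24),
    pooling = rep(1:5, times = c(5L, 5L, 5L, 5L, 4L))
  )
}

#' Resolve a scheme by name
#' @param scheme a \code{fraction_scheme}, or \code{"8-range"} / \code{"5-range"}.
#' @return A \code{fraction_scheme}.
#' @export
as_fraction_scheme <- function(scheme) {
  if (inherits(scheme, "fraction_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) {
    return(switch(scheme,
                  "8-range" = fraction_scheme_8(),
                  "5-range" = fraction_scheme_5(),
                  secmap_stop("secmap_scheme_error",
                              sprintf("unknown fraction scheme '%s'", scheme))))
  }
  secmap_stop("secmap_scheme_error", "not a fraction scheme")
}

#' Pool a 24-fraction elution profile into merged fractions
#'
#' Physical pooling conserves mass: the merged value is the sum of the member
#' collected fractions. Accepts a numeric vector of length 24 or a matrix
#' with 24 columns (rows = proteins).
#'
#' @param profile numeric vector (length 24) or matrix (n x 24), nonnegative
#'   signal per collected fraction.
#' @param scheme a [fraction_scheme()].
#' @return Vector of length n_merged, or matrix n x n_merged.
#' @export
merge_fractions <- function(profile, scheme = fraction_scheme_8()) {
  scheme <- as_fraction_scheme(scheme)
  pooling <- attr(scheme, "pooling")
  if (is.matrix(profile)) {
    if (ncol(profile) != 24L) {
      secmap_stop("secmap_scheme_error", "profile matrix must have 24 columns")
    }
    ind <- outer(pooling, scheme$fraction, `==`) + 0  # 24 x n_merged
    out <- profile %*% ind
    colnames(out) <- scheme$fraction
    return(out)
  }
  if (length(profile) != 24L) {
    secmap_stop("secmap_scheme_error", "profile must have 24 collected fractions")
  }
  as.numeric(rowsum(profile, group = pooling))
}

#' Assign the theoretical MW fraction of a protein
#'
#' Returns the merged fraction whose MW range contains \code{mw}. An MW in a
#' gap between two printed ranges is assigned to the range whose nearest
#' boundary is closest (ties go to the larger-MW fraction). MWs above the top
#' range map to fraction 1, below the bottom range to the last fraction; both
#' raise an out-of-range warning unless \code{warn = FALSE}.
#'
#' @param mw numeric vector of molecular weights (kDa), > 0.
#' @param scheme a [fraction_scheme()].
#' @param warn warn on MWs outside the covered range?
#' @return Integer vector of fraction ids (attribute \code{out_of_range}:
#'   logical vector marking clamped MWs).
#' @export
assign_theoretical_fraction <- function(mw, scheme = fraction_scheme_8(),
                                        warn = TRUE) {
  scheme <- as_fraction_scheme(scheme)
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    secmap_stop("secmap_config_error", "mw must be finite and > 0")
  }
  n <- nrow(scheme)
  out <- integer(length(mw))
  oor <- logical(length(mw))
  for (i in seq_along(mw)) {
    x <- mw[i]
    if (x > scheme$mw_high[1L]) {
      out[i] <- 1L; oor[i] <- TRUE; next
    }
    if (x < scheme$mw_low[n]) {
      out[i] <- n; oor[i] <- TRUE; next
    }
    hit <- which(x >= scheme$mw_low & x <= scheme$mw_high)
    if (length(hit)) {
      out[i] <- hit[1L]
    } else {
      # in the gap between fraction f (above) and f + 1 (below)
      f <- max(which(scheme$mw_low > x))
      d_up <- scheme$mw_low[f] - x
      d_down <- x - scheme$mw_high[f + 1L]
      out[i] <- if (d_up <= d_down) f else f + 1L
    }
  }
  if (warn && any(oor)) {
    warning(sprintf("%d MW value(s) outside the scheme range were clamped",
                    sum(oor)), call. = FALSE)
  }
  attr(out, "out_of_range") <- oor
  out
}

#' Continuous elution position consistent with a fraction scheme
#'
#' Maps an MW to a position on the 1..24 collected-fraction axis such that
#' the species' pooled peak always lands in its theoretical merged fraction:
#' the position interpolates log-linearly inside the span of collected
#' fractions pooled into that merged fraction. Used by the forward simulator
#' when no fitted calibration is supplied.
#' @noRd
scheme_elution_position <- function(mw, scheme = fraction_scheme_8()) {
  scheme <- as_fraction_scheme(scheme)
  pooling <- attr(scheme, "pooling")
  frac <- assign_theoretical_fraction(mw, scheme, warn = FALSE)
  vapply(seq_along(mw), function(i) {
    g <- frac[i]
    idx <- which(pooling == g)
    lo <- log10(scheme$mw_low[g]); hi <- log10(scheme$mw_high[g])
    t <- (hi - log10(mw[i])) / (hi - lo)  # 0 at high-MW edge (elutes first)
    t <- min(max(t, 0), 1)
    # confine to the central +/- 0.5 window of the pooling group so the
    # discretized peak mass stays almost entirely within the group
    (min(idx) + max(idx)) / 2 - 0.5 + t
  }, numeric(1))
}
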