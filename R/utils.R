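# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed secmapr condition
#'
#' All user-facing errors carry a subclass so the CLI can map them to exit
#' codes (missing files vs schema violations vs configuration errors).
#' @noRd
secmap_stop <- function(subclass, msg, ...) {
  cond <- structure(
    class = c(subclass, "secmap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Multiplicative lognormal noise with unit mean
#'
#' cv = 0 returns exactly 1 (no RNG draw side effects are avoided on purpose:
#' the draw is still made so spot layouts stay aligned across noise levels).
#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' @noRd
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    secmap_stop("secmap_config_error",
                sprintf("'%s' must be a single value in [0, 1]", name))
  }
  invisible(x)
}
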