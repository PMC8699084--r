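#' Simulate spot-level antibody microarray readout
#'
#' Each (channel, merged fraction) incubation is one subarray. A subarray
#' carries \code{n_replicate_spots} spots per antibody, MasterMix-only spots
#' per MM lot, and biotin positive-control spots. Raw spot intensity is
#'
#' \deqn{\delta = background + mm\_level + affinity \times signal \times
#'   lognormal(noise\_cv)}
#'
#' with additive Gaussian background truncated at 0 (MM-only spots omit the
#' signal term; biotin controls carry the biotin level instead, with the same
#' multiplicative noise).
#'
#' @param merged 3-d array protein x merged fraction x channel from
#'   [merge_elution()].
#' @param antibodies antibody panel data frame (see [generate_proteome()]).
#' @param config a [sim_config()].
#' @return Data frame of spot records with GenePix-style layout columns
#'   (\code{block}, \code{row}, \code{column}), identity columns
#'   (\code{subarray_id}, \code{antibody_id}, \code{mm_id},
#'   \code{replicate_index}), the raw median intensity \code{delta_median},
#'   the incubation keys (\code{fraction_id}, \code{protocol_id}) and control
#'   flags (\code{is_mm_only}, \code{is_biotin_control}).
#' @export
simulate_array <- function(merged, antibodies, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(merged < 0)) {
    secmap_stop("secmap_config_error", "elution profiles must be nonnegative")
  }
  withr::with_seed(config$seed + 1L, {
    channels <- dimnames(merged)[[3L]]
    fractions <- as.integer(dimnames(merged)[[2L]])
    n_rep <- config$n_replicate_spots
    mm_lots <- sort(unique(antibodies$mm_id))

    blocks <- list()
    block_no <- 0L
    for (ch in channels) {
      for (f in fractions) {
        block_no <- block_no + 1L
        sub_id <- sprintf("%s|F%d", ch, f)
        sig <- merged[antibodies$protein_id, as.character(f), ch]
        ab <- data.frame(
          antibody_id = rep(antibodies$antibody_id, each = n_rep),
          mm_id = rep(antibodies$mm_id, each = n_rep),
          replicate_index = rep(seq_len(n_rep), times = nrow(antibodies)),
          true_signal = rep(antibodies$affinity_factor * sig, each = n_rep),
          is_mm_only = FALSE, is_biotin_control = FALSE
        )
        mm <- data.frame(
          antibody_id = NA_character_,
          mm_id = rep(mm_lots, each = n_rep),
          replicate_index = rep(seq_len(n_rep), times = length(mm_lots)),
          true_signal = 0,
          is_mm_only = TRUE, is_biotin_control = FALSE
        )
        bio <- data.frame(
          antibody_id = NA_character_,
          mm_id = NA_character_,
          replicate_index = seq_len(n_rep),
          true_signal = 0,
          is_mm_only = FALSE, is_biotin_control = TRUE
        )
        spots <- rbind(ab, mm, bio)
        n_spot <- nrow(spots)
        bg <- pmax(stats::rnorm(n_spot, config$background_level,
                                config$background_sd), 0)
        noise <- lognormal_noise(n_spot, config$noise_cv)
        delta <- bg +
          ifelse(spots$is_biotin_control, config$biotin_control_level * noise,
                 config$mm_background_level + spots$true_signal * noise)
        n_col <- 20L
        spots$subarray_id <- sub_id
        spots$block <- block_no
        spots$row <- (seq_len(n_spot) - 1L) %/% n_col + 1L
        spots$column <- (seq_len(n_spot) - 1L) %% n_col + 1L
        spots$delta_median <- delta
        spots$fraction_id <- f
        spots$protocol_id <- ch
        blocks[[block_no]] <- spots
      }
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out[, c("subarray_id", "block", "row", "column", "antibody_id", "mm_id",
            "replicate_index", "delta_median", "fraction_id", "protocol_id",
            "is_mm_only", "is_biotin_control")]
  })
}
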