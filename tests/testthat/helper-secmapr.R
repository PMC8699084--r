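# Shared fixture builders; everything is generated in code at test time.

tiny_config <- function(..., protocols = "#1") {
  sim_config(n_proteins = 20L, n_complexes = 2L, n_antibodies = 25L,
             seed = 42L, protocols = protocols, ...)
}

# Run simulator -> array -> normalization -> state calls; returns all stages.
run_truth_pipeline <- function(cfg) {
  truth <- generate_proteome(cfg)
  elution <- simulate_elution(truth)
  merged <- merge_elution(elution)
  spots <- simulate_array(merged, truth$antibodies, cfg)
  norm <- normalize_spots(spots)
  fsm <- build_signal_matrix(norm, truth$antibodies)
  states <- call_states(fsm, truth$proteins, cfg$scheme)
  list(truth = truth, elution = elution, merged = merged, spots = spots,
       norm = norm, fsm = fsm, states = states)
}

state_accuracy <- function(truth, states) {
  called <- states$state[match(truth$proteins$protein_id, states$protein_id)]
  mean(called == truth$proteins$true_state)
}

# Build one hand-crafted subarray: n_ab antibodies (s_norm targets given as
# multiples of the biotin level), MM-only and biotin-control spots.
make_subarray <- function(ab_values, k = 500, biotin = 1000,
                          subarray_id = "T|F1", mm_id = "MM1",
                          antibody_ids = sprintf("AB%02d", seq_along(ab_values)),
                          replicate_index = rep(1L, length(ab_values))) {
  ab <- data.frame(
    subarray_id = subarray_id, antibody_id = antibody_ids, mm_id = mm_id,
    replicate_index = replicate_index,
    delta_median = k + ab_values * biotin,
    fraction_id = 1L, protocol_id = "T",
    is_mm_only = FALSE, is_biotin_control = FALSE)
  ctrl <- data.frame(
    subarray_id = subarray_id,
    antibody_id = NA_character_,
    mm_id = c(rep(mm_id, 3L), rep(NA_character_, 3L)),
    replicate_index = 1:3,
    delta_median = c(rep(k, 3L), rep(k + biotin, 3L)),
    fraction_id = 1L, protocol_id = "T",
    is_mm_only = rep(c(TRUE, FALSE), each = 3L),
    is_biotin_control = rep(c(FALSE, TRUE), each = 3L))
  rbind(ab, ctrl)
}
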