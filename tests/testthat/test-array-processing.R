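test_that("subarray background is the median and twice the SD of MM-only spots", {
  mk <- function(vals) data.frame(subarray_id = rep("S1", length(vals)),
                                  delta_median = vals,
                                  is_mm_only = rep(TRUE, length(vals)))
  bg <- estimate_background(mk(c(200, 200, 200)))
  expect_equal(bg$k, 200)
  expect_equal(bg$two_sigma_k, 0)
  bg <- estimate_background(mk(c(100, 200, 300)))
  expect_equal(bg$k, 200)
  expect_equal(bg$two_sigma_k, 200)  # SD of {100,200,300} is 100
  expect_error(estimate_background(mk(numeric(0))),
               class = "secmap_background_error")
  expect_error(estimate_background(mk(c(1, 2))),
               class = "secmap_background_error")
})

test_that("background and MasterMix corrections follow the printed formulas", {
  bg <- list(k = 200, two_sigma_k = 100)
  expect_equal(subtract_background(1000, bg), 700)
  expect_equal(subtract_background(300, bg), 0)
  expect_equal(subtract_background(0, list(k = 50, two_sigma_k = 10)), -60)
  expect_equal(mm_correct(500, c(300, 400)), 500 - 1.05 * 400)
  expect_equal(mm_correct(1.05 * 400, 400), 0)
  expect_equal(mm_correct(100, 400), -320)
  expect_error(mm_correct(100, numeric(0)), class = "secmap_mm_error")
  # biotin normalization: plain ratio, positive reference enforced
  expect_equal(biotin_normalize(80, 160), 0.5)
  expect_equal(biotin_normalize(0, 160), 0)
  expect_error(biotin_normalize(10, 0), class = "secmap_qc_error")
})

test_that("both correction formulas match an independent arithmetic oracle", {
  set.seed(101)
  for (i in 1:20) {
    delta <- runif(50, 0, 5000)
    k <- runif(1, 0, 500); two_sigma <- runif(1, 0, 200)
    mm <- runif(5, 0, 800)
    tau <- subtract_background(delta, list(k = k, two_sigma_k = two_sigma))
    s <- mm_correct(tau, mm)
    tau_oracle <- delta - k - two_sigma
    s_oracle <- tau_oracle - (max(mm) + max(mm) * 0.05)
    expect_equal(tau, tau_oracle, tolerance = 1e-12)
    expect_equal(s, s_oracle, tolerance = 1e-12)
  }
})

test_that("detection needs strictly more than half of the spotted antibodies", {
  expect_true(call_detected(c(1, 2, 0))$detected)        # 2 of 3
  expect_false(call_detected(c(1, 0))$detected)          # exactly half
  expect_false(call_detected(c(0))$detected)
  expect_equal(call_detected(c(1, 2, 0))$supporting_antibody_fraction, 2 / 3)
  expect_error(call_detected(numeric(0)), class = "secmap_panel_error")
  # monotonicity: appending a positive antibody never un-detects
  set.seed(7)
  for (i in 1:50) {
    vals <- rnorm(sample(1:6, 1))
    if (call_detected(vals)$detected) {
      expect_true(call_detected(c(vals, 1))$detected)
    }
  }
})

test_that("normalization of a crafted subarray recovers the planted signals", {
  spots <- make_subarray(c(0.5, 0, -0.1), k = 500, biotin = 1000)
  norm <- normalize_spots(spots)
  expect_length(norm$failed_subarrays, 0)
  expect_equal(norm$signals$s_norm, c(0.5, 0, -0.1), tolerance = 1e-12)
  expect_equal(norm$background$k, 500)
  expect_equal(norm$background$two_sigma_k, 0)
  expect_equal(norm$background$biotin_reference, 1000)
})

test_that("missing biotin controls and duplicate spot keys are rejected", {
  spots <- make_subarray(c(0.5, 0.2))
  no_bio <- spots[!spots$is_biotin_control, ]
  expect_error(normalize_spots(no_bio), "T|F1", fixed = TRUE,
               class = "secmap_schema_error")
  dup <- rbind(spots, spots[1L, ])
  expect_error(normalize_spots(dup), class = "secmap_integrity_error")
})

test_that("the pipeline is scale-equivariant: rescaling all raw intensities leaves s_norm unchanged", {
  cfg <- tiny_config(noise_cv = 0.15)
  sim <- run_truth_pipeline(cfg)
  scaled <- sim$spots
  scaled$delta_median <- scaled$delta_median * 7
  n1 <- normalize_spots(sim$spots)
  n2 <- normalize_spots(scaled)
  expect_equal(n2$signals$s_norm, n1$signals$s_norm, tolerance = 1e-12)
})

test_that("signal matrix entries are antibody medians of replicate medians, floored at 0", {
  # one antibody, five replicate spots with planted s_norm values
  spots <- make_subarray(c(0.1, 0.2, 0.9, 0.2, 0.2),
                         antibody_ids = rep("AB01", 5L),
                         replicate_index = 1:5)
  manifest <- data.frame(antibody_id = "AB01", protein_id = "P1")
  norm <- normalize_spots(spots)
  fsm <- build_signal_matrix(norm, manifest, threshold = 0.4)
  expect_equal(unname(fsm["P1", "1", "T"]), 0.2)
  # all-negative signals floor at zero
  spots2 <- make_subarray(c(-0.5), antibody_ids = "AB01")
  fsm2 <- build_signal_matrix(normalize_spots(spots2), manifest)
  expect_equal(unname(fsm2["P1", "1", "T"]), 0)
  # single positive spot is passed through unchanged
  spots3 <- make_subarray(c(0.5), antibody_ids = "AB01")
  fsm3 <- build_signal_matrix(normalize_spots(spots3), manifest)
  expect_equal(unname(fsm3["P1", "1", "T"]), 0.5)
})
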