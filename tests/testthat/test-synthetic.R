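test_that("proteome generation is deterministic and honours panel constraints", {
  cfg <- sim_config(n_proteins = 162, n_complexes = 10, seed = 1)
  t1 <- generate_proteome(cfg)
  t2 <- generate_proteome(cfg)
  expect_identical(t1, t2)
  expect_identical(nrow(t1$proteins), 162L)
  expect_identical(nrow(t1$antibodies), 205L)
  # every protein targeted by at least one antibody
  expect_true(all(t1$proteins$protein_id %in% t1$antibodies$protein_id))
  # complexes: >= 2 members, complex MW at least the largest member
  for (i in seq_len(nrow(t1$complexes))) {
    members <- strsplit(t1$complexes$members[i], ";")[[1L]]
    expect_gte(length(members), 2L)
    mws <- t1$proteins$theoretical_mw[t1$proteins$protein_id %in% members]
    expect_gte(t1$complexes$complex_mw[i], max(mws))
  }
  # share bookkeeping: degraded + complexed <= 1, MW within [5, 600]
  with(t1$proteins, {
    expect_true(all(degraded_fraction + complexed_fraction <= 1 + 1e-12))
    expect_true(all(theoretical_mw >= 5 & theoretical_mw <= 600))
  })
})

test_that("degenerate single-protein configuration yields one monomer, no complexes", {
  cfg <- sim_config(n_proteins = 1, n_complexes = 0, n_antibodies = 1,
                    seed = 3, p_degraded = 0)
  truth <- generate_proteome(cfg)
  expect_identical(nrow(truth$proteins), 1L)
  expect_identical(nrow(truth$complexes), 0L)
  expect_identical(truth$proteins$true_state, "monomer")
  expect_error(sim_config(n_proteins = 0), class = "secmap_config_error")
  expect_error(sim_config(rho_abundance_fpkm = 1.2),
               class = "secmap_config_error")
  expect_error(sim_config(protocols = "#10"), class = "secmap_config_error")
})

test_that("elution places species at their MW fractions and conserves signal", {
  cfg <- sim_config(n_proteins = 2, n_complexes = 0, n_antibodies = 2,
                    seed = 1, protocols = "#1", p_degraded = 0)
  base <- generate_proteome(cfg)
  truth <- base
  truth$proteins$theoretical_mw <- c(440, 26)
  truth$proteins$theoretical_fraction <- c(1L, 6L)
  truth$proteins$localizations <- "Cyt"
  truth$proteins$abundance <- c(100, 100)
  truth$proteins$monomer_fraction <- c(1, 0)
  truth$proteins$complex_id <- c(NA, "CPLX01")
  truth$proteins$complexed_fraction <- c(0, 1)
  truth$proteins$true_state <- c("monomer", "complexed")
  truth$complexes <- data.frame(complex_id = "CPLX01",
                                members = "PROT0002", complex_mw = 440)
  elu <- simulate_elution(truth, cfg)
  merged <- merge_elution(elu)
  # 440 kDa monomer: a single peak in merged fraction 1
  expect_identical(find_peaks(merged["PROT0001", , "#1"]), 1L)
  # 26 kDa protein fully in a 440 kDa complex: all signal at fraction 1,
  # none at its own 24-28 kDa fraction
  expect_identical(find_peaks(merged["PROT0002", , "#1"]), 1L)
  expect_equal(unname(merged["PROT0002", "6", "#1"]), 0, tolerance = 1e-9)
  # totals: abundance x extraction x labeling for protocol #1 / Cyt
  m <- protocol_models()[["#1"]]
  want <- 100 * m$extraction_efficiency[["Cyt"]] * m$labeling_efficiency
  expect_equal(unname(rowSums(merged[, , "#1"])), rep(want, 2),
               tolerance = 1e-9)
})

test_that("a fully degraded protein elutes strictly below its theoretical fraction", {
  cfg <- sim_config(n_proteins = 30, n_complexes = 0, n_antibodies = 30,
                    seed = 21, protocols = "#1", p_degraded = 1)
  truth <- generate_proteome(cfg)
  merged <- merge_elution(simulate_elution(truth))
  full <- which(truth$proteins$degraded_fraction == 1)
  expect_gt(length(full), 0)
  for (i in full) {
    th <- truth$proteins$theoretical_fraction[i]
    peaks <- find_peaks(merged[i, , "#1"])
    expect_true(all(peaks > th))
  }
})

test_that("array simulation is noiseless-identical to the truth and lays out replicates", {
  cfg <- sim_config(n_proteins = 5, n_complexes = 0, n_antibodies = 5,
                    seed = 2, protocols = "#1", noise_cv = 0,
                    background_level = 0, background_sd = 0,
                    mm_background_level = 0, p_degraded = 0)
  truth <- generate_proteome(cfg)
  truth$antibodies$affinity_factor <- 1
  merged <- merge_elution(simulate_elution(truth))
  spots <- simulate_array(merged, truth$antibodies, cfg)
  ab <- spots[!spots$is_mm_only & !spots$is_biotin_control, ]
  want <- merged[cbind(truth$antibodies$protein_id[
    match(ab$antibody_id, truth$antibodies$antibody_id)],
    as.character(ab$fraction_id), ab$protocol_id)]
  expect_equal(ab$delta_median, want, tolerance = 1e-12)
  # exactly n_replicate_spots spots per antibody per subarray
  counts <- table(ab$antibody_id, ab$subarray_id)
  expect_true(all(counts == cfg$n_replicate_spots))
  # rerun is byte-identical
  expect_identical(spots, simulate_array(merged, truth$antibodies, cfg))
})

test_that("omics tables carry the planted structure", {
  cfg <- sim_config(n_proteins = 400, n_complexes = 0, n_antibodies = 400,
                    seed = 8, rho_abundance_fpkm = 0.6)
  truth <- generate_proteome(cfg)
  om <- simulate_omics(truth)
  expect_identical(om, simulate_omics(truth))
  # secondary gene ids always have lower FPKM than the primary
  dup <- om$rna[duplicated(om$rna$protein_id), ]
  expect_gt(nrow(dup), 0)
  prim <- om$rna[!duplicated(om$rna$protein_id), ]
  prim_fpkm <- prim$fpkm[match(dup$protein_id, prim$protein_id)]
  expect_true(all(dup$fpkm < prim_fpkm | prim_fpkm == 0))
  # forced dropouts exist to exercise the fully-observed logic
  expect_gt(sum(om$msms$peptide_count == 0), 0)
  expect_gt(sum(prim$fpkm == 0), 0)
  # LFQ is split exactly across the true localizations
  lfq <- as.matrix(om$msms[, c("lfq_cyt", "lfq_mem", "lfq_org", "lfq_nuc")])
  locs <- strsplit(truth$proteins$localizations, ";")
  n_pos <- as.integer(rowSums(lfq > 0))
  expect_identical(n_pos, lengths(locs))
})
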