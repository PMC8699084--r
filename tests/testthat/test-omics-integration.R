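test_that("the highest-FPKM gene is selected, with deterministic tie-breaking", {
  sel <- select_gene(data.frame(gene_id = c("g1", "g2"), fpkm = c(3.0, 7.0)))
  expect_equal(sel$fpkm, 7.0)
  expect_identical(sel$gene_id, "g2")
  sel <- select_gene(data.frame(gene_id = "g1", fpkm = 2.5))
  expect_equal(sel$fpkm, 2.5)
  sel <- select_gene(data.frame(gene_id = c("geneB", "geneA"), fpkm = c(4, 4)))
  expect_equal(sel$fpkm, 4)
  expect_identical(sel$gene_id, "geneA")
  expect_true(sel$tie)
  sel <- select_gene(NULL)
  expect_equal(sel$fpkm, 0)
  expect_true(sel$no_rna_evidence)
})

test_that("fully-observed is the inclusive OR of the three unit thresholds", {
  expect_true(flag_fully_observed(0, 0.5, 2))
  expect_false(flag_fully_observed(0, 0.99, 0.99))
  expect_true(flag_fully_observed(1, 0, 0))
  expect_true(flag_fully_observed(0, 1, 0))
  # monotone in each argument
  set.seed(5)
  for (i in 1:50) {
    x <- runif(3, 0, 2)
    if (flag_fully_observed(x[1], x[2], x[3])) {
      bump <- x + c(1, 0, 0) * runif(1)
      expect_true(flag_fully_observed(bump[1], bump[2], bump[3]))
    }
  }
})

test_that("localization classifier reproduces the 15-category table", {
  comps <- c("Cyt", "Mem", "Org", "Nuc")
  # hand-enumerated subset -> category table
  want <- list(
    "Nuc" = "Nuc", "Cyt" = "Cyt", "Mem" = "Mem", "Org" = "Org",
    "Nuc,Org" = "Nuc-Org", "Nuc,Cyt" = "Nuc-Cyt", "Nuc,Mem" = "Nuc-Mem",
    "Org,Cyt" = "Org-Cyt", "Org,Mem" = "Org-Mem", "Cyt,Mem" = "Cyt-Mem",
    "Nuc,Org,Cyt" = "Nuc-Org-Cyt", "Nuc,Org,Mem" = "Nuc-Org-Mem",
    "Nuc,Cyt,Mem" = "Nuc-Cyt-Mem", "Org,Cyt,Mem" = "Org-Cyt-Mem",
    "Nuc,Org,Cyt,Mem" = "Nuc-Org-Cyt-Mem")
  got <- character(0)
  for (key in names(want)) {
    subset <- strsplit(key, ",")[[1L]]
    # input order must not matter
    expect_identical(classify_localization(subset), want[[key]])
    expect_identical(classify_localization(rev(subset)), want[[key]])
    got <- c(got, classify_localization(subset))
  }
  expect_setequal(got, localization_categories())
  expect_length(localization_categories(), 15L)
  expect_warning(res <- classify_localization(character(0)), "not classified")
  expect_identical(res, NA_character_)
  expect_error(classify_localization("Mitochondria"),
               class = "secmap_config_error")
})

test_that("overlap percentage equals a brute-force set oracle", {
  expect_equal(pairwise_overlap(paste0("p", 1:4), paste0("p", 1:2)), 50)
  expect_equal(pairwise_overlap(c("a", "b"), c("a", "b", "c")), 100)
  expect_true(is.na(pairwise_overlap(character(0), "a")))
  set.seed(11)
  for (i in 1:200) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(0:20, 1))
    brute <- 100 * sum(vapply(unique(a), function(x) x %in% b, logical(1))) /
      length(unique(a))
    expect_equal(pairwise_overlap(a, b), brute)
    # order invariance
    expect_equal(pairwise_overlap(sample(a), b), brute)
  }
})

test_that("LFQ/FPKM groups follow the quartile fences and robust-fit outlier rule", {
  set.seed(13)
  n <- 200
  x <- rnorm(n, 1, 1)                      # log FPKM
  y <- 6 + 0.8 * x + rnorm(n, 0, 1.2)     # log LFQ, wide scatter
  grp <- classify_lfq_fpkm_group(y, x)
  # the medoid point is average population
  center <- which.min((x - median(x))^2 + (y - median(y))^2)
  expect_identical(grp[center], "average")
  # quantile corners
  q_lfq <- quantile(y, c(0.25, 0.75)); q_fpkm <- quantile(x, c(0.25, 0.5, 0.75))
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 100)
  z <- residuals(fit) / fit$s
  hi_lo <- y > q_lfq[2] & x < q_fpkm[1] & abs(z) <= 3
  expect_true(all(grp[hi_lo] == "high-LFQ/low-FPKM"))
  hi_hi <- y > q_lfq[2] & x > q_fpkm[3] & abs(z) <= 3
  expect_true(all(grp[hi_hi] == "high-LFQ/high-FPKM"))
  lo_prog <- y < q_lfq[1] & x > q_fpkm[2] & abs(z) <= 3
  expect_true(all(grp[lo_prog] == "low-LFQ/progressive-FPKM"))
  # independently recomputed robust residuals define the outliers
  expect_identical(which(grp == "outlier"), unname(which(abs(z) > 3)))
  # permutation invariance
  perm <- sample(n)
  expect_identical(classify_lfq_fpkm_group(y[perm], x[perm]), grp[perm])
  expect_warning(res <- classify_lfq_fpkm_group(1:5, 1:5), "skipped")
  expect_true(all(is.na(res)))
})

test_that("merged omics records combine evidence and flag integrity problems", {
  qas <- c(P1 = 2.0, P2 = 0.1)
  msms <- data.frame(protein_id = c("P1", "P3"), peptide_count = c(5L, 0L),
                     lfq_cyt = c(10, 0), lfq_mem = c(0, 3),
                     lfq_org = c(0, 3), lfq_nuc = c(2, 0))
  rna <- data.frame(gene_id = c("g1", "g1b", "g3"),
                    protein_id = c("P1", "P1", "P3"),
                    fpkm = c(3.0, 7.0, 0.2))
  merged <- suppressWarnings(merge_omics(qas, msms, rna))
  expect_setequal(merged$protein_id, c("P1", "P2", "P3"))
  p1 <- merged[merged$protein_id == "P1", ]
  expect_equal(p1$fpkm_selected, 7.0)
  expect_identical(p1$gene_id, "g1b")
  expect_equal(p1$lfq_total, 12)
  expect_identical(p1$localization_category, "Nuc-Cyt")
  expect_true(p1$fully_observed)
  p2 <- merged[merged$protein_id == "P2", ]
  expect_false(p2$fully_observed)  # qas 0.1, no peptides, no RNA
  p3 <- merged[merged$protein_id == "P3", ]
  expect_identical(p3$localization_category, "Org-Mem")
  expect_false(p3$fully_observed)
  expect_error(merge_omics(qas, rbind(msms, msms[1L, ]), rna),
               class = "secmap_integrity_error")
  expect_error(merge_omics(qas, msms, rbind(rna, rna[1L, ])),
               class = "secmap_integrity_error")
})

test_that("overlap reports recover planted intersections and Venn counts", {
  panel <- paste0("p", 1:10)
  rep1 <- compile_overlap_report(panel[1:6], panel[1:6], panel[1:6], panel)
  expect_true(all(rep1$pairwise$matching_percentage == 100))
  expect_equal(unname(rep1$venn["all_three"]), 6)
  rep2 <- compile_overlap_report(panel[1:3], panel[4:6], panel[7:9], panel)
  expect_true(all(rep2$pairwise$matching_percentage == 0))
  expect_equal(unname(rep2$venn["all_three"]), 0)
  # planted asymmetric overlap
  rep3 <- compile_overlap_report(panel[1:4], panel[3:10], panel[1:10], panel)
  got <- rep3$pairwise
  expect_equal(
    got$matching_percentage[got$query == "SEC-MAP" & got$reference == "LC-MS/MS"],
    100 * 2 / 4)
  expect_equal(
    got$matching_percentage[got$query == "LC-MS/MS" & got$reference == "SEC-MAP"],
    100 * 2 / 8)
  expect_error(compile_overlap_report(c("x1"), panel, panel, panel),
               class = "secmap_integrity_error")
})
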