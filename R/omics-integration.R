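#' Select the gene for a protein mapped to several gene ids
#'
#' When a protein maps to more than one gene id, the gene with the highest
#' FPKM is selected. Ties are broken by the lexicographically smallest gene
#' id and flagged. A protein with no candidate genes gets FPKM 0 and is
#' flagged as lacking RNA evidence.
#'
#' @param candidates data frame with columns \code{gene_id}, \code{fpkm} for
#'   one protein.
#' @return List with \code{gene_id}, \code{fpkm}, \code{tie},
#'   \code{no_rna_evidence}.
#' @export
select_gene <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(gene_id = NA_character_, fpkm = 0, tie = FALSE,
                no_rna_evidence = TRUE))
  }
  best <- max(candidates$fpkm)
  hits <- candidates$gene_id[candidates$fpkm == best]
  list(gene_id = sort(hits)[1L], fpkm = best, tie = length(hits) > 1L,
       no_rna_evidence = FALSE)
}

#' Fully-observed flag
#'
#' A protein is fully observed when any of the three evidence streams reaches
#' its unit threshold: peptide count >= 1, FPKM >= 1 or QAS >= 1 (QAS being
#' the maximum biotin-normalized SEC-MAP signal, so 1 means
#' biotin-control-level signal).
#'
#' @param peptide_count,fpkm,qas nonnegative numerics (vectorized).
#' @return Logical vector.
#' @export
flag_fully_observed <- function(peptide_count, fpkm, qas) {
  peptide_count >= 1 | fpkm >= 1 | qas >= 1
}

#' The 15 subcellular localization categories
#'
#' Every non-empty subset of \{Cyt, Mem, Org, Nuc\} in the canonical
#' positive-selection order.
#' @return Character vector of length 15.
#' @export
localization_categories <- function() {
  c("Nuc", "Cyt", "Mem", "Org",
    "Nuc-Org", "Nuc-Cyt", "Nuc-Mem", "Org-Cyt", "Org-Mem", "Cyt-Mem",
    "Nuc-Org-Cyt", "Nuc-Org-Mem", "Nuc-Cyt-Mem", "Org-Cyt-Mem",
    "Nuc-Org-Cyt-Mem")
}

#' Classify a compartment set into its localization category
#'
#' @param compartments character vector of detected compartments (a subset
#'   of Cyt, Mem, Org, Nuc), or a list of such vectors.
#' @return The category label(s); \code{NA} (with a warning) for an empty
#'   set, which is excluded from classification.
#' @export
classify_localization <- function(compartments) {
  if (is.list(compartments)) {
    return(vapply(compartments, classify_localization, character(1)))
  }
  compartments <- unique(compartments[!is.na(compartments) & compartments != ""])
  if (length(compartments) == 0L) {
    warning("empty compartment set: protein not classified", call. = FALSE)
    return(NA_character_)
  }
  order_ref <- c("Nuc", "Org", "Cyt", "Mem")
  if (!all(compartments %in% order_ref)) {
    secmap_stop("secmap_config_error",
                "compartments must be a subset of Cyt, Mem, Org, Nuc")
  }
  paste(order_ref[order_ref %in% compartments], collapse = "-")
}

#' Query-normalized overlap percentage of two protein sets
#'
#' \code{100 * |A intersect B| / |A|} with A the first-named (query) set.
#' Inputs are de-duplicated; an empty query set yields \code{NA}.
#'
#' @param a,b character vectors of protein ids.
#' @return Percentage in \[0, 100\], or \code{NA} when \code{a} is empty.
#' @export
pairwise_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L) return(NA_real_)
  100 * length(intersect(a, b)) / length(a)
}

#' Classify proteins into LFQ/FPKM population groups
#'
#' Rank-based, seedless grouping of the log LFQ vs log FPKM scatter:
#' outliers are points whose standardized residual from a Huber robust
#' linear fit of log LFQ on log FPKM exceeds \code{outlier_z}; the remaining
#' points fall into quartile-fence groups — high LFQ (> Q3) with low FPKM
#' (< Q1), high LFQ with high FPKM (> Q3), low LFQ (< Q1) with FPKM above
#' its median ("progressive"), and the average population otherwise.
#'
#' @param log_lfq,log_fpkm numeric vectors (log10 scale; non-finite entries
#'   are left unclassified).
#' @param outlier_z standardized-residual cutoff (default 3).
#' @return Character vector of group labels (\code{NA} where either value is
#'   missing); \code{NA} everywhere, with a warning, when fewer than 10
#'   complete records are available.
#' @export
classify_lfq_fpkm_group <- function(log_lfq, log_fpkm, outlier_z = 3) {
  stopifnot(length(log_lfq) == length(log_fpkm))
  ok <- is.finite(log_lfq) & is.finite(log_fpkm)
  out <- rep(NA_character_, length(log_lfq))
  if (sum(ok) < 10L) {
    warning("fewer than 10 complete LFQ/FPKM records: grouping skipped",
            call. = FALSE)
    return(out)
  }
  x <- log_fpkm[ok]; y <- log_lfq[ok]
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 100)
  z <- stats::residuals(fit) / fit$s
  q_lfq <- stats::quantile(y, c(0.25, 0.75))
  q_fpkm <- stats::quantile(x, c(0.25, 0.5, 0.75))
  grp <- rep("average", length(y))
  grp[y > q_lfq[2L] & x < q_fpkm[1L]] <- "high-LFQ/low-FPKM"
  grp[y > q_lfq[2L] & x > q_fpkm[3L]] <- "high-LFQ/high-FPKM"
  grp[y < q_lfq[1L] & x > q_fpkm[2L]] <- "low-LFQ/progressive-FPKM"
  grp[abs(z) > outlier_z] <- "outlier"
  out[ok] <- grp
  out
}

#' Merge SEC-MAP, LC-MS/MS and RNA-seq evidence per protein
#'
#' Joins the three datasets on protein id, applies the highest-FPKM gene
#' selection, sums compartment LFQs, derives the localization category from
#' the compartments with positive LFQ, flags fully-observed proteins and
#' assigns LFQ/FPKM population groups.
#'
#' @param qas named numeric vector: maximum biotin-normalized SEC-MAP signal
#'   per protein (see [qas_values()]), 0 / absent for undetected proteins.
#' @param msms LC-MS/MS table (\code{protein_id}, \code{peptide_count},
#'   \code{lfq_cyt}, \code{lfq_mem}, \code{lfq_org}, \code{lfq_nuc}).
#' @param rna RNA-seq table (\code{gene_id}, \code{protein_id}, \code{fpkm}).
#' @param outlier_z residual cutoff passed to [classify_lfq_fpkm_group()].
#' @return Data frame, one row per protein appearing in any dataset.
#' @export
merge_omics <- function(qas, msms, rna, outlier_z = 3) {
  if (anyDuplicated(msms$protein_id)) {
    secmap_stop("secmap_integrity_error", "duplicate protein_id in LC-MS/MS table")
  }
  if (anyDuplicated(rna$gene_id)) {
    secmap_stop("secmap_integrity_error", "duplicate gene_id in RNA-seq table")
  }
  ids <- sort(unique(c(names(qas), msms$protein_id, rna$protein_id)))
  mi <- match(ids, msms$protein_id)
  sel <- lapply(ids, function(p) {
    select_gene(rna[rna$protein_id == p, c("gene_id", "fpkm"), drop = FALSE])
  })
  lfq_cols <- c("lfq_cyt", "lfq_mem", "lfq_org", "lfq_nuc")
  comp_of <- c(lfq_cyt = "Cyt", lfq_mem = "Mem", lfq_org = "Org",
               lfq_nuc = "Nuc")
  out <- data.frame(
    protein_id = ids,
    qas = ifelse(is.na(match(ids, names(qas))), 0, qas[ids]),
    peptide_count = ifelse(is.na(mi), 0L, msms$peptide_count[mi]),
    fpkm_selected = vapply(sel, `[[`, numeric(1), "fpkm"),
    gene_id = vapply(sel, `[[`, character(1), "gene_id"),
    fpkm_tie = vapply(sel, `[[`, logical(1), "tie")
  )
  lfq_mat <- matrix(0, length(ids), 4L, dimnames = list(NULL, lfq_cols))
  lfq_mat[!is.na(mi), ] <- as.matrix(msms[mi[!is.na(mi)], lfq_cols])
  out$lfq_total <- rowSums(lfq_mat)
  out$localization_category <- vapply(seq_along(ids), function(i) {
    comps <- comp_of[lfq_cols[lfq_mat[i, ] > 0]]
    if (length(comps) == 0L) NA_character_ else classify_localization(comps)
  }, character(1))
  out$fully_observed <- flag_fully_observed(out$peptide_count,
                                            out$fpkm_selected, out$qas)
  pos <- out$lfq_total > 0 & out$fpkm_selected > 0
  out$lfq_fpkm_group <- NA_character_
  out$lfq_fpkm_group[pos] <- classify_lfq_fpkm_group(
    log10(out$lfq_total[pos]), log10(out$fpkm_selected[pos]), outlier_z)
  out
}

#' Per-protein QAS values from a signal matrix
#'
#' QAS (quantified array signal) is the maximum biotin-normalized SEC-MAP
#' signal of a protein across fractions and protocol channels; a value of 1
#' means biotin-control-level signal.
#'
#' @param fsm a [build_signal_matrix()] result.
#' @return Named numeric vector over the panel proteins.
#' @export
qas_values <- function(fsm) {
  apply(fsm, 1L, max)
}

#' Overlap statistics across the three datasets
#'
#' Computes query-normalized matching percentages in both orientations (plus
#' Jaccard) for the three dataset pairs, and the Venn region counts of the
#' triple. When a pair involves SEC-MAP, both sets are restricted to the
#' SEC-MAP panel universe before comparison; the RNA-seq vs LC-MS/MS pair is
#' compared on the full id space.
#'
#' @param secmap_detected protein ids detected by SEC-MAP.
#' @param msms_detected protein ids detected by LC-MS/MS.
#' @param rna_detected protein ids with RNA evidence.
#' @param panel the SEC-MAP panel universe (all targeted protein ids).
#' @return List of class \code{overlap_report}: \code{sizes},
#'   \code{pairwise} (data frame: query, reference, n_query, n_intersection,
#'   matching_percentage, jaccard), \code{venn} (7 region counts).
#' @export
compile_overlap_report <- function(secmap_detected, msms_detected,
                                   rna_detected, panel) {
  S <- unique(secmap_detected); M <- unique(msms_detected)
  R <- unique(rna_detected); panel <- unique(panel)
  if (!all(S %in% panel)) {
    secmap_stop("secmap_integrity_error",
                "SEC-MAP detections outside the panel universe")
  }
  pair_row <- function(qname, q, rname, r) {
    data.frame(query = qname, reference = rname,
               n_query = length(q),
               n_intersection = length(intersect(q, r)),
               matching_percentage = pairwise_overlap(q, r),
               jaccard = if (length(union(q, r)) == 0L) NA_real_ else
                 length(intersect(q, r)) / length(union(q, r)))
  }
  Mp <- intersect(M, panel); Rp <- intersect(R, panel)
  pairwise <- rbind(
    pair_row("SEC-MAP", S, "LC-MS/MS", Mp),
    pair_row("LC-MS/MS", Mp, "SEC-MAP", S),
    pair_row("SEC-MAP", S, "RNA-Seq", Rp),
    pair_row("RNA-Seq", Rp, "SEC-MAP", S),
    pair_row("RNA-Seq", R, "LC-MS/MS", M),
    pair_row("LC-MS/MS", M, "RNA-Seq", R)
  )
  venn <- c(
    secmap_only = length(setdiff(S, union(M, R))),
    msms_only = length(setdiff(M, union(S, R))),
    rna_only = length(setdiff(R, union(S, M))),
    secmap_msms = length(setdiff(intersect(S, M), R)),
    secmap_rna = length(setdiff(intersect(S, R), M)),
    msms_rna = length(setdiff(intersect(M, R), S)),
    all_three = length(intersect(intersect(S, M), R))
  )
  structure(list(sizes = c(secmap = length(S), msms = length(M),
                           rna = length(R), panel = length(panel)),
                 pairwise = pairwise, venn = venn),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Dataset overlap report\n")
  cat(sprintf("sizes: SEC-MAP %d, LC-MS/MS %d, RNA-Seq %d (panel %d)\n",
              x$sizes["secmap"], x$sizes["msms"], x$sizes["rna"],
              x$sizes["panel"]))
  print(x$pairwise, row.names = FALSE)
  cat("Venn regions:\n"); print(x$venn)
  invisible(x)
}
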