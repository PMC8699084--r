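# Plain-text readers and writers: GenePix-style spot tables, omics TSVs,
# truth tables, YAML configs, JSON reports. All tables are TSV with a header
# row so every artifact stays diffable.

genepix_required <- c("Block", "Row", "Column", "ID", "Name", "F532 Median",
                      "B532 Median", "fraction_id", "protocol_id")

#' Write a spot table as a GenePix-style TSV
#'
#' Columns: Block, Row, Column, ID (antibody id, or the MM lot for MM-only
#' spots / "BIOTIN" for positive controls), Name, F532 Median (the raw median
#' intensity), B532 Median, plus sidecar columns fraction_id, protocol_id,
#' subarray_id, mm_id, replicate_index, is_mm_only, is_biotin_control.
#'
#' @param spots spot table from [simulate_array()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  gp <- data.frame(
    Block = spots$block,
    Row = spots$row,
    Column = spots$column,
    ID = ifelse(spots$is_biotin_control, "BIOTIN",
                ifelse(spots$is_mm_only, spots$mm_id, spots$antibody_id)),
    Name = ifelse(spots$is_biotin_control, "biotin-control",
                  ifelse(spots$is_mm_only, "mastermix-only", "antibody")),
    `F532 Median` = spots$delta_median,
    `B532 Median` = 0,
    fraction_id = spots$fraction_id,
    protocol_id = spots$protocol_id,
    subarray_id = spots$subarray_id,
    mm_id = spots$mm_id,
    replicate_index = spots$replicate_index,
    is_mm_only = spots$is_mm_only,
    is_biotin_control = spots$is_biotin_control,
    check.names = FALSE
  )
  utils::write.table(gp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GenePix-style spot table
#'
#' Headers are matched case-insensitively; unknown extra columns are ignored
#' with a warning (GenePix dialects vary). Rows with negative intensity are
#' rejected with their line numbers.
#'
#' @param path TSV file written by [write_spot_table()] or an equivalent
#'   GenePix export carrying the sidecar columns.
#' @return Spot table data frame (see [simulate_array()]).
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) {
    secmap_stop("secmap_missing_file", sprintf("spot table not found: %s", path))
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names_lc <- tolower(names(raw))
  miss <- setdiff(tolower(genepix_required), names_lc)
  if (length(miss)) {
    secmap_stop("secmap_schema_error",
                sprintf("spot table missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names_lc, tolower(c(genepix_required, "subarray_id",
                                       "mm_id", "replicate_index",
                                       "is_mm_only", "is_biotin_control")))
  if (length(extra)) {
    warning(sprintf("ignoring %d unrecognized column(s): %s", length(extra),
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  col <- function(nm) raw[[which(names_lc == tolower(nm))[1L]]]
  delta <- as.numeric(col("F532 Median"))
  bad <- which(!is.finite(delta) | delta < 0)
  if (length(bad)) {
    secmap_stop("secmap_schema_error",
                sprintf("negative or non-numeric intensity at data row(s): %s",
                        paste(utils::head(bad, 5L), collapse = ", ")))
  }
  has <- function(nm) tolower(nm) %in% names_lc
  is_mm <- if (has("is_mm_only")) as.logical(col("is_mm_only")) else
    grepl("^MM", col("ID"))
  is_bio <- if (has("is_biotin_control")) as.logical(col("is_biotin_control")) else
    col("ID") == "BIOTIN"
  data.frame(
    subarray_id = if (has("subarray_id")) as.character(col("subarray_id")) else
      sprintf("%s|F%d", as.character(col("protocol_id")),
              as.integer(col("fraction_id"))),
    block = as.integer(col("Block")),
    row = as.integer(col("Row")),
    column = as.integer(col("Column")),
    antibody_id = ifelse(is_mm | is_bio, NA_character_,
                         as.character(col("ID"))),
    mm_id = if (has("mm_id")) {
      mm <- as.character(col("mm_id")); mm[mm == "" | mm == "NA"] <- NA; mm
    } else ifelse(is_mm, as.character(col("ID")), NA_character_),
    replicate_index = if (has("replicate_index"))
      as.integer(col("replicate_index")) else seq_len(nrow(raw)),
    delta_median = delta,
    fraction_id = as.integer(col("fraction_id")),
    protocol_id = as.character(col("protocol_id")),
    is_mm_only = is_mm,
    is_biotin_control = is_bio
  )
}

#' Write / read the panel manifest and omics tables
#'
#' Simple TSV round-trips for the antibody panel manifest, the LC-MS/MS
#' summary and the RNA-seq gene table.
#' @param x data frame to write.
#' @param path file path.
#' @return The data frame (readers) or \code{path} invisibly (writers).
#' @name omics_io
NULL

#' @rdname omics_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname omics_io
#' @param required character vector of required column names.
#' @export
read_tsv_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) {
    secmap_stop("secmap_missing_file", sprintf("file not found: %s", path))
  }
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  miss <- setdiff(tolower(required), names(x))
  if (length(miss)) {
    secmap_stop("secmap_schema_error",
                sprintf("%s missing column(s): %s", basename(path),
                        paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname omics_io
#' @export
read_omics_tables <- function(msms_path, rna_path) {
  msms <- read_tsv_checked(msms_path, c("protein_id", "peptide_count",
                                        "lfq_cyt", "lfq_mem", "lfq_org",
                                        "lfq_nuc"))
  rna <- read_tsv_checked(rna_path, c("gene_id", "protein_id", "fpkm"))
  if (any(msms$peptide_count < 0) || any(rna$fpkm < 0)) {
    secmap_stop("secmap_schema_error",
                "negative peptide counts or FPKM values")
  }
  list(msms = msms, rna = rna)
}

#' Write / read a run configuration as YAML
#'
#' Unknown keys are rejected so typos cannot silently disable a threshold.
#' @param config a [sim_config()] (or plain list of its fields).
#' @param path YAML file path.
#' @return \code{path} invisibly / the validated [sim_config()].
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    secmap_stop("secmap_missing_file", sprintf("config not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    secmap_stop("secmap_schema_error",
                sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  for (nm in c("abundance_lognormal_params", "lfq_lognormal_params",
               "fpkm_lognormal_params")) {
    if (!is.null(vals[[nm]])) {
      v <- unlist(vals[[nm]])
      if (is.null(names(v)) && length(v) == 2L) {
        names(v) <- c("meanlog", "sdlog")
      }
      vals[[nm]] <- v
    }
  }
  do.call(sim_config, vals)
}
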