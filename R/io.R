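#' Read a per-cell copy-number table
#'
#' Reads the delimited cell tables produced by sequential-iFISH scoring (or by
#' [generate_cohort()]): one row per nucleus, a `cell_id` column, optionally a
#' `sample_id` column, and one column per panel chromosome holding the
#' integer copy-number call. An empty field or a sentinel value marks a
#' channel with no hybridization signal; such cells are not informative and
#' are excluded from downstream clonality analysis.
#'
#' @param path Path to a TSV/CSV file (delimiter auto-detected from the
#'   header line).
#' @param panel A `ChromosomePanel`; every panel chromosome must have a
#'   column.
#' @param na_strings Sentinels marking a missing signal (besides empty
#'   fields).
#' @return A data frame with `cell_id`, `sample_id` (if present), one integer
#'   column per panel chromosome (NA = missing signal), a logical
#'   `informative` column, and attributes `n_informative` /
#'   `n_noninformative`. Input row order is preserved.
#' @export
read_cell_table <- function(path, panel = default_panel(),
                            na_strings = c("", "NA")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel$label, names(tab))
  if (length(missing_cols))
    stop("cell table lacks panel chromosome column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), c("cell_id", "sample_id", panel$label))
  if (length(extra))
    stop("unknown chromosome column(s) in cell table: ",
         paste(extra, collapse = ", "))
  for (ch in panel$label) {
    v <- suppressWarnings(as.integer(tab[[ch]]))
    bad <- which(!is.na(tab[[ch]]) & is.na(v))
    if (length(bad))
      stop("non-integer count in column ", ch, ", row ", bad[1])
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      stop("negative copy-number count in column ", ch, ", row ", neg[1])
    tab[[ch]] <- v
  }
  tab$informative <- !apply(is.na(as.matrix(tab[, panel$label])), 1, any)
  attr(tab, "n_informative") <- sum(tab$informative)
  attr(tab, "n_noninformative") <- sum(!tab$informative)
  tab
}

#' Read a per-sample clinical table
#'
#' Expected columns: `patient_id`, `timepoint` (DX/REL), `outcome` (CR/REL),
#' `relapse`, `death`, `time_years`, `age`, `sex`, and optionally `wbc`,
#' `mrd`, `protocol`, `karyotype`.
#'
#' @param path Path to a TSV/CSV file.
#' @return A data frame, one row per sample.
#' @export
read_clinical_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  required <- c("patient_id", "timepoint", "outcome", "relapse", "death",
                "time_years", "age", "sex")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.na(tab$time_years) & tab$time_years < 0))
    stop("time_years must be non-negative")
  bad <- which(tab$outcome == "CR" & tab$relapse %in% c(1, TRUE, "Yes"))
  if (length(bad))
    stop("outcome CR inconsistent with relapse indicator in row ", bad[1])
  tab
}

#' Write a cell table in the dialect read_cell_table() accepts
#'
#' @param cells Data frame with `cell_id`, optionally `sample_id`, and one
#'   column per panel chromosome.
#' @param path Output TSV path.
#' @param panel A `ChromosomePanel`.
#' @export
write_cell_table <- function(cells, path, panel = default_panel()) {
  keep <- intersect(c("cell_id", "sample_id", panel$label), names(cells))
  utils::write.table(cells[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Discovery-cohort table printed in the study
#'
#' Per-case karyotype strings (restricted ISCN dialect), sex, clinical
#' outcome, and the major subclone code and its percentage determined by
#' sequential iFISH, for the 22 diagnostic samples of the discovery cohort.
#' Shipped as a plain-text fixture so the karyotype-concordance analysis can
#' be reproduced without the (undeposited) raw single-cell data.
#'
#' @return Data frame with columns `case`, `outcome`, `sex`, `karyotype`,
#'   `fish_major_clone`, `fish_pmc`, `karyotype_concordant`.
#' @export
discovery_cohort <- function() {
  path <- system.file("extdata", "discovery_cohort.tsv", package = "clonefish",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c(fish_major_clone = "character"),
                    stringsAsFactors = FALSE)
}
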