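#' Subclone codes
#'
#' A subclone code is the vector of per-chromosome gains relative to the
#' constitutional baseline, in panel order (X, 4, 6, 10, 14, 17, 18, 21 by
#' default). Its canonical string form is the plain digit concatenation used
#' for the 8-digit codes (e.g. "10001002") whenever all gains lie in 0..9;
#' when any gain is negative (a loss) or exceeds 9, a comma-separated form is
#' used instead (e.g. "1,0,-1,0,0,0,0,0").
#'
#' @param gains Integer vector of per-chromosome gains.
#' @return `subclone_string()`: a single string; `subclone_gains()`: an
#'   integer vector.
#' @examples
#' subclone_string(c(1, 0, 0, 0, 1, 0, 0, 2))   # "10001002"
#' subclone_gains("10001002")
#' @export
subclone_string <- function(gains) {
  gains <- as.integer(gains)
  if (anyNA(gains)) stop("gains must not contain NA")
  if (all(gains >= 0 & gains <= 9)) paste(gains, collapse = "")
  else paste(gains, collapse = ",")
}

#' @rdname subclone_string
#' @param code Canonical subclone code string.
#' @export
subclone_gains <- function(code) {
  stopifnot(is.character(code), length(code) == 1)
  if (grepl(",", code, fixed = TRUE)) {
    as.integer(strsplit(code, ",", fixed = TRUE)[[1]])
  } else {
    as.integer(strsplit(code, "", fixed = TRUE)[[1]])
  }
}

#' Encode a cell's copy-number profile as a subclone code
#'
#' Gains are observed copies minus the constitutional baseline (X baseline 1
#' for males, 2 for females; autosomes 2).
#'
#' @param counts Integer vector of observed copy numbers in panel order, or a
#'   one-row slice of a cell table. Cells with any missing channel are not
#'   informative and cannot be encoded.
#' @param sex "M" or "F".
#' @param panel A `ChromosomePanel`.
#' @return Integer gain vector with the canonical string in attribute
#'   `"code"`.
#' @export
encode_subclone <- function(counts, sex, panel = default_panel()) {
  counts <- as.integer(counts)
  if (length(counts) != nrow(panel))
    stop("expected one copy-number count per panel chromosome")
  if (anyNA(counts))
    stop("cell is not informative: missing signal in one or more channels")
  if (any(counts < 0)) stop("copy-number counts must be non-negative")
  gains <- counts - constitutional_baseline(panel, sex)
  structure(gains, code = subclone_string(gains))
}

#' Encode all informative cells of a cell table
#'
#' @param cells A cell table as returned by [read_cell_table()].
#' @param sex "M" or "F" (one value, or one per row).
#' @param panel A `ChromosomePanel`.
#' @return The cell table with a `code` column holding the canonical subclone
#'   string for informative cells and `NA` otherwise.
#' @export
encode_cells <- function(cells, sex, panel = default_panel()) {
  counts <- as.matrix(cells[, panel$label, drop = FALSE])
  sex <- rep_len(sex, nrow(cells))
  code <- character(nrow(cells))
  for (s in unique(sex)) {
    base <- constitutional_baseline(panel, s)
    idx <- which(sex == s)
    gm <- sweep(counts[idx, , drop = FALSE], 2, base)
    code[idx] <- apply(gm, 1, function(g)
      if (anyNA(g)) NA_character_ else subclone_string(g))
  }
  cells$code <- code
  cells
}
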