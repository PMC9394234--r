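#' Parse a karyotype string (restricted ISCN dialect) into panel gains
#'
#' Handles the karyotype dialect seen in clinical cytogenetics reports of
#' hyperdiploid B-ALL: a modal chromosome number (possibly a range,
#' "52-56"), a sex-chromosome block with possible multiplication (XXY,
#' XXYY) that may be split across comma tokens ("54,X,+X,Y,..."),
#' comma-separated "+chr" gain tokens with optional "?" qualifiers ("+10?",
#' "+?X"), structural tokens (add/del/dup/inv/ins/der/t/mar/idem/inc) which
#' are ignored for gain counting, and clone separators "/" with cell counts
#' in square brackets.
#'
#' Only the FIRST abnormal clone is parsed (clinical tables print one major
#' karyotype line per case). A string consisting only of normal clones
#' ("46,XX"/"46,XY") and/or the annotation "High hyperdiploid by FISH" is
#' uninformative: the karyotype carries no usable gain vector.
#'
#' Gains are counted per panel chromosome: each "+N" (qualified or not) adds
#' one; the X gain is (number of X in the sex-chromosome block minus the
#' constitutional X count) plus the number of "+X" tokens.
#'
#' @param iscn Karyotype string.
#' @param sex "M" or "F"; if missing, inferred from the sex-chromosome block
#'   (a Y present implies male). If neither is available the parser refuses.
#' @param panel A `ChromosomePanel`.
#' @return A list of class `KaryotypeGains` with elements `informative`
#'   (logical), `gains` (named integer vector over panel chromosomes, or NULL
#'   when uninformative), `code` (canonical subclone string or NA), and
#'   `clone` (the clone text that was parsed).
#' @examples
#' parse_karyotype("55,XXY,+3,+4,+6,+10,+14,+18,+21,+21/46,XY", sex = "M")
#' @export
parse_karyotype <- function(iscn, sex = NA, panel = default_panel()) {
  stopifnot(is.character(iscn), length(iscn) == 1)
  txt <- iscn
  # normalize unicode dashes/minus and strip platform annotations
  txt <- gsub("[‐‑‒–—−]", "-", txt)
  txt <- gsub("\\(SNP6\\)", "", txt)
  clones <- strsplit(txt, "/", fixed = TRUE)[[1]]
  clones <- trimws(clones)

  uninformative <- function(clone_txt) {
    structure(list(informative = FALSE, gains = NULL, code = NA_character_,
                   clone = clone_txt), class = "KaryotypeGains")
  }

  parsed <- NULL
  for (cl in clones) {
    p <- parse_clone(cl)
    if (is.null(p)) next                      # "High hyperdiploid by FISH" etc.
    if (p$abnormal) { parsed <- p; break }
  }
  if (is.null(parsed)) return(uninformative(txt))

  if (is.na(sex) || !sex %in% c("M", "F")) {
    if (nchar(parsed$sex_block) > 0) {
      sex <- if (grepl("Y", parsed$sex_block)) "M" else "F"
    } else {
      stop("sex not recorded and no sex-chromosome block in karyotype; ",
           "refusing to guess the constitutional X baseline")
    }
  }
  const_x <- if (sex == "M") 1L else 2L

  gains <- stats::setNames(integer(nrow(panel)), panel$label)
  for (chr in names(parsed$plus)) {
    if (chr %in% panel$label) gains[chr] <- gains[chr] + parsed$plus[[chr]]
  }
  n_x_block <- lengths(regmatches(parsed$sex_block,
                                  gregexpr("X", parsed$sex_block)))
  if (nchar(parsed$sex_block) > 0) {
    gains["X"] <- gains["X"] + (n_x_block - const_x)
  }
  structure(list(informative = TRUE, gains = gains,
                 code = subclone_string(gains), clone = parsed$clone),
            class = "KaryotypeGains")
}

# Parse one clone; returns NULL for non-karyotype annotations, otherwise a
# list with the modal number, sex block, "+chr" gain counts and an
# `abnormal` flag (modal != 46 or any gain token).
parse_clone <- function(clone_txt) {
  if (grepl("hyperdiploid", clone_txt, ignore.case = TRUE)) return(NULL)
  cl <- gsub("\\[[^]]*\\]", "", clone_txt)    # drop cell-count brackets
  tokens <- trimws(strsplit(cl, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(NULL)

  modal_re <- "^([0-9]+(\\s*[-~]\\s*[0-9]+)?)\\s*([XY]*)$"
  if (!grepl(modal_re, tokens[1]))
    stop("unparseable modal/sex block: \"", tokens[1], "\"")
  modal <- as.integer(sub(modal_re, "\\1",
                          sub("\\s*[-~].*$", "", tokens[1])))
  sex_block <- sub(modal_re, "\\3", tokens[1])
  rest <- tokens[-1]

  # pure sex-chromosome tokens extend the sex block ("54,X,+X,Y,...")
  is_sex <- grepl("^[XY]+$", rest)
  sex_block <- paste0(sex_block, paste(rest[is_sex], collapse = ""))
  rest <- rest[!is_sex]

  gain_re <- "^\\+\\??([0-9]+|[XY])\\??$"
  plus_tokens <- rest[grepl(gain_re, rest)]
  plus_chr <- sub(gain_re, "\\1", plus_tokens)
  plus <- if (length(plus_chr)) table(plus_chr) else table(character(0))

  list(clone = clone_txt, modal = modal, sex_block = sex_block,
       plus = as.list(plus),
       abnormal = (!is.na(modal) && modal != 46L) || length(plus_chr) > 0)
}

#' @export
print.KaryotypeGains <- function(x, ...) {
  if (!x$informative) cat("KaryotypeGains: uninformative\n")
  else cat("KaryotypeGains:", x$code, "\n")
  invisible(x)
}

#' Concordance between karyotype-derived and iFISH major-clone gains
#'
#' For each case, the karyotype string is parsed and its panel gain vector is
#' compared with the major subclone code observed by single-cell iFISH. A
#' case is concordant iff the karyotype is informative and equals the major
#' clone on all panel chromosomes; uninformative or missing karyotypes are
#' non-concordant.
#'
#' @param records Data frame with columns `karyotype`, `sex` and
#'   `fish_major_clone` (canonical subclone strings). Typically
#'   [discovery_cohort()].
#' @param panel A `ChromosomePanel`.
#' @return A list with `table` (per-case karyotype code and match flag),
#'   `n_concordant` and `n_total`.
#' @export
karyotype_concordance <- function(records, panel = default_panel()) {
  stopifnot(all(c("karyotype", "sex", "fish_major_clone") %in% names(records)))
  codes <- character(nrow(records))
  match <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    k <- records$karyotype[i]
    if (is.na(k) || !nzchar(k)) { codes[i] <- NA; match[i] <- FALSE; next }
    kg <- parse_karyotype(k, sex = records$sex[i], panel = panel)
    codes[i] <- kg$code
    match[i] <- kg$informative &&
      identical(unname(kg$gains), subclone_gains(records$fish_major_clone[i]))
  }
  out <- data.frame(case = if ("case" %in% names(records)) records$case
                    else seq_len(nrow(records)),
                    karyotype_code = codes,
                    fish_major_clone = records$fish_major_clone,
                    concordant = match, stringsAsFactors = FALSE)
  list(table = out, n_concordant = sum(match), n_total = nrow(out))
}
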