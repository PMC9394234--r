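#' Tabulate subclones of a sample
#'
#' Counts hyperdiploid blasts by exact subclone code and derives the clone
#' frequency distribution, the major clone and its percentage (PMC), and the
#' Shannon entropy in bits. The major clone is the most frequent code; ties
#' are broken deterministically by the lexicographically smallest code and
#' flagged.
#'
#' @param blasts Filtered blast table (with a `code` column), or a character
#'   vector of subclone codes.
#' @return An object of class `ClonalDistribution`: a list with `counts`
#'   (named integer vector, decreasing), `n` (total blasts), `freq`,
#'   `major`, `pmc` (percent), `entropy` (bits), `tie` (logical).
#' @export
tabulate_clones <- function(blasts) {
  codes <- if (is.character(blasts)) blasts else blasts$code
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("no blasts to tabulate")
  counts <- table(codes)
  counts <- stats::setNames(as.integer(counts), names(counts))
  new_clonal_distribution(counts, sum(counts))
}

new_clonal_distribution <- function(counts, n) {
  ord <- order(-counts, names(counts))   # decreasing count, lexicographic ties
  counts <- counts[ord]
  freq <- if (n > 0) counts / n else counts * NA_real_
  major <- if (length(counts)) names(counts)[1] else NA_character_
  tie <- length(counts) > 1 && counts[1] == counts[2]
  structure(list(counts = counts, n = n, freq = freq, major = major,
                 pmc = if (length(counts)) unname(freq[1]) * 100 else NA_real_,
                 entropy = shannon_entropy(counts), tie = tie),
            class = "ClonalDistribution")
}

#' @export
print.ClonalDistribution <- function(x, ...) {
  cat("ClonalDistribution:", length(x$counts), "clones over", x$n, "blasts\n")
  cat("  major clone", x$major, sprintf("(PMC %.2f%%)", x$pmc),
      if (isTRUE(x$tie)) "[tie]" else "", "\n")
  cat(sprintf("  Shannon entropy %.3f bits\n", x$entropy))
  invisible(x)
}

#' Shannon entropy of a clone-frequency distribution
#'
#' H = -sum(P_i * log2(P_i)), with 0 * log 0 taken as 0. A sample dominated
#' by one clone has H = 0; K equally frequent clones have H = log2(K).
#'
#' @param x A `ClonalDistribution`, or a numeric vector of counts or
#'   frequencies (normalized internally).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))  # 1.5 bits
#' @export
shannon_entropy <- function(x) {
  p <- if (inherits(x, "ClonalDistribution")) as.numeric(x$counts) else
    as.numeric(x)
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Per-chromosome gain rates and trisomy/tetrasomy split
#'
#' Marginal fraction of blasts gaining each chromosome (gain >= 1), split
#' into trisomy (gain 1), tetrasomy (gain 2) and higher contributions, plus
#' the histogram of total gains per cell.
#'
#' @param blasts Blast table with a `code` column, or character vector of
#'   codes.
#' @param panel A `ChromosomePanel`.
#' @return List of class `TrisomyProfile` with `rates` (data frame:
#'   `chromosome`, `gain_pct`, `trisomy_pct`, `tetrasomy_pct`, `higher_pct`),
#'   `total_gain_hist` (named vector), `n` cells.
#' @export
gain_rates <- function(blasts, panel = default_panel()) {
  codes <- if (is.character(blasts)) blasts else blasts$code
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("no blasts")
  gm <- t(vapply(codes, subclone_gains, integer(nrow(panel))))
  n <- nrow(gm)
  rates <- data.frame(
    chromosome = panel$label,
    gain_pct = 100 * colMeans(gm >= 1),
    trisomy_pct = 100 * colMeans(gm == 1),
    tetrasomy_pct = 100 * colMeans(gm == 2),
    higher_pct = 100 * colMeans(gm > 2),
    stringsAsFactors = FALSE)
  total <- rowSums(gm > 0)
  structure(list(rates = rates,
                 total_gain_hist = table(factor(total, levels = 0:nrow(panel))),
                 n = n),
            class = "TrisomyProfile")
}

#' Fraction of blasts simultaneously gaining a set of chromosomes
#'
#' E.g. the triple-trisomy fraction for chromosomes 4, 10 and 17, or the
#' single-trisomy-18 fraction, irrespective of other gains.
#'
#' @param blasts Blast table or character vector of codes.
#' @param chromosomes Non-empty subset of panel labels.
#' @param panel A `ChromosomePanel`.
#' @return Percentage of blasts with gain >= 1 on every listed chromosome.
#' @export
combined_trisomy_fraction <- function(blasts, chromosomes,
                                      panel = default_panel()) {
  if (!length(chromosomes)) stop("chromosome set must be non-empty")
  bad <- setdiff(as.character(chromosomes), panel$label)
  if (length(bad))
    stop("chromosome(s) outside the panel: ", paste(bad, collapse = ", "))
  codes <- if (is.character(blasts)) blasts else blasts$code
  codes <- codes[!is.na(codes)]
  gm <- t(vapply(codes, subclone_gains, integer(nrow(panel))))
  colnames(gm) <- panel$label
  idx <- match(as.character(chromosomes), panel$label)
  100 * mean(apply(gm[, idx, drop = FALSE] >= 1, 1, all))
}

#' Two-group comparison of per-sample statistics
#'
#' Two-sided t-test (unpaired by default, paired on request) with group
#' means and standard errors, for comparing e.g. entropies or trisomy rates
#' between outcome groups.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param groups Factor/character with exactly two levels (unpaired), or
#'   ignored when `paired = TRUE` and `values2` given.
#' @param paired Paired test over (values, values2)?
#' @param values2 Second member of each pair when `paired = TRUE`.
#' @return List with `means`, `sem`, `statistic`, `p_value`, `paired`.
#' @export
compare_groups <- function(values, groups = NULL, paired = FALSE,
                           values2 = NULL) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  if (paired) {
    if (is.null(values2) || length(values2) != length(values))
      stop("paired comparison needs matched values2 of equal length")
    if (length(values) < 2) stop("need at least 2 pairs")
    d <- values - values2
    if (stats::sd(d) == 0) {
      # degenerate constant difference: certain at 0, impossible otherwise
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(values, values2, paired = TRUE)
    }
    list(means = c(mean(values), mean(values2)),
         sem = c(sem(values), sem(values2)),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         paired = TRUE)
  } else {
    g <- factor(groups)
    if (nlevels(g) != 2) stop("need exactly two groups")
    if (any(table(g) < 2)) stop("need at least 2 samples per group")
    sp <- split(values, g)
    tt <- stats::t.test(sp[[1]], sp[[2]])
    list(means = stats::setNames(vapply(sp, mean, 0), names(sp)),
         sem = stats::setNames(vapply(sp, sem, 0), names(sp)),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         paired = FALSE)
  }
}
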