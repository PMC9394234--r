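#' Estimate per-chromosome false gain/loss rates from diploid controls
#'
#' Control nuclei come from constitutionally diploid donors, so any apparent
#' gain or loss is a hybridization artifact. The observed artifact rate per
#' chromosome and direction anchors the binomial positivity cutoffs.
#'
#' @param cells Cell table of informative control cells (copy-number
#'   columns per panel chromosome).
#' @param sex "M" or "F" for the control donor (one value or per row).
#' @param panel A `ChromosomePanel`.
#' @return Data frame with columns `chromosome`, `direction` ("gain"/"loss"),
#'   `errors`, `n`, `rate`.
#' @export
estimate_error_rates <- function(cells, sex, panel = default_panel()) {
  counts <- as.matrix(cells[, panel$label, drop = FALSE])
  keep <- !apply(is.na(counts), 1, any)
  counts <- counts[keep, , drop = FALSE]
  n <- nrow(counts)
  if (n == 0) stop("no informative control cells")
  sex <- rep_len(sex, nrow(cells))[keep]
  base <- vapply(sex, function(s) constitutional_baseline(panel, s),
                 integer(nrow(panel)))
  gains <- t(counts) > base
  losses <- t(counts) < base
  data.frame(
    chromosome = rep(panel$label, 2),
    direction = rep(c("gain", "loss"), each = nrow(panel)),
    errors = c(rowSums(gains), rowSums(losses)),
    n = n,
    rate = c(rowSums(gains), rowSums(losses)) / n,
    stringsAsFactors = FALSE)
}

#' Binomial positivity cutoff
#'
#' Given a control artifact rate `p`, the cutoff is the minimal count `k*`
#' such that Pr[Binomial(n, p) >= k*] < alpha: observing at least `k*`
#' aberrant cells among `n` is unlikely to be noise alone. The tail is
#' computed exactly (no normal approximation). For `p = 0` any single
#' observation exceeds the null, so `k* = 1`.
#'
#' @param p Control error rate in [0, 1).
#' @param n Number of cells scored.
#' @param alpha Tail significance level (default 0.05).
#' @return A list with `k` (minimal count) and `cutoff` (fraction `k`/`n`).
#' @examples
#' binomial_cutoff(0.0037, 200, 0.05)  # k = 3, cutoff 1.5%
#' @export
binomial_cutoff <- function(p, n, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  if (p < 0 || p >= 1)
    stop("control rate p must lie in [0, 1)")
  if (p == 0) return(list(k = 1L, cutoff = 1 / n))
  # upper tail Pr[X >= k] = 1 - F(k - 1); exact in pbinom
  tail <- 1 - stats::pbinom(0:n, n, p)   # tail[k] = Pr[X >= k]
  k <- which(tail < alpha)[1]
  list(k = as.integer(k), cutoff = k / n)
}

#' Build a cutoff table for all panel chromosomes and both directions
#'
#' @param rates Data frame from [estimate_error_rates()] (pooled over the
#'   control samples).
#' @param n_cells Number of cells the cutoff will be applied to.
#' @param alpha Tail significance level; optionally Bonferroni-corrected
#'   over the 8 x 2 chromosome/direction tests.
#' @param bonferroni Apply Bonferroni correction (default FALSE).
#' @return `rates` with extra columns `k` and `cutoff`.
#' @export
cutoff_table <- function(rates, n_cells, alpha = 0.05, bonferroni = FALSE) {
  a <- if (bonferroni) alpha / nrow(rates) else alpha
  cut <- t(vapply(rates$rate, function(p) {
    b <- binomial_cutoff(p, n_cells, a)
    c(b$k, b$cutoff)
  }, numeric(2)))
  rates$k <- as.integer(cut[, 1])
  rates$cutoff <- cut[, 2]
  rates
}

#' Filter cells to informative hyperdiploid blasts
#'
#' Keeps cells that are informative on every channel and carry at least one
#' chromosome gain (the operational definition of a hyperdiploid blast).
#' Losses alone do not qualify. Excluded cells are returned with a reason
#' code.
#'
#' @param cells Encoded cell table (from [encode_cells()], with a `code`
#'   column) or a cell table plus `sex` to encode on the fly.
#' @param sex Required when `cells` has no `code` column.
#' @param panel A `ChromosomePanel`.
#' @return List with `blasts` (retained rows) and `excluded` (rows plus a
#'   `reason` column: "missing-signal" or "no-gain").
#' @export
filter_cells <- function(cells, sex = NULL, panel = default_panel()) {
  if (!"code" %in% names(cells)) {
    if (is.null(sex)) stop("cells are not encoded; supply sex")
    cells <- encode_cells(cells, sex, panel)
  }
  has_gain <- vapply(cells$code, function(cd) {
    if (is.na(cd)) return(FALSE)
    any(subclone_gains(cd) > 0)
  }, logical(1))
  reason <- ifelse(is.na(cells$code), "missing-signal",
                   ifelse(has_gain, NA_character_, "no-gain"))
  list(blasts = cells[is.na(reason), , drop = FALSE],
       excluded = cbind(cells[!is.na(reason), , drop = FALSE],
                        reason = reason[!is.na(reason)]))
}

#' Sample-level QC on blast counts
#'
#' A sample passes QC iff it contributes at least `min_blasts` informative
#' hyperdiploid blasts (default 200).
#'
#' @param blasts Filtered blast table for one sample.
#' @param min_blasts Minimum informative hyperdiploid nuclei.
#' @return List with `pass` (logical) and `n_blasts`.
#' @export
qc_sample <- function(blasts, min_blasts = 200) {
  n <- nrow(blasts)
  list(pass = !is.null(n) && n >= min_blasts, n_blasts = if (is.null(n)) 0L else n)
}

#' Filter a clonal distribution by the calibrated cutoffs
#'
#' A subclone is retained iff, for every non-zero aneusomy digit it carries,
#' the marginal frequency of that chromosome/direction aberration across the
#' sample exceeds the corresponding cutoff; subclones whose defining
#' aberrations all fall within noise range are removed. Retained clones are a
#' subset of the input; frequencies are renormalized only on request, so the
#' major-clone percentage stays comparable across filter settings.
#'
#' @param dist A `ClonalDistribution` (see [tabulate_clones()]).
#' @param cutoffs Data frame from [cutoff_table()].
#' @param renormalize Recompute frequencies over retained cells (default
#'   FALSE).
#' @param panel A `ChromosomePanel`.
#' @return A filtered `ClonalDistribution`; removed clones are reported in
#'   attribute `"removed"`.
#' @export
apply_cutoffs <- function(dist, cutoffs, renormalize = FALSE,
                          panel = default_panel()) {
  codes <- names(dist$counts)
  gm <- t(vapply(codes, subclone_gains, integer(nrow(panel))))
  freqs <- dist$counts / dist$n
  # marginal frequency of each chromosome/direction aberration in the sample
  marg_gain <- colSums(freqs * (gm > 0))
  marg_loss <- colSums(freqs * (gm < 0))
  cut_of <- function(chr, dir) {
    i <- which(cutoffs$chromosome == chr & cutoffs$direction == dir)
    if (!length(i)) stop("no cutoff for chromosome ", chr, " (", dir, ")")
    cutoffs$cutoff[i[1]]
  }
  gain_cut <- vapply(panel$label, cut_of, numeric(1), dir = "gain")
  loss_cut <- vapply(panel$label, cut_of, numeric(1), dir = "loss")
  keep <- vapply(seq_along(codes), function(i) {
    g <- gm[i, ]
    all(marg_gain[g > 0] > gain_cut[g > 0]) &&
      all(marg_loss[g < 0] > loss_cut[g < 0])
  }, logical(1))
  removed <- dist$counts[!keep]
  counts <- dist$counts[keep]
  n <- if (renormalize) sum(counts) else dist$n
  out <- new_clonal_distribution(counts, n)
  attr(out, "removed") <- removed
  out
}
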