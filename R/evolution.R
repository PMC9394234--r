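#' Match diagnosis-relapse sample pairs by patient
#'
#' @param samples Data frame with `patient_id` and `timepoint` ("DX"/"REL")
#'   columns (one row per sample).
#' @return List with `pairs` (data frame `patient_id`, `dx_row`, `rel_row`
#'   giving row indices into `samples`) and `unmatched` (patient ids with
#'   only one timepoint).
#' @export
match_pairs <- function(samples) {
  if (!nrow(samples))
    return(list(pairs = data.frame(patient_id = character(0),
                                   dx_row = integer(0), rel_row = integer(0)),
                unmatched = character(0)))
  dup <- duplicated(samples[, c("patient_id", "timepoint")])
  if (any(dup))
    stop("duplicate timepoint for patient ",
         samples$patient_id[dup][1])
  ids <- unique(samples$patient_id)
  dx <- match(paste(ids, "DX"), paste(samples$patient_id, samples$timepoint))
  rel <- match(paste(ids, "REL"), paste(samples$patient_id, samples$timepoint))
  ok <- !is.na(dx) & !is.na(rel)
  list(pairs = data.frame(patient_id = ids[ok], dx_row = dx[ok],
                          rel_row = rel[ok], stringsAsFactors = FALSE),
       unmatched = ids[!ok])
}

#' Classify the clonal-evolution pattern of a diagnosis-relapse pair
#'
#' Two patterns are distinguished at relapse: major leukemic clones shared
#' between diagnosis and relapse, or a large clonal replacement. The default
#' decision rule calls "shared" iff at least one of the top-k diagnosis
#' clones (by frequency) reappears among the top-k relapse clones, and
#' "replacement" otherwise. The call is invariant to total cell counts and
#' to clone relabeling.
#'
#' @param dx,rel `ClonalDistribution`s of the matched samples.
#' @param k Number of top clones compared (default 3).
#' @return List of class `EvolutionPattern`: `pattern`
#'   ("shared"/"replacement"), `k`, `shared_clones`, `overlap_mass`
#'   (summed DX frequency of clones also present anywhere at REL),
#'   `major_persists`, `entropy_change` (REL minus DX, bits).
#' @export
classify_evolution <- function(dx, rel, k = 3) {
  stopifnot(inherits(dx, "ClonalDistribution"),
            inherits(rel, "ClonalDistribution"))
  top <- function(d) utils::head(names(d$counts), k)
  shared <- intersect(top(dx), top(rel))
  common <- intersect(names(dx$counts), names(rel$counts))
  structure(list(
    pattern = if (length(shared)) "shared" else "replacement",
    k = k,
    shared_clones = shared,
    overlap_mass = sum(dx$freq[common]),
    major_persists = dx$major %in% names(rel$counts),
    entropy_change = rel$entropy - dx$entropy), class = "EvolutionPattern")
}

#' @export
print.EvolutionPattern <- function(x, ...) {
  cat("EvolutionPattern:", x$pattern, sprintf("(top-%d rule)", x$k), "\n")
  invisible(x)
}

#' Paired diagnosis-relapse shifts in gain rates and entropy
#'
#' Per-chromosome differences in gain rates (REL minus DX) across matched
#' pairs, with a paired t-test per chromosome, and the paired entropy
#' comparison. With fewer than two pairs only descriptive output is
#' returned.
#'
#' @param dx_profiles,rel_profiles Lists of `TrisomyProfile`s, aligned by
#'   patient.
#' @param dx_entropy,rel_entropy Numeric vectors of per-sample entropies,
#'   aligned with the profiles.
#' @return List with `gain_shift` (data frame `chromosome`, `mean_diff`,
#'   `p_value`) and `entropy_test` (result of [compare_groups()] with
#'   `paired = TRUE`, or NULL when untestable).
#' @export
paired_gain_shift <- function(dx_profiles, rel_profiles,
                              dx_entropy = NULL, rel_entropy = NULL) {
  stopifnot(length(dx_profiles) == length(rel_profiles))
  n <- length(dx_profiles)
  rates <- function(p) stats::setNames(p$rates$gain_pct, p$rates$chromosome)
  dxm <- t(vapply(dx_profiles, rates, rates(dx_profiles[[1]])))
  relm <- t(vapply(rel_profiles, rates, rates(rel_profiles[[1]])))
  diff <- relm - dxm
  gain_shift <- data.frame(
    chromosome = colnames(diff),
    mean_diff = colMeans(diff),
    p_value = if (n >= 2) apply(diff, 2, function(d)
      if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value)
      else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  entropy_test <- NULL
  if (!is.null(dx_entropy) && n >= 2) {
    entropy_test <- if (stats::sd(rel_entropy - dx_entropy) == 0)
      list(means = c(mean(dx_entropy), mean(rel_entropy)),
           statistic = 0, p_value = 1, paired = TRUE)
    else compare_groups(dx_entropy, paired = TRUE, values2 = rel_entropy)
  }
  list(gain_shift = gain_shift, entropy_test = entropy_test, n_pairs = n)
}
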