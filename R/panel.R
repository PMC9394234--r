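#' Chromosome panel for sequential iFISH
#'
#' The eight chromosomes typically gained in high-hyperdiploid B-ALL, in the
#' fixed order used throughout for subclone codes: X, 4, 6, 10, 14, 17, 18, 21.
#' Each chromosome carries its enumeration probe and the hybridization round
#' (1-3) in which it is scored.
#'
#' @param labels Character vector of unique chromosome labels.
#' @param probes Character vector of probe names, same length as `labels`.
#' @param rounds Integer vector of hybridization round indices in 1..3.
#' @return A data frame of class `ChromosomePanel` with columns `label`,
#'   `probe`, `round`.
#' @examples
#' default_panel()
#' @export
chromosome_panel <- function(labels, probes, rounds) {
  stopifnot(length(labels) == length(probes), length(labels) == length(rounds))
  if (anyDuplicated(labels)) stop("chromosome labels must be unique")
  rounds <- as.integer(rounds)
  if (!all(rounds %in% 1:3)) stop("hybridization round index must be 1, 2 or 3")
  structure(
    data.frame(label = as.character(labels), probe = as.character(probes),
               round = rounds, stringsAsFactors = FALSE),
    class = c("ChromosomePanel", "data.frame"))
}

#' @rdname chromosome_panel
#' @export
default_panel <- function() {
  chromosome_panel(
    labels = c("X", "4", "6", "10", "14", "17", "18", "21"),
    probes = c("DXZ1", "CEP4", "D6Z1", "CEP10", "D14S1420", "D17Z1", "D18Z1",
               "LSI21"),
    rounds = c(2L, 1L, 1L, 1L, 3L, 2L, 2L, 3L))
}

#' Constitutional copy-number baseline for a panel
#'
#' Autosomes have a constitutional copy number of 2; chromosome X has 1 in
#' males and 2 in females. Gains in subclone codes are expressed relative to
#' this baseline.
#'
#' @param panel A `ChromosomePanel`.
#' @param sex "M" or "F".
#' @return Integer vector of baseline copy numbers, one per panel chromosome.
#' @export
constitutional_baseline <- function(panel = default_panel(), sex) {
  if (missing(sex) || is.na(sex) || !sex %in% c("M", "F"))
    stop("sex must be \"M\" or \"F\" (needed for the X baseline)")
  ifelse(panel$label == "X", if (sex == "M") 1L else 2L, 2L)
}
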