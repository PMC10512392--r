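# Chemogenomics-based synergy prediction: if drug A's single-agent profile
# sensitizes the deletion mutant of drug B's target, A and B are predicted
# to be synergistic when combined.

#' Predict synergistic drug pairs from chemogenomic profiles
#'
#' For each profile of drug A and every other mapped drug B, a prediction
#' (A, B, via target(B)) is emitted when target(B) scores at or above
#' `threshold` in A's profile and the two drugs do not share that target.
#' Unordered duplicates (A,B predicted from both directions) are collapsed
#' keeping the direction with the stronger rationale score; ties break
#' lexicographically by drug name.
#'
#' @param profiles Long tibble `drug`, `gene`, `score` (log2 control/
#'   treatment ratio, or robust Z when `threshold` is on the Z scale).
#' @param target_map Tibble `drug`, `target`.
#' @param threshold Sensitivity threshold on `score` (default 1, i.e. a
#'   two-fold depletion on the log2 scale; use 2 for Z-scored profiles).
#' @return Tibble `drug_a`, `drug_b`, `via_gene`, `rationale` sorted by
#'   descending rationale.
#' @export
predict_pairs <- function(profiles, target_map, threshold = 1) {
  need <- c("drug", "gene", "score")
  if (!all(need %in% names(profiles))) {
    abort("`profiles` must have columns drug, gene, score.",
          class = "synergyscreen_invalid_input")
  }
  universe <- unique(profiles$gene)
  missing_t <- filter(target_map, !(.data$target %in% universe))
  if (nrow(missing_t)) {
    warn(paste0("Target gene absent from the profile universe; skipping drug(s): ",
                paste(missing_t$drug, collapse = ", ")))
    target_map <- filter(target_map, .data$target %in% universe)
  }
  own <- setNames(target_map$target, target_map$drug)
  hits <- profiles |>
    filter(.data$score >= threshold) |>
    inner_join(select(target_map, drug_b = "drug", gene = "target"),
               by = "gene", relationship = "many-to-many") |>
    rename(drug_a = "drug", via_gene = "gene", rationale = "score") |>
    filter(.data$drug_a != .data$drug_b,
           is.na(own[.data$drug_a]) | .data$via_gene != own[.data$drug_a])
  if (!nrow(hits)) {
    return(tibble(drug_a = character(), drug_b = character(),
                  via_gene = character(), rationale = numeric()))
  }
  hits |>
    mutate(lo = pmin(.data$drug_a, .data$drug_b),
           hi = pmax(.data$drug_a, .data$drug_b)) |>
    group_by(.data$lo, .data$hi) |>
    arrange(dplyr::desc(.data$rationale), .data$drug_a, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("drug_a", "drug_b", "via_gene", "rationale") |>
    arrange(dplyr::desc(.data$rationale), .data$drug_a, .data$drug_b)
}

#' Number of unordered drug pairs
#'
#' `(n^2 - n) / 2` candidate combinations from `n` compounds.
#'
#' @param n Number of compounds.
#' @return Pair count (vectorized).
#' @examples
#' pair_count(11) # 55
#' pair_count(15) # 105
#' @export
pair_count <- function(n) {
  stopifnot(all(n >= 0))
  (n^2 - n) / 2
}

#' Fold enrichment of a hit rate over a background rate
#'
#' `(hits / tested) / (bg_hits / bg_tested)`, e.g. the synergy rate among
#' predicted pairs over the synergy rate among random pairs.
#'
#' @param hits,tested Hits and trials in the focal set.
#' @param bg_hits,bg_tested Hits and trials in the background set.
#' @return The fold enrichment.
#' @export
fold_enrichment <- function(hits, tested, bg_hits, bg_tested) {
  if (tested <= 0 || bg_tested <= 0) {
    abort("`tested` and `bg_tested` must be positive.",
          class = "synergyscreen_invalid_input")
  }
  if (bg_hits <= 0) {
    abort("Zero background rate: fold enrichment undefined.",
          class = "synergyscreen_undefined_enrichment")
  }
  (hits / tested) / (bg_hits / bg_tested)
}
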