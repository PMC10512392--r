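# Drug-gene interaction calling on heterozygote fitness tables: negative
# (aggravating) interactions at a fitness-defect cutoff, partition into
# expected (known-target) and novel, and hypergeometric enrichment of a
# predicted interaction set.

#' Packaged heterozygote fitness table
#'
#' The published 10 x 11 matrix of relative fitness (1.0 = wild-type-like
#' growth) of heterozygous deletion mutants of known drug targets, each
#' challenged with each of the 11 screened compounds. The act1 heterozygote
#' is absent: it showed a significant fitness defect without drug and was
#' excluded before analysis, leaving 110 drug-gene tests.
#'
#' @param long Return the long form (`mutant`, `drug`, `fitness`; default)
#'   or the wide published layout.
#' @return A tibble.
#' @export
het_fitness_table <- function(long = TRUE) {
  path <- system.file("extdata", "heterozygote_fitness.tsv",
                      package = "synergyscreen", mustWork = TRUE)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!long) return(wide)
  pivot_longer(wide, -"mutant", names_to = "drug", values_to = "fitness")
}

#' Packaged compound-to-target map
#'
#' The 11 screened compounds with their known primary yeast target genes
#' and the method by which each target was established.
#'
#' @return Tibble `drug`, `target`, `method`.
#' @export
drug_target_map <- function() {
  path <- system.file("extdata", "drug_targets.tsv",
                      package = "synergyscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

validate_fitness <- function(fitness) {
  need <- c("mutant", "drug", "fitness")
  if (!is.data.frame(fitness) || !all(need %in% names(fitness))) {
    abort("`fitness` must have columns mutant, drug, fitness.",
          class = "synergyscreen_invalid_input")
  }
  if (anyNA(fitness$fitness) || any(fitness$fitness < 0)) {
    abort("Fitness values must be complete and non-negative.",
          class = "synergyscreen_invalid_input")
  }
  as_tibble(fitness)
}

#' Call negative drug-gene interactions
#'
#' A cell qualifies as a negative (aggravating) interaction when the
#' mutant's relative fitness falls at or below the cutoff. A fitness defect
#' of at least 10% corresponds to `cutoff = 0.90` with the inclusive rule
#' (`strict = FALSE`); a defect of more than 30% corresponds to
#' `cutoff = 0.70` with the exclusive rule (`strict = TRUE`).
#'
#' @param fitness Long fitness table (`mutant`, `drug`, `fitness`).
#' @param cutoff Fitness threshold in (0, 1] (default 0.90).
#' @param strict If `FALSE` (default) `fitness <= cutoff` qualifies; if
#'   `TRUE`, `fitness < cutoff`.
#' @return Tibble of qualifying cells (`mutant`, `drug`, `fitness`) with
#'   attributes `cutoff`, `strict`, `n_tested`.
#' @examples
#' calls <- call_negative(het_fitness_table(), cutoff = 0.90)
#' nrow(calls) # 76 negative interactions among the 110 tests
#' @export
call_negative <- function(fitness, cutoff = 0.90, strict = FALSE) {
  fitness <- validate_fitness(fitness)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    abort("`cutoff` must lie in (0, 1].", class = "synergyscreen_invalid_input")
  }
  hit <- if (strict) fitness$fitness < cutoff else fitness$fitness <= cutoff
  out <- fitness[hit, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  attr(out, "strict") <- strict
  attr(out, "n_tested") <- nrow(fitness)
  out
}

#' Partition interaction calls into expected and novel
#'
#' A call is "expected" when the sensitive mutant is the known target of
#' the drug that elicited it (the drug inhibiting the very product the
#' heterozygote is depleted for); all other calls are novel.
#'
#' @param calls Output of [call_negative()].
#' @param target_map Tibble `drug`, `target` (see [drug_target_map()]).
#' @return `calls` with an added `class` column (`"expected"` / `"novel"`).
#' @export
partition_expected <- function(calls, target_map = drug_target_map()) {
  if (!all(c("drug", "target") %in% names(target_map))) {
    abort("`target_map` must have columns drug and target.",
          class = "synergyscreen_invalid_input")
  }
  out <- calls |>
    left_join(select(target_map, "drug", "target"), by = "drug") |>
    mutate(class = if_else(!is.na(.data$target) & .data$mutant == .data$target,
                           "expected", "novel")) |>
    select(-"target")
  for (a in c("cutoff", "strict", "n_tested")) attr(out, a) <- attr(calls, a)
  out
}

#' Upper-tail hypergeometric enrichment
#'
#' Probability of drawing at least `overlap` sensitive cells when
#' `predicted` cells are drawn without replacement from a universe of
#' `universe` cells containing `sensitive` sensitive ones:
#' P(X >= overlap).
#'
#' @param overlap Observed overlap between the predicted and sensitive sets.
#' @param predicted Number of predicted cells (draws).
#' @param sensitive Number of sensitive cells in the universe (successes).
#' @param universe Total number of tested cells.
#' @return The enrichment p-value.
#' @export
hypergeom_enrichment <- function(overlap, predicted, sensitive, universe) {
  ok <- overlap >= 0 && predicted >= 0 && sensitive >= 0 &&
    overlap <= min(predicted, sensitive) &&
    max(predicted, sensitive) <= universe
  if (!ok) {
    abort("Counts must satisfy overlap <= min(predicted, sensitive) <= universe.",
          class = "synergyscreen_invalid_input")
  }
  phyper(overlap - 1, sensitive, universe - sensitive, predicted,
         lower.tail = FALSE)
}

#' Flag mutants with a drug-free fitness defect
#'
#' Data-preparation rule for tables that include a no-drug control column:
#' rows whose control fitness deviates from 1 by more than `tol` carry an
#' intrinsic (haploinsufficient) growth defect and should be excluded
#' before interaction calling.
#'
#' @param fitness Long fitness table including the control condition.
#' @param control_drug Name of the no-drug condition in `drug`.
#' @param tol Allowed deviation from 1 (default 0.2).
#' @return Tibble `mutant`, `control_fitness`, `exclude`.
#' @export
flag_baseline_defect <- function(fitness, control_drug = "control", tol = 0.2) {
  fitness <- validate_fitness(fitness)
  fitness |>
    filter(.data$drug == control_drug) |>
    mutate(exclude = abs(.data$fitness - 1) > tol) |>
    select("mutant", control_fitness = "fitness", "exclude")
}
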