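# HIP-HOP barcode-screen processing. A barcode intensity table is a long
# tibble with one row per array feature:
#   strain, tag ("up"/"down", or "ctrl" for control probes), replicate
#   (feature 1..5), intensity, array (hybridization id), batch (chip date),
#   treatment, essentiality ("het-essential"/"hom-nonessential", NA for
#   controls), is_control (logical).
# Pipeline order is fixed: saturation_correct -> quantile_normalize ->
# log2 -> snm_normalize -> select_tag -> robust_z.

intensity_cols <- c("strain", "tag", "replicate", "intensity",
                    "array", "batch", "treatment", "is_control")

validate_intensity <- function(t) {
  miss <- setdiff(intensity_cols, names(t))
  if (length(miss)) {
    abort(paste0("Intensity table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "synergyscreen_invalid_input")
  }
  if (!"essentiality" %in% names(t)) t$essentiality <- NA_character_
  if (anyNA(t$intensity) || any(t$intensity < 0)) {
    abort("Intensities must be complete and non-negative.",
          class = "synergyscreen_invalid_input")
  }
  as_tibble(t)
}

probe_matrix <- function(t) {
  wide <- t |>
    mutate(probe = paste(.data$strain, .data$tag, .data$replicate, sep = "\r")) |>
    select("probe", "array", "intensity") |>
    pivot_wider(names_from = "array", values_from = "intensity")
  if (anyNA(wide)) {
    abort("Arrays carry unequal probe sets; every array must have every probe.",
          class = "synergyscreen_invalid_input")
  }
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$probe
  m
}

matrix_to_long <- function(m, meta) {
  as_tibble(m, rownames = "probe") |>
    pivot_longer(-"probe", names_to = "array", values_to = "intensity") |>
    tidyr::separate_wider_delim("probe", "\r",
                                names = c("strain", "tag", "replicate")) |>
    mutate(replicate = as.integer(.data$replicate)) |>
    left_join(meta, by = "array")
}

array_meta <- function(t) {
  distinct(t, .data$array, .data$batch, .data$treatment)
}

probe_meta <- function(t) {
  distinct(t, .data$strain, .data$tag, .data$is_control, .data$essentiality)
}

rebuild <- function(m, t) {
  matrix_to_long(m, array_meta(t)) |>
    left_join(probe_meta(t), by = c("strain", "tag")) |>
    select(dplyr::all_of(c(intensity_cols, "essentiality")))
}

#' Correct feature intensities for hybridization saturation
#'
#' Inverts the hyperbolic transfer function of a saturating array feature:
#' an observed signal `x` below the ceiling is mapped to
#' `x * ceiling / (ceiling - x)` (the exact inverse of
#' `y = ceiling * s / (ceiling + s)`). Signals at or above 95% of the
#' ceiling cannot be inverted reliably: they are winsorized to the
#' correction at 0.95 * ceiling and flagged in a `saturated` column.
#'
#' @param t Barcode intensity table (linear scale).
#' @param ceiling Saturation ceiling; default 0.95 times the maximum
#'   observed feature intensity.
#' @return The table with corrected intensities and a `saturated` flag.
#' @export
saturation_correct <- function(t, ceiling = NULL) {
  t <- validate_intensity(t)
  ceiling <- ceiling %||% (0.95 * max(t$intensity))
  x <- t$intensity
  sat <- x >= 0.95 * ceiling
  xw <- pmin(x, 0.95 * ceiling)
  t$intensity <- xw * ceiling / (ceiling - xw)
  t$saturated <- sat
  t
}

#' Quantile-normalize arrays
#'
#' Maps every array's intensity distribution onto the mean order-statistic
#' profile across arrays so all hybridizations share one distribution;
#' within-array ranks are preserved. Backed by
#' [limma::normalizeQuantiles()].
#'
#' @param t Barcode intensity table; every array must carry the same probes.
#' @return The table with normalized intensities.
#' @export
quantile_normalize <- function(t) {
  t <- validate_intensity(t)
  m <- probe_matrix(t)
  if (ncol(m) < 2) {
    abort("Quantile normalization needs at least 2 arrays.",
          class = "synergyscreen_invalid_input")
  }
  rebuild(limma::normalizeQuantiles(m), t)
}

#' Log-transform intensities
#'
#' @param t Barcode intensity table (linear scale).
#' @param floor Small positive floor applied before `log2` (default 1).
#' @return The table with `intensity` on the log2 scale.
#' @export
log_intensities <- function(t, floor = 1) {
  t <- validate_intensity(t)
  t$intensity <- log2(pmax(t$intensity, floor))
  t
}

#' Supervised batch-effect removal
#'
#' Fits, per probe, an additive two-factor model of log intensity on
#' treatment plus batch (chip date) and subtracts the batch component,
#' leaving treatment effects untouched — the supervised-normalization
#' model, computed with [limma::removeBatchEffect()] supplied with the
#' treatment design matrix. A single batch is a no-op; a fully confounded
#' design (batch indistinguishable from treatment) is refused.
#'
#' @param t Barcode intensity table on the log scale.
#' @return The table with batch components removed.
#' @export
snm_normalize <- function(t) {
  t <- validate_intensity(t)
  meta <- array_meta(t)
  if (dplyr::n_distinct(meta$batch) < 2) {
    inform("Single batch: supervised normalization is a no-op.")
    return(t)
  }
  trt <- factor(meta$treatment)
  bat <- factor(meta$batch)
  X <- cbind(model.matrix(~trt), model.matrix(~bat)[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    abort(paste0("Batch is confounded with treatment (design rank ",
                 qr(X)$rank, " < ", ncol(X), "); cannot separate the effects."),
          class = "synergyscreen_confounded_design")
  }
  m <- probe_matrix(t)
  meta <- meta[match(colnames(m), meta$array), ]
  corrected <- limma::removeBatchEffect(
    m, batch = factor(meta$batch),
    design = model.matrix(~ factor(meta$treatment)))
  rebuild(corrected, t)
}

#' Select the quieter barcode per strain
#'
#' For each strain, keeps the tag (uptag or downtag) with the lower
#' coefficient of variation of its replicate features pooled over arrays;
#' ties go to the uptag, and a degenerate tag (non-positive mean signal)
#' is disqualified.
#'
#' @param t Barcode intensity table (control probes are ignored).
#' @return Tibble `strain`, `tag` (the selected tag per strain).
#' @export
select_tag <- function(t) {
  t <- validate_intensity(t)
  cv <- t |>
    filter(!.data$is_control) |>
    group_by(.data$strain, .data$tag) |>
    summarise(mu = mean(.data$intensity), cv = sd(.data$intensity) / .data$mu,
              .groups = "drop") |>
    mutate(cv = if_else(.data$mu <= 0, Inf, .data$cv))
  cv |>
    group_by(.data$strain) |>
    arrange(.data$cv, factor(.data$tag, levels = c("up", "down")),
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("strain", "tag")
}

#' Robust Z fitness-defect profile for one treatment
#'
#' Averages each strain's selected-tag features on the treatment's
#' array(s) and scores it against the control distribution:
#' `z = (center - x) / (1.4826 * MAD)`, center and MAD taken from the
#' control probes of the same array(s) (or, absent control probes, from
#' all strains of the same essentiality panel). Positive scores mean the
#' strain was depleted — a fitness defect.
#'
#' @param t Processed barcode intensity table (log scale, normalized).
#' @param profile_for Treatment label to profile.
#' @param tags Tag selection from [select_tag()]; computed from `t` when
#'   `NULL`.
#' @return A `screen_profile` tibble: `treatment`, `strain`,
#'   `essentiality`, `tag_used`, `intensity`, `z`.
#' @export
robust_z <- function(t, profile_for, tags = NULL) {
  t <- validate_intensity(t)
  if (!profile_for %in% t$treatment) {
    abort(paste0("No arrays for treatment '", profile_for, "'."),
          class = "synergyscreen_invalid_input")
  }
  tt <- filter(t, .data$treatment == profile_for)
  tags <- tags %||% select_tag(t)
  x <- tt |>
    filter(!.data$is_control) |>
    inner_join(tags, by = c("strain", "tag")) |>
    group_by(.data$strain, .data$essentiality, .data$tag) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    rename(tag_used = "tag")
  ctrl <- tt |>
    filter(.data$is_control) |>
    group_by(.data$strain) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop")
  zscore <- function(vals, ctrl_vals) {
    ctr <- median(ctrl_vals)
    scale <- mad(ctrl_vals, constant = 1.4826)
    if (scale == 0) {
      abort("Degenerate control scale: MAD is zero.",
            class = "synergyscreen_degenerate_scale")
    }
    (ctr - vals) / scale
  }
  if (nrow(ctrl) >= 3) {
    x$z <- zscore(x$intensity, ctrl$intensity)
  } else {
    inform("No control probes: falling back to the all-strain distribution per panel.")
    x <- x |>
      group_by(.data$essentiality) |>
      mutate(z = zscore(.data$intensity, .data$intensity)) |>
      ungroup()
  }
  out <- x |>
    mutate(treatment = profile_for) |>
    select("treatment", "strain", "essentiality", "tag_used", "intensity", "z") |>
    arrange(.data$strain)
  class(out) <- c("screen_profile", class(out))
  out
}

#' Run the full processing chain on a raw intensity table
#'
#' Applies, in order: saturation correction, quantile normalization, log2,
#' supervised batch removal, tag selection, and robust Z-scoring of every
#' treatment.
#'
#' @param t Raw barcode intensity table (linear scale).
#' @param ceiling Saturation ceiling (see [saturation_correct()]).
#' @return Named list of `screen_profile` tibbles, one per treatment.
#' @export
process_screens <- function(t, ceiling = NULL) {
  t <- saturation_correct(t, ceiling = ceiling)
  t <- quantile_normalize(t)
  t <- log_intensities(t)
  t <- snm_normalize(t)
  tags <- select_tag(t)
  trts <- unique(t$treatment)
  setNames(lapply(trts, function(tr) robust_z(t, tr, tags = tags)), trts)
}

#' Bundle the five screens of one combination assay
#'
#' A genome-wide synergy assay comprises five screens: the combination
#' (A+B), each single agent at its IC20, and each single agent at the dose
#' used in the combination.
#'
#' @param combo,a_ic20,a_combo,b_ic20,b_combo `screen_profile` tibbles.
#' @return A `combination_result` object.
#' @export
combination_result <- function(combo, a_ic20, a_combo, b_ic20, b_combo) {
  profs <- list(combo = combo, a_ic20 = a_ic20, a_combo = a_combo,
                b_ic20 = b_ic20, b_combo = b_combo)
  miss <- names(profs)[vapply(profs, is.null, logical(1))]
  if (length(miss)) {
    abort(paste0("Missing screen(s): ", paste(miss, collapse = ", "),
                 ". All five screens of the design are required."),
          class = "synergyscreen_invalid_input")
  }
  common <- Reduce(intersect, lapply(profs, function(p) p$strain))
  structure(list(profiles = profs, strains = common),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat("<combination_result> 5 screens,", length(x$strains), "common strains\n")
  invisible(x)
}

combo_z_table <- function(r) {
  stopifnot(inherits(r, "combination_result"))
  z_of <- function(p, nm) {
    p |> select("strain", "essentiality", z = "z") |> rename(!!nm := "z")
  }
  purrr::reduce(
    imap(r$profiles, function(p, nm) z_of(p, paste0("z_", nm))),
    ~ inner_join(.x, .y, by = c("strain", "essentiality"))) |>
    filter(.data$strain %in% r$strains)
}

#' Call combination-specific sensitive strains
#'
#' A strain is combination-specific when its fitness defect in the
#' combination screen is `threshold` (2.0) or greater while in each of the
#' four single-agent screens the defect stays strictly below the
#' threshold. Reported separately for the heterozygous-essential (HIP)
#' and homozygous-nonessential (HOP) panels via the `essentiality` column.
#'
#' @param r A `combination_result`.
#' @param threshold Z threshold (default 2.0; inclusive for the
#'   combination, exclusive for singles).
#' @return Tibble with per-strain Z-scores across the five screens and a
#'   logical `specific` column.
#' @export
combination_specific <- function(r, threshold = 2.0) {
  combo_z_table(r) |>
    mutate(specific = .data$z_combo >= threshold &
             .data$z_a_ic20 < threshold & .data$z_a_combo < threshold &
             .data$z_b_ic20 < threshold & .data$z_b_combo < threshold)
}

#' Combination sensitivity epsilon per strain
#'
#' Deviation of the combination fitness defect from the single-agent
#' expectation, with the single-agent scores taken from the combo-dose
#' screens. `mode = "product"` (default) uses
#' `eps = z_AB - z_A * z_B`; `mode = "sum"` uses
#' `eps = z_AB - (z_A + z_B)`.
#'
#' @param r A `combination_result`.
#' @param mode `"product"` or `"sum"`.
#' @return Tibble `strain`, `essentiality`, `eps`.
#' @export
sensitivity_epsilon <- function(r, mode = c("product", "sum")) {
  mode <- match.arg(mode)
  combo_z_table(r) |>
    mutate(eps = if (mode == "product") {
      .data$z_combo - .data$z_a_combo * .data$z_b_combo
    } else {
      .data$z_combo - (.data$z_a_combo + .data$z_b_combo)
    }) |>
    select("strain", "essentiality", "eps")
}

#' Full per-strain combination report
#'
#' Merges the five-screen Z-scores, the combination-specific call and both
#' sensitivity-epsilon variants into one table.
#'
#' @param r A `combination_result`.
#' @param threshold Passed to [combination_specific()].
#' @return Tibble with z columns, `specific`, `eps_product`, `eps_sum`.
#' @export
combination_report <- function(r, threshold = 2.0) {
  combination_specific(r, threshold) |>
    left_join(sensitivity_epsilon(r, "product") |> rename(eps_product = "eps"),
              by = c("strain", "essentiality")) |>
    left_join(sensitivity_epsilon(r, "sum") |> rename(eps_sum = "eps"),
              by = c("strain", "essentiality"))
}

#' Cluster profiles by Pearson correlation
#'
#' Distance is `1 - Pearson r` of the Z (or epsilon) vectors; strains and
#' treatments are clustered separately by average-linkage agglomeration.
#' Input rows are sorted by label first so the result is deterministic,
#' with ties broken by label order.
#'
#' @param x Long tibble `strain`, `treatment`, `value`, or a numeric
#'   matrix (strains x treatments).
#' @return A `profile_clustering` list: `strains` and `treatments`
#'   [stats::hclust] objects plus the data matrix.
#' @export
cluster_profiles <- function(x) {
  if (is.data.frame(x)) {
    need <- c("strain", "treatment", "value")
    if (!all(need %in% names(x))) {
      abort("Long input needs columns strain, treatment, value.",
            class = "synergyscreen_invalid_input")
    }
    m <- x |>
      pivot_wider(id_cols = "strain", names_from = "treatment",
                  values_from = "value") |>
      tibble::column_to_rownames("strain") |>
      as.matrix()
  } else {
    m <- as.matrix(x)
  }
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  cor_dist <- function(mm) {
    d <- 1 - suppressWarnings(cor(t(mm)))
    d[!is.finite(d)] <- 1
    as.dist(d)
  }
  structure(list(strains = hclust(cor_dist(m), method = "average"),
                 treatments = hclust(cor_dist(t(m)), method = "average"),
                 matrix = m),
            class = "profile_clustering")
}

#' Export a clustering as a Newick string
#'
#' @param clustering A `profile_clustering`.
#' @param what `"strains"` or `"treatments"`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when writing to file.
#' @export
clustering_newick <- function(clustering, what = c("strains", "treatments"),
                              path = NULL) {
  what <- match.arg(what)
  phy <- ape::as.phylo(clustering[[what]])
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
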