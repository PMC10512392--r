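# Checkerboard dose-matrix scoring: Bliss multiplicative epsilon and AvgS,
# plus the three confirmatory models (Loewe combination index, highest
# single agent, potentiation) and the four-model consensus call.

#' Build a dose matrix from long checkerboard data
#'
#' A dose matrix holds the relative-growth grid W for one drug pair: row
#' margin = drug A alone, column margin = drug B alone, both dose ladders
#' ascending from 0 (the no-drug corner, W = 1).
#'
#' @param data Long tibble with columns `dose_a`, `dose_b`, `w`.
#' @param drug_a,drug_b Drug names.
#' @return A `dose_matrix` object.
#' @export
dose_matrix <- function(data, drug_a = "A", drug_b = "B") {
  need <- c("dose_a", "dose_b", "w")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns dose_a, dose_b, w.",
          class = "synergyscreen_invalid_input")
  }
  doses_a <- sort(unique(data$dose_a))
  doses_b <- sort(unique(data$dose_b))
  wide <- data |>
    group_by(.data$dose_a, .data$dose_b) |>
    summarise(w = mean(.data$w), .groups = "drop")
  w <- matrix(NA_real_, length(doses_a), length(doses_b),
              dimnames = list(doses_a, doses_b))
  w[cbind(match(wide$dose_a, doses_a), match(wide$dose_b, doses_b))] <- wide$w
  new_dose_matrix(drug_a, drug_b, doses_a, doses_b, w)
}

new_dose_matrix <- function(drug_a, drug_b, doses_a, doses_b, w) {
  if (anyNA(w)) {
    abort("Dose matrix has missing cells (incomplete checkerboard).",
          class = "synergyscreen_invalid_matrix")
  }
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    abort("Dose ladders must start at 0 (the no-drug control).",
          class = "synergyscreen_invalid_matrix")
  }
  if (abs(w[1, 1] - 1) > 0.05) {
    abort("The no-drug corner W[0,0] must be 1 within 0.05.",
          class = "synergyscreen_invalid_matrix")
  }
  if (any(w < 0)) {
    abort("All W values must be non-negative.",
          class = "synergyscreen_invalid_matrix")
  }
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = doses_a, doses_b = doses_b, w = w),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("<dose_matrix> ", x$drug_a, " x ", x$drug_b, " (",
      length(x$doses_a), "x", length(x$doses_b), ")\n", sep = "")
  print(round(x$w, 3))
  invisible(x)
}

#' @rdname dose_matrix
#' @param x A `dose_matrix`.
#' @param ... Unused.
#' @export
tidy.dose_matrix <- function(x, ...) {
  expand_grid_wa_wb(x) |>
    select("dose_a", "dose_b", "w", "w_a", "w_b")
}

expand_grid_wa_wb <- function(m) {
  tidyr::expand_grid(i = seq_along(m$doses_a), j = seq_along(m$doses_b)) |>
    mutate(dose_a = m$doses_a[.data$i], dose_b = m$doses_b[.data$j],
           w = m$w[cbind(.data$i, .data$j)],
           w_a = m$w[cbind(.data$i, 1L)], w_b = m$w[cbind(1L, .data$j)])
}

#' Assemble a dose matrix from plate curves and a plate map
#'
#' Computes the inhibition ratio of every well against the dose-0/0 control
#' well and arranges the W values on the checkerboard grid. Curves are
#' smoothed first.
#'
#' @param plate Long growth data (`well`, `time`, `od`).
#' @param plate_map Plate map tibble (`well`, `drug_a`, `dose_a`, `drug_b`,
#'   `dose_b`).
#' @param window Smoothing window (points), passed to [smooth_curve()].
#' @return A `dose_matrix`.
#' @export
assemble_dose_matrix <- function(plate, plate_map, window = 5L) {
  plate <- smooth_curve(plate, window = window)
  ctrl_wells <- plate_map$well[plate_map$dose_a == 0 & plate_map$dose_b == 0]
  if (!length(ctrl_wells)) {
    abort("Plate map has no dose 0/0 control well.",
          class = "synergyscreen_invalid_matrix")
  }
  ctrl <- filter(plate, .data$well == ctrl_wells[1]) |> select("time", "od")
  ratios <- plate_map |>
    mutate(w = map_dbl(.data$well, function(wl) {
      crv <- filter(plate, .data$well == wl) |> select("time", "od")
      inhibition_ratio(crv, ctrl)$w
    }))
  dose_matrix(ratios, drug_a = plate_map$drug_a[1], drug_b = plate_map$drug_b[1])
}

#' Bliss multiplicative-model epsilon
#'
#' Under Bliss independence two non-interacting drugs combine
#' multiplicatively: expected combined growth is `w_a * w_b`. Epsilon is the
#' observed deviation, `w_ab - w_a * w_b`: negative means synergy, positive
#' antagonism, zero independence.
#'
#' @param w_a,w_b Single-agent relative growth (inhibition ratios).
#' @param w_ab Combined relative growth.
#' @return Epsilon (vectorized).
#' @examples
#' bliss_epsilon(0.9, 0.8, 0.5) # -0.22, a synergistic deviation
#' @export
bliss_epsilon <- function(w_a, w_b, w_ab) {
  w_ab - w_a * w_b
}

#' Epsilon matrix and AvgS for a dose matrix
#'
#' Applies [bliss_epsilon()] cellwise using the zero-dose row and column as
#' the single-agent margins. AvgS is the mean epsilon over the dual-drug
#' cells only (both doses > 0); margin cells are identically ~0 and would
#' dilute the score.
#'
#' @param m A `dose_matrix`.
#' @return An `epsilon_matrix` object (fields `eps`, `avg_s`, `min_eps`).
#' @export
epsilon_matrix <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  w <- m$w
  eps <- w - outer(w[, 1], w[1, ])
  dual <- eps[-1, -1, drop = FALSE]
  structure(list(drug_a = m$drug_a, drug_b = m$drug_b,
                 doses_a = m$doses_a, doses_b = m$doses_b,
                 eps = eps, avg_s = mean(dual), min_eps = min(dual)),
            class = "epsilon_matrix")
}

#' @export
print.epsilon_matrix <- function(x, ...) {
  cat("<epsilon_matrix> ", x$drug_a, " x ", x$drug_b,
      "  AvgS = ", signif(x$avg_s, 3),
      "  min eps = ", signif(x$min_eps, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname epsilon_matrix
#' @param x An `epsilon_matrix`.
#' @param ... Unused.
#' @export
tidy.epsilon_matrix <- function(x, ...) {
  tidyr::expand_grid(i = seq_along(x$doses_a), j = seq_along(x$doses_b)) |>
    mutate(dose_a = x$doses_a[.data$i], dose_b = x$doses_b[.data$j],
           eps = x$eps[cbind(.data$i, .data$j)],
           dual = .data$i > 1L & .data$j > 1L) |>
    select("dose_a", "dose_b", "eps", "dual")
}

#' @rdname epsilon_matrix
#' @export
glance.epsilon_matrix <- function(x, ...) {
  tibble(drug_a = x$drug_a, drug_b = x$drug_b,
         avg_s = x$avg_s, min_eps = x$min_eps,
         n_dual = (length(x$doses_a) - 1L) * (length(x$doses_b) - 1L))
}

#' Bliss synergy call
#'
#' `mode = "avg"` tests `AvgS < avg_threshold` (the 6x6 primary screens);
#' `mode = "min_cell"` tests the most synergistic dual-drug cell against
#' `cell_threshold` (the 4x4 background screens). Inequalities are strict.
#'
#' @param e An `epsilon_matrix`.
#' @param avg_threshold AvgS threshold (default -0.05).
#' @param cell_threshold Single-cell epsilon threshold (default -0.20).
#' @param mode `"avg"` or `"min_cell"`.
#' @return Logical.
#' @export
call_bliss <- function(e, avg_threshold = -0.05, cell_threshold = -0.20,
                       mode = c("avg", "min_cell")) {
  stopifnot(inherits(e, "epsilon_matrix"))
  mode <- match.arg(mode)
  if (mode == "avg") e$avg_s < avg_threshold else e$min_eps < cell_threshold
}

# First-crossing inverse interpolation of a single-agent margin: the dose
# (log-dose linear-effect) at which relative growth falls to `target`.
# Zero dose never enters the interpolation. NA when the margin never
# crosses the target going up the ladder.
dose_at_effect <- function(doses, w, target) {
  keep <- doses > 0
  d <- doses[keep]; ww <- w[keep]
  if (length(d) < 2) return(NA_real_)
  for (k in seq_len(length(d) - 1L)) {
    w1 <- ww[k]; w2 <- ww[k + 1L]
    if ((w1 - target) * (w2 - target) <= 0 && w1 != w2) {
      f <- (w1 - target) / (w1 - w2)
      return(exp(log(d[k]) + f * (log(d[k + 1L]) - log(d[k]))))
    }
  }
  if (ww[1] <= target) return(d[1])  # already past the target at the lowest dose
  NA_real_
}

#' Loewe additivity call via the combination index
#'
#' For every dual-drug cell whose combined growth `w_ab` reaches
#' `effect_cap` (default 0.8) or below, the combination index is
#' `CI = d_a / D_a(w_ab) + d_b / D_b(w_ab)`, where `D_x(w)` is the
#' single-agent dose producing growth `w`, interpolated log-dose/linear-
#' effect along that drug's margin. Under Loewe additivity CI = 1; the pair
#' is called synergistic when the median CI over evaluable cells falls
#' below `ci_threshold`.
#'
#' @param m A `dose_matrix`.
#' @param ci_threshold Median-CI cutoff (default 0.9).
#' @param effect_cap Only cells with `w_ab` at or below this level are
#'   evaluable (default 0.8).
#' @return Logical; `FALSE` with attribute `indeterminate = TRUE` (and a
#'   message) when no cell is evaluable.
#' @export
call_loewe <- function(m, ci_threshold = 0.9, effect_cap = 0.8) {
  stopifnot(inherits(m, "dose_matrix"))
  cells <- expand_grid_wa_wb(m) |> filter(.data$dose_a > 0, .data$dose_b > 0,
                                          .data$w <= effect_cap)
  ci <- map_dbl(seq_len(nrow(cells)), function(k) {
    tgt <- cells$w[k]
    da <- dose_at_effect(m$doses_a, m$w[, 1], tgt)
    db <- dose_at_effect(m$doses_b, m$w[1, ], tgt)
    if (is.na(da) || is.na(db)) return(NA_real_)
    cells$dose_a[k] / da + cells$dose_b[k] / db
  })
  ci <- ci[is.finite(ci)]
  if (!length(ci)) {
    inform("Loewe call indeterminate: no evaluable cell (treated as FALSE).")
    return(structure(FALSE, indeterminate = TRUE))
  }
  median(ci) < ci_threshold
}

#' Highest-single-agent call
#'
#' TRUE when any dual-drug cell beats the better of its two single agents
#' by more than `excess_threshold` growth units:
#' `min(w_a, w_b) - w_ab > excess_threshold`.
#'
#' @param m A `dose_matrix`.
#' @param excess_threshold Required excess over the best single agent
#'   (default 0.10).
#' @return Logical.
#' @export
call_hsa <- function(m, excess_threshold = 0.10) {
  stopifnot(inherits(m, "dose_matrix"))
  cells <- expand_grid_wa_wb(m) |> filter(.data$dose_a > 0, .data$dose_b > 0)
  any(pmin(cells$w_a, cells$w_b) - cells$w > excess_threshold)
}

#' Potentiation call (dose-shift model)
#'
#' TRUE when the midpoint (IC50-equivalent) dose of either drug, read off
#' its dose-response by log-dose interpolation, drops by at least
#' `shift_threshold`-fold in the presence of the lowest non-zero dose of
#' the partner. An axis whose response never brackets W = 0.5, or that runs
#' the wrong way (protective), is skipped; if both axes are skipped the
#' call is indeterminate and FALSE.
#'
#' @param m A `dose_matrix`.
#' @param shift_threshold Minimum fold-decrease of the midpoint dose
#'   (default 2).
#' @return Logical; attribute `indeterminate = TRUE` when no axis was
#'   evaluable.
#' @export
call_potentiation <- function(m, shift_threshold = 2.0) {
  stopifnot(inherits(m, "dose_matrix"))
  axis_fold <- function(doses, w_alone, w_with) {
    d0 <- dose_at_effect(doses, w_alone, 0.5)
    d1 <- dose_at_effect(doses, w_with, 0.5)
    if (is.na(d0) || is.na(d1)) return(NA_real_)
    d0 / d1
  }
  folds <- c(axis_fold(m$doses_a, m$w[, 1], m$w[, 2]),
             axis_fold(m$doses_b, m$w[1, ], m$w[2, ]))
  folds <- folds[is.finite(folds)]
  if (!length(folds)) {
    inform("Potentiation call indeterminate: no evaluable axis (treated as FALSE).")
    return(structure(FALSE, indeterminate = TRUE))
  }
  any(folds >= shift_threshold)
}

#' Four-model consensus synergy call
#'
#' Runs the Bliss, Loewe, highest-single-agent and potentiation calls and
#' reports their conjunction: a pair is classified synergistic only when it
#' deviates from expectation in all four models.
#'
#' @param m A `dose_matrix`.
#' @param avg_threshold,cell_threshold,mode Passed to [call_bliss()].
#' @param ci_threshold Passed to [call_loewe()].
#' @param excess_threshold Passed to [call_hsa()].
#' @param shift_threshold Passed to [call_potentiation()].
#' @return One-row tibble: `drug_a`, `drug_b`, `bliss`, `loewe`, `hsa`,
#'   `potentiation`, `consensus`, `avg_s`, `min_eps`.
#' @export
consensus_call <- function(m, avg_threshold = -0.05, cell_threshold = -0.20,
                           mode = c("avg", "min_cell"), ci_threshold = 0.9,
                           excess_threshold = 0.10, shift_threshold = 2.0) {
  stopifnot(inherits(m, "dose_matrix"))
  mode <- match.arg(mode)
  e <- epsilon_matrix(m)
  bliss <- call_bliss(e, avg_threshold, cell_threshold, mode)
  loewe <- as.logical(call_loewe(m, ci_threshold))
  hsa <- call_hsa(m, excess_threshold)
  pot <- as.logical(call_potentiation(m, shift_threshold))
  tibble(drug_a = m$drug_a, drug_b = m$drug_b,
         bliss = bliss, loewe = loewe, hsa = hsa, potentiation = pot,
         consensus = bliss && loewe && hsa && pot,
         avg_s = e$avg_s, min_eps = e$min_eps)
}

#' Transpose a dose matrix (swap drugs)
#'
#' @param m A `dose_matrix`.
#' @return The matrix with drugs A and B exchanged.
#' @export
transpose_dose_matrix <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  new_dose_matrix(m$drug_b, m$drug_a, m$doses_b, m$doses_a, t(m$w))
}

#' Read / write a dose-matrix TSV
#'
#' The on-disk dialect mirrors the checkerboard: first column holds drug A
#' doses, remaining column names hold drug B doses, cells hold W.
#'
#' @param path TSV path.
#' @param drug_a,drug_b Drug names (not stored in the grid file).
#' @return `read_dose_matrix()` a `dose_matrix`; `write_dose_matrix()` the
#'   input, invisibly.
#' @export
read_dose_matrix <- function(path, drug_a = "A", drug_b = "B") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  doses_a <- df[[1]]
  doses_b <- as.numeric(names(df)[-1])
  w <- as.matrix(df[, -1])
  dimnames(w) <- list(doses_a, doses_b)
  new_dose_matrix(drug_a, drug_b, doses_a, doses_b, w)
}

#' @rdname read_dose_matrix
#' @param m A `dose_matrix` (or `epsilon_matrix`, whose `eps` grid is
#'   written).
#' @export
write_dose_matrix <- function(m, path) {
  grid <- if (inherits(m, "epsilon_matrix")) m$eps else m$w
  df <- as_tibble(grid, .name_repair = "minimal")
  names(df) <- as.character(m$doses_b)
  df <- bind_cols(tibble(dose_a = m$doses_a), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(m)
}
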