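# Growth-curve reduction: smoothing, area under the curve, inhibition ratio,
# and average generation time. Times are minutes throughout; readers convert.

#' Validate a growth curve
#'
#' A growth curve is a data frame with numeric columns `time` (minutes,
#' strictly increasing) and `od` (OD600, non-negative), at least three rows.
#'
#' @param curve A data frame with columns `time` and `od`.
#' @return The curve as a tibble, invisibly usable downstream.
#' @keywords internal
validate_curve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time", "od") %in% names(curve))) {
    abort("`curve` must be a data frame with columns `time` and `od`.",
          class = "synergyscreen_invalid_input")
  }
  curve <- as_tibble(curve)
  if (nrow(curve) < 3) {
    abort("A growth curve needs at least 3 time points.",
          class = "synergyscreen_invalid_input")
  }
  if (any(!is.finite(curve$time)) || any(diff(curve$time) <= 0)) {
    abort("`time` must be finite and strictly increasing.",
          class = "synergyscreen_invalid_input")
  }
  if (any(!is.finite(curve$od)) || any(curve$od < 0)) {
    abort("`od` must be finite and non-negative.",
          class = "synergyscreen_invalid_input")
  }
  curve
}

roll_stat <- function(x, window, fun) {
  n <- length(x)
  half <- (window - 1L) / 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    fun(x[lo:hi])
  }, numeric(1))
}

#' Smooth a growth curve
#'
#' Centered moving median followed by a centered moving mean, both with
#' truncated windows at the edges. The median stage removes single-read
#' spikes (a common plate-reader artifact); the mean stage reduces residual
#' noise before integration.
#'
#' @param curve A growth curve (columns `time`, `od`; a `well` column, if
#'   present, is smoothed per well).
#' @param window Odd window size in points (default 5).
#' @return The curve with `od` replaced by its smoothed values.
#' @examples
#' crv <- tibble::tibble(time = seq(0, 135, by = 15),
#'                       od = c(0.1, 0.1, 0.6, 0.1, 0.1, 0.2, 0.3, 0.5, 0.7, 0.8))
#' smooth_curve(crv, window = 3)
#' @export
smooth_curve <- function(curve, window = 5L) {
  if (!is.data.frame(curve)) {
    abort("`curve` must be a data frame.", class = "synergyscreen_invalid_input")
  }
  if ("well" %in% names(curve) && dplyr::n_distinct(curve$well) > 1L) {
    return(curve |>
             group_by(.data$well) |>
             dplyr::group_modify(~ smooth_curve(.x, window = window)) |>
             ungroup())
  }
  curve <- validate_curve(curve)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L || window > nrow(curve)) {
    abort("`window` must be an odd integer between 1 and the curve length.",
          class = "synergyscreen_invalid_input")
  }
  od <- roll_stat(curve$od, window, median)
  od <- roll_stat(od, window, mean)
  curve$od <- pmax(od, 0)
  curve
}

auc_trapezoid <- function(time, od, baseline) {
  pracma::trapz(time, pmax(od - baseline, 0))
}

#' Area under a growth curve
#'
#' Trapezoidal integral of `max(od - baseline, 0)` over time. The default
#' baseline is the first OD reading of the well, which removes the blank and
#' inoculum offset.
#'
#' @param curve A growth curve (columns `time`, `od`; optional `well`).
#' @param baseline Non-negative OD offset; `NULL` (default) uses the first
#'   reading per well.
#' @return A tibble with one row per well (`well`, `area`), or a single-row
#'   tibble with `area` if no `well` column is present. Units: OD.min.
#' @export
curve_auc <- function(curve, baseline = NULL) {
  if (!is.null(baseline) && baseline < 0) {
    abort("`baseline` must be non-negative.", class = "synergyscreen_invalid_input")
  }
  one <- function(df) {
    df <- validate_curve(df)
    b <- baseline %||% df$od[1]
    tibble(area = auc_trapezoid(df$time, df$od, b))
  }
  if ("well" %in% names(curve)) {
    curve |>
      group_by(.data$well) |>
      dplyr::group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(curve)
  }
}

#' Inhibition ratio of a treated well against its no-drug control
#'
#' W = AUC(drug) / AUC(control), each integrated over the common time span
#' with its own first-reading baseline. W near 1 means unimpeded growth, 0
#' means complete inhibition; values slightly above 1 indicate stimulation.
#'
#' @param drug_curve,control_curve Growth curves (columns `time`, `od`).
#' @param w_max Upper cap for plausible W (values above are kept but flagged
#'   downstream by dose-matrix validation); default 1.2.
#' @return One-row tibble: `w`, `area_drug`, `area_control`.
#' @export
inhibition_ratio <- function(drug_curve, control_curve, w_max = 1.2) {
  drug_curve <- validate_curve(drug_curve)
  control_curve <- validate_curve(control_curve)
  lo <- max(min(drug_curve$time), min(control_curve$time))
  hi <- min(max(drug_curve$time), max(control_curve$time))
  ctrl_span <- diff(range(control_curve$time))
  if ((hi - lo) < 0.9 * ctrl_span) {
    abort("Drug and control curves overlap less than 90% of the control span.",
          class = "synergyscreen_invalid_input")
  }
  clip <- function(df) filter(df, .data$time >= lo, .data$time <= hi)
  d <- clip(drug_curve)
  c0 <- clip(control_curve)
  area_drug <- auc_trapezoid(d$time, d$od, d$od[1])
  area_control <- auc_trapezoid(c0$time, c0$od, c0$od[1])
  if (area_control <= 1e-6) {
    abort("Control AUC is at the degenerate floor (<= 1e-6 OD.min).",
          class = "synergyscreen_degenerate_control")
  }
  tibble(w = area_drug / area_control,
         area_drug = area_drug, area_control = area_control)
}

#' Average generation time from a smoothed growth curve
#'
#' Works on `log2(od - baseline + floor)` versus time. The log-phase span is
#' bracketed by the two inflection points around the maximal-slope region:
#' walking out from the global maximum of the first finite difference, the
#' start is the zero-crossing that ends the positive-curvature (lag-exit)
#' hump and the end is the zero-crossing where curvature turns negative as
#' the culture decelerates into stationary phase. AvgG is the elapsed time
#' divided by the number of doublings across that span (minutes/doubling).
#'
#' The default `baseline` is 0: the OD reading is itself the biomass
#' observable, and subtracting the first reading would remove the living
#' inoculum and destroy the early log-linearity the metric relies on. Pass
#' the medium blank as `baseline` if the plate was not blank-corrected
#' upstream.
#'
#' @param curve A smoothed growth curve (columns `time`, `od`; optional
#'   `well`, processed per well).
#' @param baseline Non-growing OD offset (medium blank) subtracted before
#'   taking logs; default 0.
#' @param floor Tiny positive guard added before taking logs so wells that
#'   touch the baseline stay finite (default 1e-6).
#' @param min_rise Minimum OD rise above the first reading to count as
#'   growth (default 0.05); below it `status = "no_growth"`.
#' @return Tibble with columns `avg_g` (min/doubling), `inflection_start`,
#'   `inflection_end` (minutes) and `status` in `ok`, `no_growth`,
#'   `censored` (one row per well).
#' @export
avg_generation_time <- function(curve, baseline = 0, floor = 1e-6,
                                min_rise = 0.05) {
  one <- function(df) {
    df <- validate_curve(df)
    if (max(df$od) - df$od[1] < min_rise) {
      return(tibble(avg_g = NA_real_, inflection_start = NA_real_,
                    inflection_end = NA_real_, status = "no_growth"))
    }
    y <- log2(pmax(df$od - baseline, 0) + floor)
    t <- df$time
    d1 <- diff(y) / diff(t)                    # slope between points i, i+1
    d2 <- diff(d1)                             # curvature at interior points
    m <- which.max(d1)                         # earliest index on ties
    if (!any(is.finite(d2)) || max(abs(d2)) == 0) {
      return(tibble(avg_g = NA_real_, inflection_start = NA_real_,
                    inflection_end = NA_real_, status = "censored"))
    }
    # d2[k] sits between slope segments k and k+1; segment m is the peak.
    # Numeric-zero thresholds are scaled per side so an edge artifact on
    # one flank cannot mask the gentle curvature on the other.
    # Start: end of the last positive-curvature run at or before the peak.
    before <- d2[seq_len(max(m - 1L, 0L))]
    eps_start <- 0.05 * max(c(before, 0))
    pos <- which(before > eps_start & before > 0)
    start_seg <- if (length(pos)) max(pos) + 1L else 1L
    # End: first clearly negative curvature after the peak.
    after_idx <- which(seq_along(d2) >= m)
    eps_end <- 0.05 * max(c(-d2[after_idx], 0))
    neg <- after_idx[d2[after_idx] < -eps_end & d2[after_idx] < 0]
    end_seg <- if (length(neg)) min(neg) + 1L else length(d1) + 1L
    i0 <- start_seg            # point index opening the log-linear span
    i1 <- min(end_seg, length(t))
    if (i1 <= i0 || (y[i1] - y[i0]) <= 0) {
      return(tibble(avg_g = NA_real_, inflection_start = NA_real_,
                    inflection_end = NA_real_, status = "censored"))
    }
    tibble(avg_g = (t[i1] - t[i0]) / (y[i1] - y[i0]),
           inflection_start = t[i0], inflection_end = t[i1], status = "ok")
  }
  if ("well" %in% names(curve)) {
    curve |>
      group_by(.data$well) |>
      dplyr::group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(curve)
  }
}

as_avg_g <- function(x) {
  if (is.data.frame(x)) {
    list(avg_g = x$avg_g[1], status = x$status[1])
  } else {
    list(avg_g = as.numeric(x), status = "ok")
  }
}

#' Relative fitness of a heterozygous mutant under drug
#'
#' Normalizes the mutant's drug response to wild type so any baseline
#' haploinsufficient growth defect cancels:
#' `fitness = (wt_drug / mut_drug) / (wt_ctrl / mut_ctrl)` on AvgG values.
#' 1.0 means no drug-gene interaction; values below 1 mean the mutant is
#' hypersensitive to the drug.
#'
#' @param mut_drug,mut_ctrl,wt_drug,wt_ctrl AvgG results: either numeric
#'   minutes/doubling, or one-row tibbles from [avg_generation_time()].
#' @return One-row tibble `fitness`, `flagged` (`TRUE` when a no-growth
#'   input forced fitness to 0).
#' @export
relative_fitness <- function(mut_drug, mut_ctrl, wt_drug, wt_ctrl) {
  parts <- lapply(list(mut_drug, mut_ctrl, wt_drug, wt_ctrl), as_avg_g)
  if (any(vapply(parts, function(p) identical(p$status, "no_growth"), logical(1)))) {
    warn("A no-growth input propagates as fitness 0.")
    return(tibble(fitness = 0, flagged = TRUE))
  }
  if (any(vapply(parts, function(p) !identical(p$status, "ok") ||
                   !is.finite(p$avg_g) || p$avg_g <= 0, logical(1)))) {
    abort("All four AvgG inputs must have status 'ok' and positive avg_g.",
          class = "synergyscreen_invalid_input")
  }
  g <- vapply(parts, function(p) p$avg_g, numeric(1))
  tibble(fitness = (g[3] / g[1]) / (g[4] / g[2]), flagged = FALSE)
}

#' Read a plate-reader export
#'
#' Accepts the long dialect (columns `well`, `time_min`, `od600`) or a wide
#' dialect with a time column (`time`, `time_min` or `Time`) and one column
#' per well. Returns a long tibble with columns `well`, `time`, `od`.
#'
#' @param path CSV file path.
#' @return Long tibble `well`, `time` (minutes), `od`.
#' @export
read_plate <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(df))
  if (all(c("well", "time_min", "od600") %in% nm)) {
    names(df) <- nm
    out <- df |> select(well = "well", time = "time_min", od = "od600")
  } else {
    tcol <- which(nm %in% c("time", "time_min"))[1]
    if (is.na(tcol)) {
      abort("Plate file is neither long (well,time_min,od600) nor wide with a time column.",
            class = "synergyscreen_invalid_input")
    }
    out <- df |>
      rename(time = names(df)[tcol]) |>
      pivot_longer(-"time", names_to = "well", values_to = "od") |>
      select("well", "time", "od")
  }
  arrange(out, .data$well, .data$time)
}

#' Read a plate map
#'
#' TSV with columns `well`, `drug_a`, `dose_a`, `drug_b`, `dose_b` binding
#' wells to checkerboard conditions (dose 0/0 marks the no-drug control).
#'
#' @param path TSV file path.
#' @return Tibble with the five columns above.
#' @export
read_plate_map <- function(path) {
  pm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("well", "drug_a", "dose_a", "drug_b", "dose_b")
  miss <- setdiff(need, names(pm))
  if (length(miss)) {
    abort(paste0("Plate map is missing column(s): ", paste(miss, collapse = ", ")),
          class = "synergyscreen_invalid_input")
  }
  bad <- which(!is.finite(pm$dose_a) | !is.finite(pm$dose_b) |
                 pm$dose_a < 0 | pm$dose_b < 0)
  if (length(bad)) {
    abort(paste0("Plate map row ", bad[1], " (well ", pm$well[bad[1]],
                 ") has an invalid dose."),
          class = "synergyscreen_invalid_input")
  }
  pm
}
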