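# Synthetic-data generators with known ground truth for every stage:
# checkerboard growth curves with a planted Bliss deviation, five-screen
# barcode intensity tables with spiked combination-specific strains, and
# chemogenomic prediction worlds with planted synergy structure.

#' Configuration for the synthetic generators
#'
#' Collects every tunable of the three generators with defaults matching
#' the screening designs the package analyzes: 96 OD600 readings at 15-min
#' spacing (24 h), 6x6 checkerboards on an IC0/2/5/10/20/50 inhibition
#' ladder, and five-screen barcode assays of 200 strains with 10 features
#' per strain (2 tags x 5 replicate features) in 2 chip-date batches.
#'
#' @param seed Mandatory integer seed; every generator is deterministic
#'   given the config.
#' @param ... Overrides of the defaults listed below.
#' @return A `synth_config` list.
#' @section Growth/checkerboard defaults:
#' `n_timepoints = 96`, `dt = 15` (min), `inhibition_targets =
#' c(0, .02, .05, .10, .20, .50)` (the IC ladder), `hill_slope_a/b = 2`,
#' `ic50_a = 1`, `ic50_b = 2` (arbitrary dose units), `delta = 0` (planted
#' Bliss deviation on the growth-ratio scale, clamped to keep W in
#' [0, 1.2]), `od_noise_sd = 0` (additive OD noise), `od0 = 0.0625`
#' (inoculum), `capacity = 1.0`, `growth_rate = log(2)/90` (per min),
#' `t_mid = 600` (min).
#' @section Barcode-screen defaults:
#' `n_strains = 200`, `n_spikes = 20`, `spike_z = 4` (planted combination
#' fitness defect in robust-Z units; one unit is the control-probe-level
#' scale), `n_controls = 40`, `base_mean = 10`, `base_sd = 0.15` (log2
#' strain abundance spread), `ctrl_sd = 0.5` (control-probe spread),
#' `tag_sd = 0.1`, `feature_sd = 0.4` (per-feature hybridization noise),
#' `batch_shifts = c(0, 0.5)` (log2 units; one replicate array set per
#' batch), `slow_frac = 0.15` and `slow_depth = c(1.3, 3.5)` (fraction and
#' log2 depth range of low-abundance slow-growing pool strains, present in
#' every screen), `n_single_sensitive = 15` with `single_depth_ic20 = 2.5`
#' and `single_depth_combo = 1` (per-drug sensitive strains, in Z units),
#' `saturation_ceiling = 60000`, `apply_saturation = TRUE`,
#' `spike_leak_screen = NULL` (optionally also deplete spikes in one named
#' single-agent screen).
#' @section Prediction-world defaults:
#' `n_drugs = 8`, `n_extra_genes = 40`, `n_true_pairs = 6`,
#' `decoy_rate = 0`, `score_high = 3`, `score_noise_sd = 0.2`.
#' @export
synth_config <- function(seed, ...) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("A numeric `seed` is mandatory for reproducibility.",
          class = "synergyscreen_invalid_input")
  }
  cfg <- list(
    seed = as.integer(seed),
    # growth / checkerboard
    n_timepoints = 96L, dt = 15, inhibition_targets = c(0, .02, .05, .10, .20, .50),
    hill_slope_a = 2, hill_slope_b = 2, ic50_a = 1, ic50_b = 2,
    delta = 0, od_noise_sd = 0, od0 = 0.0625, capacity = 1.0,
    growth_rate = log(2) / 90, t_mid = 600,
    # barcode screens
    n_strains = 200L, n_spikes = 20L, spike_z = 4, n_controls = 40L,
    base_mean = 10, base_sd = 0.15, ctrl_sd = 0.5, tag_sd = 0.1,
    feature_sd = 0.4, batch_shifts = c(0, 0.5),
    slow_frac = 0.15, slow_depth = c(1.3, 3.5),
    n_single_sensitive = 15L, single_depth_ic20 = 2.5,
    single_depth_combo = 1.0,
    saturation_ceiling = 60000, apply_saturation = TRUE,
    spike_leak_screen = NULL,
    # prediction world
    n_drugs = 8L, n_extra_genes = 40L, n_true_pairs = 6L,
    decoy_rate = 0, score_high = 3, score_noise_sd = 0.2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown synth_config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "synergyscreen_invalid_input")
  }
  cfg[names(dots)] <- dots
  scales <- c("dt", "base_sd", "ctrl_sd", "feature_sd", "capacity",
              "growth_rate", "saturation_ceiling")
  if (any(vapply(cfg[scales], function(v) any(v <= 0), logical(1)))) {
    abort("All scale parameters must be positive.",
          class = "synergyscreen_invalid_input")
  }
  structure(cfg, class = "synth_config")
}

with_cfg_seed <- function(cfg, offset, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(code)
}

hill_dose <- function(w_target, ic50, slope) {
  # inverse of W(d) = 1 / (1 + (d/ic50)^slope); w_target = 1 gives dose 0
  ifelse(w_target >= 1, 0, ic50 * (1 / w_target - 1)^(1 / slope))
}

#' Generate a checkerboard of growth curves with a planted Bliss deviation
#'
#' Builds Hill single-agent dose ladders hitting the configured inhibition
#' targets, plants the interaction on the growth-ratio scale —
#' `W(da, db) = W_a(da) * W_b(db) + delta` on dual-drug cells, clamped to
#' [0, 1.2] — and renders each well as a logistic OD600 curve whose growth
#' amplitude is scaled by W (shared shape across wells, so the planted
#' deviation is exactly recoverable through the AUC/inhibition-ratio
#' pipeline), plus additive Gaussian OD noise.
#'
#' @param cfg A [synth_config()].
#' @return List: `curves` (long `well`, `time`, `od`), `plate_map`,
#'   `w_true` (the planted W grid), `truth` (the planted delta).
#' @export
gen_dose_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  w_targets <- 1 - cfg$inhibition_targets
  doses_a <- hill_dose(w_targets, cfg$ic50_a, cfg$hill_slope_a)
  doses_b <- hill_dose(w_targets, cfg$ic50_b, cfg$hill_slope_b)
  n <- length(w_targets)
  w_true <- outer(w_targets, w_targets)
  w_true[-1, -1] <- pmin(pmax(w_true[-1, -1] + cfg$delta, 0), 1.2)
  times <- seq(0, by = cfg$dt, length.out = cfg$n_timepoints)
  sigma <- function(t) 1 / (1 + exp(-cfg$growth_rate * (t - cfg$t_mid)))
  shape <- (sigma(times) - sigma(0)) / (1 - sigma(0))
  grid <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
    mutate(well = sprintf("w%02d", row_number()),
           dose_a = doses_a[.data$i], dose_b = doses_b[.data$j],
           w = w_true[cbind(.data$i, .data$j)])
  curves <- with_cfg_seed(cfg, 0L, {
    grid |>
      mutate(curve = map(.data$w, function(wv) {
        od <- cfg$od0 + wv * (cfg$capacity - cfg$od0) * shape
        if (cfg$od_noise_sd > 0) {
          od <- pmax(od + rnorm(length(od), 0, cfg$od_noise_sd), 0)
        }
        tibble(time = times, od = od)
      })) |>
      select("well", "curve") |>
      unnest("curve")
  })
  plate_map <- grid |>
    mutate(drug_a = "drugA", drug_b = "drugB") |>
    select("well", "drug_a", "dose_a", "drug_b", "dose_b")
  list(curves = curves, plate_map = plate_map, w_true = w_true,
       truth = cfg$delta)
}

screen_roles <- c("combo", "a_ic20", "a_combo", "b_ic20", "b_combo")

#' Generate a five-screen barcode intensity table with spiked strains
#'
#' Emulates one genome-wide combination assay: the A+B screen plus the
#' four single-agent screens, each hybridized once per chip-date batch.
#' Strain abundances are lognormal; each strain carries 10 features (up
#' and down tags x 5 replicate features); batches add log-scale shifts;
#' control probes span a wider calibration distribution. Spiked strains
#' are depleted, in the combination screen only, by `spike_z` control-
#' scale units — exactly the quantity the combination-specific gate
#' measures. Optionally the features pass through the saturating transfer
#' function that [saturation_correct()] inverts.
#'
#' @param cfg A [synth_config()].
#' @return List: `table` (barcode intensity table covering all five
#'   screens), `roles` (treatment labels in design order), `truth`
#'   (tibble of spiked strains).
#' @export
gen_combination_screens <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_cfg_seed(cfg, 1L, {
    strains <- sprintf("strain%03d", seq_len(cfg$n_strains))
    ess <- rep(c("het-essential", "hom-nonessential"),
               length.out = cfg$n_strains)
    spikes <- sort(sample(seq_len(cfg$n_strains), cfg$n_spikes))
    base <- rnorm(cfg$n_strains, cfg$base_mean, cfg$base_sd)
    # low-abundance strains: the pool's slow growers, depleted to the same
    # depth range in every screen (spikes are drawn from well-represented
    # strains -- an absent strain cannot be scored combination-specific)
    n_slow <- round(cfg$slow_frac * cfg$n_strains)
    slow <- sample(setdiff(seq_len(cfg$n_strains), spikes), n_slow)
    base[slow] <- base[slow] -
      runif(n_slow, cfg$slow_depth[1], cfg$slow_depth[2])
    tag_off <- matrix(rnorm(cfg$n_strains * 2, 0, cfg$tag_sd),
                      ncol = 2, dimnames = list(strains, c("up", "down")))
    ctrl_names <- sprintf("ctrl%03d", seq_len(cfg$n_controls))
    ctrl_base <- rnorm(cfg$n_controls, cfg$base_mean, cfg$ctrl_sd)
    n_batches <- length(cfg$batch_shifts)
    arrays <- tidyr::expand_grid(treatment = screen_roles,
                                 batch_i = seq_len(n_batches)) |>
      mutate(array = paste0(.data$treatment, "_rep", .data$batch_i),
             batch = paste0("chip", .data$batch_i),
             shift = cfg$batch_shifts[.data$batch_i])
    # one robust-Z unit equals the control-probe-level scale: probe spread
    # plus feature noise averaged over 5 replicates x n_batches arrays
    z_unit <- sqrt(cfg$ctrl_sd^2 + cfg$feature_sd^2 / (5 * n_batches))
    # strains genuinely sensitive to each single agent: depleted at IC20
    # depth in that drug's IC20 screen, shallower at the combo dose and in
    # the combination (which contains the drug at its combo dose)
    pool <- setdiff(seq_len(cfg$n_strains), c(spikes, slow))
    sens_a <- sample(pool, min(cfg$n_single_sensitive, length(pool)))
    sens_b <- sample(setdiff(pool, sens_a),
                     min(cfg$n_single_sensitive, length(setdiff(pool, sens_a))))
    depletion <- function(trt, idx) {
      d <- numeric(length(idx))
      hit <- idx %in% spikes
      if (trt == "combo") d[hit] <- cfg$spike_z * z_unit
      if (!is.null(cfg$spike_leak_screen) && trt == cfg$spike_leak_screen) {
        d[hit] <- cfg$spike_z * z_unit
      }
      ia <- idx %in% sens_a
      ib <- idx %in% sens_b
      if (trt == "a_ic20") d[ia] <- d[ia] + cfg$single_depth_ic20 * z_unit
      if (trt == "b_ic20") d[ib] <- d[ib] + cfg$single_depth_ic20 * z_unit
      if (trt %in% c("a_combo", "combo")) {
        d[ia] <- d[ia] + cfg$single_depth_combo * z_unit
      }
      if (trt %in% c("b_combo", "combo")) {
        d[ib] <- d[ib] + cfg$single_depth_combo * z_unit
      }
      d
    }
    one_array <- function(trt, arr, bat, shift) {
      sgrid <- tidyr::expand_grid(idx = seq_len(cfg$n_strains),
                                  tag = c("up", "down"),
                                  replicate = 1:5)
      slog <- base[sgrid$idx] +
        tag_off[cbind(sgrid$idx, match(sgrid$tag, c("up", "down")))] +
        shift - depletion(trt, sgrid$idx) +
        rnorm(nrow(sgrid), 0, cfg$feature_sd)
      cgrid <- tidyr::expand_grid(idx = seq_len(cfg$n_controls),
                                  replicate = 1:5)
      clog <- ctrl_base[cgrid$idx] + shift + rnorm(nrow(cgrid), 0, cfg$feature_sd)
      bind_rows(
        tibble(strain = strains[sgrid$idx], tag = sgrid$tag,
               replicate = sgrid$replicate, intensity = 2^slog,
               essentiality = ess[sgrid$idx], is_control = FALSE),
        tibble(strain = ctrl_names[cgrid$idx], tag = "ctrl",
               replicate = cgrid$replicate, intensity = 2^clog,
               essentiality = NA_character_, is_control = TRUE)) |>
        mutate(array = arr, batch = bat, treatment = trt)
    }
    tab <- pmap(list(arrays$treatment, arrays$array, arrays$batch,
                     arrays$shift), one_array) |>
      bind_rows()
    if (cfg$apply_saturation) {
      cc <- cfg$saturation_ceiling
      tab$intensity <- cc * tab$intensity / (cc + tab$intensity)
    }
    list(table = tab, roles = screen_roles,
         truth = tibble(strain = strains[spikes],
                        essentiality = ess[spikes]))
  })
}

#' Generate a chemogenomic prediction world
#'
#' Plants the prediction signal exactly where the method looks: for each
#' true synergistic pair (A, B), the target gene of B scores high in A's
#' single-agent profile. Decoy sensitivities on other drugs' targets are
#' added at `decoy_rate` to degrade precision in a controlled way.
#'
#' @param cfg A [synth_config()].
#' @return List: `profiles` (long `drug`, `gene`, `score`), `target_map`,
#'   `truth` (tibble of true unordered pairs).
#' @export
gen_prediction_world <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_cfg_seed(cfg, 2L, {
    drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
    targets <- sprintf("gene%02d", seq_len(cfg$n_drugs))
    genes <- c(targets, sprintf("bg%03d", seq_len(cfg$n_extra_genes)))
    target_map <- tibble(drug = drugs, target = targets)
    all_pairs <- if (cfg$n_drugs >= 2) {
      as_tibble(t(combn(drugs, 2)), .name_repair = ~ c("drug_a", "drug_b"))
    } else {
      tibble(drug_a = character(), drug_b = character())
    }
    n_true <- min(cfg$n_true_pairs, nrow(all_pairs))
    truth <- all_pairs[sample(nrow(all_pairs), n_true), , drop = FALSE] |>
      arrange(.data$drug_a, .data$drug_b)
    profiles <- tidyr::expand_grid(drug = drugs, gene = genes) |>
      mutate(score = rnorm(n(), 0, cfg$score_noise_sd))
    plant <- function(profiles, a, g) {
      mutate(profiles, score = if_else(
        .data$drug == a & .data$gene == g,
        cfg$score_high + rnorm(1, 0, cfg$score_noise_sd), .data$score))
    }
    for (k in seq_len(nrow(truth))) {
      profiles <- plant(profiles, truth$drug_a[k],
                        targets[match(truth$drug_b[k], drugs)])
    }
    if (cfg$decoy_rate > 0) {
      cand <- tidyr::expand_grid(drug_a = drugs, drug_b = drugs) |>
        filter(.data$drug_a != .data$drug_b) |>
        anti_join(bind_rows(truth, rename(truth, drug_a = "drug_b",
                                          drug_b = "drug_a")),
                  by = c("drug_a", "drug_b")) |>
        filter(runif(n()) < cfg$decoy_rate)
      for (k in seq_len(nrow(cand))) {
        profiles <- plant(profiles, cand$drug_a[k],
                          targets[match(cand$drug_b[k], drugs)])
      }
    }
    list(profiles = profiles, target_map = target_map, truth = truth)
  })
}
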