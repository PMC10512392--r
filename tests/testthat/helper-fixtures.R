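# Shared builders for in-code fixtures.

hill_w <- function(d, ic50 = 1, slope = 2) 1 / (1 + (d / ic50)^slope)

hill_dose_for <- function(w, ic50 = 1, slope = 2) {
  ifelse(w >= 1, 0, ic50 * (1 / w - 1)^(1 / slope))
}

# 6x6 checkerboard from analytic Hill margins with an additive Bliss
# deviation `delta` on dual-drug cells.
make_checkerboard <- function(delta = 0, slope = 2, ic50_a = 1, ic50_b = 2,
                              targets = c(0, .02, .05, .10, .20, .50)) {
  wt <- 1 - targets
  doses_a <- hill_dose_for(wt, ic50_a, slope)
  doses_b <- hill_dose_for(wt, ic50_b, slope)
  df <- tidyr::expand_grid(i = 1:6, j = 1:6)
  df$dose_a <- doses_a[df$i]
  df$dose_b <- doses_b[df$j]
  df$w <- wt[df$i] * wt[df$j] +
    ifelse(df$i > 1 & df$j > 1, delta, 0)
  df$w <- pmin(pmax(df$w, 0), 1.2)
  dose_matrix(df, "A", "B")
}

# sham: one Hill curve combined with itself, combined dose = da + db
make_sham <- function(slope = 2) {
  doses <- hill_dose_for(1 - c(0, .02, .05, .10, .20, .50), slope = slope)
  df <- tidyr::expand_grid(i = 1:6, j = 1:6)
  df$dose_a <- doses[df$i]
  df$dose_b <- doses[df$j]
  df$w <- hill_w(doses[df$i] + doses[df$j], slope = slope)
  dose_matrix(df, "self", "self")
}

# exact logistic growth curve in minutes
make_logistic <- function(r = 0.01, od0 = 0.005, K = 1, t_max = 1440,
                          dt = 15) {
  t <- seq(0, t_max, by = dt)
  tibble::tibble(time = t,
                 od = K * od0 * exp(r * t) / (K + od0 * (exp(r * t) - 1)))
}

# minimal screen_profile for gating arithmetic tests
make_profile <- function(strain, z, treatment = "t",
                         essentiality = "het-essential") {
  out <- tibble::tibble(treatment = treatment, strain = strain,
                        essentiality = essentiality, tag_used = "up",
                        intensity = 10 - z, z = z)
  class(out) <- c("screen_profile", class(out))
  out
}

# small deterministic barcode table: n strains x 2 tags x nrep features,
# per-array values supplied by f(strain_index, array_index)
make_intensity_table <- function(n_strains, arrays, f, nrep = 2,
                                 n_controls = 0, fc = NULL) {
  strains <- sprintf("s%02d", seq_len(n_strains))
  rows <- list()
  for (a in seq_len(nrow(arrays))) {
    g <- tidyr::expand_grid(idx = seq_len(n_strains), tag = c("up", "down"),
                            replicate = seq_len(nrep))
    g$intensity <- f(g$idx, a)
    rows[[length(rows) + 1]] <- tibble::tibble(
      strain = strains[g$idx], tag = g$tag, replicate = g$replicate,
      intensity = g$intensity, array = arrays$array[a],
      batch = arrays$batch[a], treatment = arrays$treatment[a],
      essentiality = "het-essential", is_control = FALSE)
    if (n_controls > 0) {
      cg <- tidyr::expand_grid(idx = seq_len(n_controls),
                               replicate = seq_len(nrep))
      rows[[length(rows) + 1]] <- tibble::tibble(
        strain = sprintf("c%02d", cg$idx), tag = "ctrl",
        replicate = cg$replicate, intensity = fc(cg$idx, a),
        array = arrays$array[a], batch = arrays$batch[a],
        treatment = arrays$treatment[a], essentiality = NA_character_,
        is_control = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# independent classic (unweighted) KS enrichment score oracle
ks_oracle <- function(membership) {
  n <- length(membership)
  k <- sum(membership)
  steps <- ifelse(membership, 1 / k, -1 / (n - k))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}
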