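two_arrays <- tibble::tibble(array = c("a1", "a2"), batch = "b1",
                             treatment = c("t1", "t2"))

test_that("quantile normalization maps arrays to mean order statistics", {
  # array2 = 2 x array1 -> both become 1.5 x array1's order statistics
  vals <- c(1, 5, 3, 2, 10, 4, 7, 6)
  t <- make_intensity_table(2, two_arrays, function(idx, a) 0, nrep = 2)
  t$intensity <- rep(vals, 2) * rep(c(1, 2), each = 8)
  out <- quantile_normalize(t)
  m <- tidyr::pivot_wider(
    dplyr::mutate(out, probe = paste(strain, tag, replicate)),
    id_cols = "probe", names_from = "array", values_from = "intensity")
  expect_equal(m$a1, m$a2)
  expect_equal(sort(m$a1), 1.5 * sort(vals))

  # already identical arrays are unchanged
  t2 <- t
  t2$intensity <- rep(vals, 2)
  out2 <- quantile_normalize(t2)
  expect_equal(sort(out2$intensity), sort(t2$intensity))
})

test_that("quantile normalization equalizes random lognormal arrays", {
  set.seed(9)
  arrays <- tibble::tibble(array = paste0("a", 1:4), batch = "b1",
                           treatment = paste0("t", 1:4))
  t <- make_intensity_table(10, arrays, function(idx, a) rlnorm(length(idx), 5, 1))
  out <- quantile_normalize(t)
  sorted <- lapply(split(out$intensity, out$array), sort)
  for (k in 2:4) expect_equal(sorted[[k]], sorted[[1]])

  # unequal probe sets are refused
  expect_error(quantile_normalize(t[-1, ]),
               class = "synergyscreen_invalid_input")
})

test_that("saturation correction inverts the hyperbolic transfer", {
  cc <- 1000
  t <- make_intensity_table(3, two_arrays[1, ], function(idx, a) 0, nrep = 1)
  x_true <- c(1, 5, 50, 200, 500, 800)
  t$intensity <- cc * x_true / (cc + x_true)  # saturated observation
  out <- saturation_correct(t, ceiling = cc)
  expect_equal(out$intensity, x_true, tolerance = 1e-9)

  # x = ceiling / 2 maps to the ceiling
  t$intensity <- rep(cc / 2, 6)
  expect_equal(saturation_correct(t, ceiling = cc)$intensity, rep(cc, 6))

  # far below the ceiling the correction is a < 1% relative change
  t$intensity <- rep(cc / 200, 6)
  out3 <- saturation_correct(t, ceiling = cc)
  expect_true(all(abs(out3$intensity / t$intensity - 1) < 0.01))

  # at or above 95% of the ceiling: winsorized and flagged
  t$intensity <- c(rep(10, 5), 0.97 * cc)
  out4 <- saturation_correct(t, ceiling = cc)
  expect_true(out4$saturated[6])
  expect_equal(out4$intensity[6], 0.95 * cc * cc / (0.05 * cc))
})

test_that("snm removes an additive batch shift and keeps treatment effects", {
  arrays <- tidyr::expand_grid(treatment = c("t1", "t2"),
                               batch = c("b1", "b2"))
  arrays$array <- paste(arrays$treatment, arrays$batch, sep = "_")
  trt_eff <- c(t1 = 0, t2 = -1.5)
  probe_base <- function(idx) 10 + 0.3 * idx
  shift <- c(b1 = 0, b2 = 0.5)
  t <- make_intensity_table(6, arrays, function(idx, a) {
    probe_base(idx) + trt_eff[arrays$treatment[a]] + shift[arrays$batch[a]]
  }, nrep = 2)
  out <- snm_normalize(t)
  # batch difference gone
  by_batch <- tapply(out$intensity, out$batch, mean)
  expect_equal(unname(diff(by_batch)), 0, tolerance = 1e-9)
  # treatment contrast preserved exactly (noiseless additive design)
  by_trt <- tapply(out$intensity, out$treatment, mean)
  expect_equal(unname(by_trt["t2"] - by_trt["t1"]), -1.5, tolerance = 1e-9)

  # zero injected batch effect: output equals input (noiseless)
  t0 <- make_intensity_table(6, arrays, function(idx, a) {
    probe_base(idx) + trt_eff[arrays$treatment[a]]
  }, nrep = 2)
  out0 <- snm_normalize(t0)
  expect_equal(dplyr::arrange(out0, array, strain, tag, replicate)$intensity,
               dplyr::arrange(t0, array, strain, tag, replicate)$intensity,
               tolerance = 1e-9)

  # single batch is a no-op with a message
  expect_message(out1 <- snm_normalize(dplyr::filter(t, batch == "b1")),
                 "no-op")
  expect_equal(sort(out1$intensity),
               sort(dplyr::filter(t, batch == "b1")$intensity))

  # fully confounded design is refused
  conf <- tidyr::expand_grid(treatment = c("t1", "t2"))
  conf$batch <- conf$treatment
  conf$array <- paste0("a_", conf$treatment)
  tc <- make_intensity_table(4, conf, function(idx, a) 10 + idx, nrep = 2)
  expect_error(snm_normalize(tc), class = "synergyscreen_confounded_design")
})

test_that("tag selection prefers the lower-CV tag with ties to uptag", {
  t <- make_intensity_table(1, two_arrays[1, ], function(idx, a) 0, nrep = 3)
  t$intensity <- ifelse(t$tag == "up", c(10, 10.1, 9.9), c(10, 13, 7))
  expect_equal(select_tag(t)$tag, "up")
  t$intensity <- ifelse(t$tag == "up", c(10, 13, 7), c(10, 10.1, 9.9))
  expect_equal(select_tag(t)$tag, "down")
  t$intensity <- rep(c(4, 5, 6), 2)  # identical CVs -> uptag
  expect_equal(select_tag(t)$tag, "up")
  t$intensity <- ifelse(t$tag == "up", 0, c(9, 10, 11))  # degenerate uptag
  expect_equal(select_tag(t)$tag, "down")
})

test_that("robust z matches the stated formula against control probes", {
  arrays <- tibble::tibble(array = "a1", batch = "b1", treatment = "drug")
  t <- make_intensity_table(1, arrays, function(idx, a) 1.5173, nrep = 1,
                            n_controls = 5, fc = function(idx, a) idx)
  pr <- robust_z(t, "drug")
  # controls {1..5}: median 3, scaled MAD 1.4826 -> z ~ +1
  expect_equal(pr$z, 1, tolerance = 1e-3)

  # a strain at the control median scores 0
  t2 <- t
  t2$intensity[t2$strain == "s01"] <- 3
  expect_equal(robust_z(t2, "drug")$z, 0)

  # constant controls: degenerate scale
  t3 <- t
  t3$intensity[t3$is_control] <- 2
  expect_error(robust_z(t3, "drug"),
               class = "synergyscreen_degenerate_scale")
})

test_that("robust z is invariant to joint affine transforms", {
  arrays <- tibble::tibble(array = "a1", batch = "b1", treatment = "drug")
  set.seed(3)
  t <- make_intensity_table(8, arrays, function(idx, a) rnorm(length(idx), 10),
                            nrep = 2, n_controls = 10,
                            fc = function(idx, a) rnorm(length(idx), 10))
  z1 <- robust_z(t, "drug")$z
  t2 <- t
  t2$intensity <- 3 * t$intensity + 7
  z2 <- robust_z(t2, "drug")$z
  expect_equal(z2, z1, tolerance = 1e-9)  # scale cancels, shift drops
})

test_that("combination-specific gating applies the 2.0 rules per strain", {
  strains <- c("s1", "s2", "s3", "s4")
  res <- combination_result(
    combo = make_profile(strains, c(3.1, 3.1, 1.9, 2.0)),
    a_ic20 = make_profile(strains, c(0.5, 2.5, 0.1, 1.99)),
    a_combo = make_profile(strains, c(1.0, 0.5, 0.1, 1.2)),
    b_ic20 = make_profile(strains, c(1.9, 0.2, 0.1, 0.5)),
    b_combo = make_profile(strains, c(0.2, 0.1, 0.1, 1.0)))
  out <- combination_specific(res)
  expect_equal(out$specific[match(strains, out$strain)],
               c(TRUE,    # combo 3.1, all singles < 2
                 FALSE,   # one single at 2.5
                 FALSE,   # combo below 2
                 TRUE))   # combo exactly 2.0 (inclusive), singles < 2
  # threshold monotonicity and the infinite-threshold limit
  expect_lte(sum(combination_specific(res, 2.5)$specific),
             sum(out$specific))
  expect_equal(sum(combination_specific(res, Inf)$specific), 0)
})

test_that("sensitivity epsilon supports both the printed and prose forms", {
  res <- combination_result(
    combo = make_profile("s1", 4),
    a_ic20 = make_profile("s1", 0.4),
    a_combo = make_profile("s1", 1),
    b_ic20 = make_profile("s1", 0.6),
    b_combo = make_profile("s1", 1))
  expect_equal(sensitivity_epsilon(res, "product")$eps, 4 - 1 * 1)
  expect_equal(sensitivity_epsilon(res, "sum")$eps, 4 - (1 + 1))
  # z_AB equal to the product expectation: zero in product mode
  res2 <- combination_result(
    combo = make_profile("s1", 6), a_ic20 = make_profile("s1", 2),
    a_combo = make_profile("s1", 2), b_ic20 = make_profile("s1", 3),
    b_combo = make_profile("s1", 3))
  expect_equal(sensitivity_epsilon(res2, "product")$eps, 0)
  expect_error(combination_result(make_profile("s1", 1), NULL,
                                  make_profile("s1", 1),
                                  make_profile("s1", 1),
                                  make_profile("s1", 1)),
               class = "synergyscreen_invalid_input")
})

test_that("profile clustering groups by Pearson correlation", {
  base <- c(1, 2, 3, 4, 5)
  m <- rbind(s1 = base, s2 = base * 2 - 1,  # r = 1 with s1
             s3 = -base, s4 = -base * 1.5 + 2)
  colnames(m) <- paste0("t", 1:5)
  cl <- cluster_profiles(m)
  h <- cl$strains
  expect_equal(h$height[1], 0, tolerance = 1e-9)  # identical-correlation pair
  grp <- stats::cutree(h, k = 2)
  expect_equal(grp[["s1"]], grp[["s2"]])
  expect_equal(grp[["s3"]], grp[["s4"]])
  expect_false(grp[["s1"]] == grp[["s3"]])
  # profile vs its negation: distance 2
  d <- 1 - cor(t(m))
  expect_equal(d["s1", "s3"], 2)
  # newick export is parseable
  nwk <- clustering_newick(cl, "strains")
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("clustering recovers planted groups exactly on epsilon maps", {
  set.seed(4)
  centers <- matrix(rnorm(3 * 6, sd = 3), nrow = 3)
  m <- centers[rep(1:3, each = 4), ] + matrix(rnorm(12 * 6, sd = 0.01), 12)
  rownames(m) <- sprintf("s%02d", 1:12)
  colnames(m) <- sprintf("t%d", 1:6)
  cl <- cluster_profiles(m)
  grp <- stats::cutree(cl$strains, k = 3)
  truth <- rep(1:3, each = 4)[match(names(grp), rownames(m))]
  expect_equal(mclust::adjustedRandIndex(grp, truth), 1)
})
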