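test_that("bliss epsilon follows the multiplicative model", {
  expect_equal(bliss_epsilon(0.9, 0.8, 0.5), -0.22)
  expect_equal(bliss_epsilon(0.7, 0.6, 0.7 * 0.6), 0)
  expect_equal(bliss_epsilon(0.9, 0.8, 0.9), 0.18)
})

test_that("epsilon matrix uses margins and averages dual-drug cells only", {
  m <- make_checkerboard(delta = 0)
  e <- epsilon_matrix(m)
  expect_equal(e$avg_s, 0, tolerance = 1e-12)
  expect_true(all(abs(e$eps) < 1e-12))

  m2 <- make_checkerboard(delta = -0.15)
  expect_equal(epsilon_matrix(m2)$avg_s, -0.15, tolerance = 1e-12)

  # 4x4 with one dual cell at eps -0.3, others independent
  df <- tidyr::expand_grid(i = 1:4, j = 1:4)
  wa <- c(1, 0.9, 0.8, 0.7)
  df$dose_a <- c(0, 1, 2, 4)[df$i]
  df$dose_b <- c(0, 1, 2, 4)[df$j]
  df$w <- wa[df$i] * wa[df$j]
  df$w[df$i == 4 & df$j == 4] <- wa[4]^2 - 0.3
  e3 <- epsilon_matrix(dose_matrix(df))
  expect_equal(e3$avg_s, -0.3 / 9, tolerance = 1e-12)
})

test_that("bliss call is strict at both thresholds and modes", {
  e <- list(avg_s = -0.051, min_eps = -0.1)
  class(e) <- "epsilon_matrix"
  expect_true(call_bliss(e, mode = "avg"))
  e$avg_s <- -0.05
  expect_false(call_bliss(e, mode = "avg"))
  e$min_eps <- -0.21
  expect_true(call_bliss(e, mode = "min_cell"))
  e$min_eps <- -0.20
  expect_false(call_bliss(e, mode = "min_cell"))
})

test_that("loewe combination index is ~1 on shams and low on true synergy", {
  expect_false(as.logical(call_loewe(make_sham(2))))

  # constructed pair: margins log-linear with W=0.5 exactly at dose 4 on
  # both axes; one evaluable dual cell at (1, 1) reaching W=0.5 -> CI=0.5
  df <- tidyr::expand_grid(i = 1:5, j = 1:5)
  doses <- c(0, 1, 2, 4, 8)
  marg <- c(1, 0.95, 0.8, 0.5, 0.2)
  df$dose_a <- doses[df$i]; df$dose_b <- doses[df$j]
  df$w <- pmax(marg[df$i] * marg[df$j], 0.81)
  df$w[df$i == 1] <- marg[df$j][df$i == 1]
  df$w[df$j == 1] <- marg[df$i][df$j == 1]
  df$w[df$i == 2 & df$j == 2] <- 0.5
  m <- dose_matrix(df)
  expect_true(call_loewe(m))

  # no cell at or below the effect cap -> indeterminate, treated as FALSE
  df$w[df$i > 1 & df$j > 1] <- 0.9
  expect_message(out <- call_loewe(dose_matrix(df)), "indeterminate")
  expect_false(as.logical(out))
  expect_true(attr(out, "indeterminate"))
})

test_that("hsa flags cells beating the best single agent by the margin", {
  df <- tidyr::expand_grid(i = 1:3, j = 1:3)
  wa <- c(1, 0.9, 0.8)
  df$dose_a <- c(0, 1, 2)[df$i]; df$dose_b <- c(0, 1, 2)[df$j]
  df$w <- pmin(wa[df$i], wa[df$j])          # equals best single agent
  expect_false(call_hsa(dose_matrix(df)))
  df$w[df$i == 3 & df$j == 3] <- 0.6        # excess 0.2 over min(0.8, 0.8)
  expect_true(call_hsa(dose_matrix(df)))
  # all-zero margins and cells: no excess anywhere
  df$w <- ifelse(df$i == 1 & df$j == 1, 1, 0)
  expect_false(call_hsa(dose_matrix(df)))
})

test_that("potentiation detects a 4-fold midpoint shift and skips bad axes", {
  doses_a <- c(0, 0.5, 1, 2, 4, 8)
  alone <- c(1, 0.95, 0.9, 0.7, 0.5, 0.3)
  with_b <- c(0.93, 0.7, 0.5, 0.35, 0.25, 0.15)
  df <- tidyr::expand_grid(i = 1:6, j = 1:2)
  df$dose_a <- doses_a[df$i]; df$dose_b <- c(0, 1)[df$j]
  df$w <- ifelse(df$j == 1, alone[df$i], with_b[df$i])
  expect_true(call_potentiation(dose_matrix(df)))  # midpoint 4 -> 1

  # partner leaves the response unchanged -> no shift
  df$w <- alone[df$i] * c(1, 0.999)[df$j]
  expect_false(as.logical(call_potentiation(dose_matrix(df))))

  # response never brackets W = 0.5 on either axis -> indeterminate
  df$w <- pmax(df$w, 0.8)
  expect_message(out <- call_potentiation(dose_matrix(df)), "indeterminate")
  expect_false(as.logical(out))
})

test_that("consensus is the conjunction of the four models", {
  sham <- make_sham(1)
  cc <- consensus_call(sham)
  expect_false(cc$bliss)
  expect_false(cc$consensus)

  strong <- consensus_call(make_checkerboard(delta = -0.3))
  expect_true(strong$bliss)
  expect_true(strong$loewe)
  expect_true(strong$hsa)
  expect_true(strong$potentiation)
  expect_true(strong$consensus)

  # Bliss-only borderline: AvgS just past -0.05 on near-flat margins,
  # so no cell beats the best single agent by more than 0.10
  border <- make_checkerboard(delta = -0.06,
                              targets = c(0, .005, .01, .015, .02, .03))
  cb <- consensus_call(border)
  expect_true(cb$bliss)
  expect_false(cb$hsa)
  expect_false(cb$consensus)
})

test_that("transposing a dose matrix leaves AvgS and calls unchanged", {
  m <- make_checkerboard(delta = -0.18)
  mt <- transpose_dose_matrix(m)
  expect_equal(epsilon_matrix(mt)$avg_s, epsilon_matrix(m)$avg_s)
  c1 <- consensus_call(m)
  c2 <- consensus_call(mt)
  expect_equal(c2[c("bliss", "loewe", "hsa", "potentiation", "consensus")],
               c1[c("bliss", "loewe", "hsa", "potentiation", "consensus")])
})

test_that("avg_s recovers the planted deviation across the delta sweep", {
  for (delta in seq(-0.3, 0.3, by = 0.1)) {
    m <- make_checkerboard(delta = delta)
    expect_lt(abs(epsilon_matrix(m)$avg_s - delta), 0.01)
  }
})

test_that("dose matrix validation rejects broken checkerboards", {
  df <- tidyr::expand_grid(dose_a = c(0, 1), dose_b = c(0, 1))
  df$w <- c(1, 0.9, 0.8, 0.7)
  expect_s3_class(dose_matrix(df), "dose_matrix")
  expect_error(dose_matrix(dplyr::filter(df, !(dose_a == 1 & dose_b == 1))),
               class = "synergyscreen_invalid_matrix")
  df$w[1] <- 0.8  # no-drug corner far from 1
  expect_error(dose_matrix(df), class = "synergyscreen_invalid_matrix")
  df$w[1] <- 1
  df2 <- df
  df2$dose_a <- df2$dose_a + 1  # ladder not starting at 0
  expect_error(dose_matrix(df2), class = "synergyscreen_invalid_matrix")
})

test_that("dose and epsilon matrices round-trip through TSV", {
  m <- make_checkerboard(delta = -0.12)
  f <- tempfile(fileext = ".tsv")
  write_dose_matrix(m, f)
  m2 <- read_dose_matrix(f, drug_a = "A", drug_b = "B")
  expect_equal(m2$w, m$w, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$doses_a, m$doses_a, tolerance = 1e-9)
})

test_that("tidy and glance views expose the grids and the summary", {
  m <- make_checkerboard(delta = -0.1)
  e <- epsilon_matrix(m)
  td <- tidy(e)
  expect_equal(nrow(td), 36)
  expect_equal(sum(td$dual), 25)
  gl <- glance(e)
  expect_equal(gl$avg_s, e$avg_s)
  expect_s3_class(autoplot(e), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
})
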