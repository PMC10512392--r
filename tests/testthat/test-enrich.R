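test_that("gene-set filtering is strict on both size bounds", {
  universe <- sprintf("g%03d", 1:300)
  sets <- list(tiny = universe[1:5], ok6 = universe[1:6],
               ok199 = universe[1:199], big = universe[1:200],
               off_universe = c(universe[1:10], "zzz"))
  kept <- filter_sets(sets, universe)
  expect_setequal(names(kept), c("ok6", "ok199", "off_universe"))
  expect_equal(length(kept$off_universe), 10)  # intersected first
})

test_that("gmt files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c("first", "second"))
  expect_equal(read_gmt(f), sets)
})

test_that("enrichment score hits its analytic extremes", {
  scores <- setNames(seq(10, 1), paste0("g", 1:10))
  # set occupying the top ranks with equal scores reaches ES = 1
  eq <- setNames(c(rep(5, 3), rep(1, 7)), paste0("g", 1:10))
  out <- gsea_preranked(eq, paste0("g", 1:3), n_perm = 50, seed = 1)
  expect_equal(out$es, 1)
  # set == universe is skipped
  expect_message(
    all_out <- gsea_preranked(scores, paste0("g", 1:10), n_perm = 10),
    "skipped")
  expect_true(is.na(all_out$es))
  # bottom-ranked set has a negative ES
  out_lo <- gsea_preranked(scores, paste0("g", 8:10), n_perm = 50, seed = 1)
  expect_lt(out_lo$es, 0)
})

test_that("unweighted ES equals the classic KS statistic (oracle check)", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:14, 1)
    k <- sample(2:4, 1)
    scores <- setNames(sort(rnorm(n), decreasing = TRUE), paste0("g", 1:n))
    memb_idx <- sample(n, k)
    set <- names(scores)[memb_idx]
    out <- gsea_preranked(scores, set, weight = 0, n_perm = 10, seed = 1)
    memb <- names(scores) %in% set
    expect_equal(out$es, ks_oracle(memb), tolerance = 1e-12)
  }
})

test_that("unweighted ES is invariant to monotone score transforms", {
  scores <- setNames(c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.2, 0.1),
                     paste0("g", 1:10))
  set <- c("g2", "g5", "g9")
  a <- gsea_preranked(scores, set, weight = 0, n_perm = 20, seed = 1)
  b <- gsea_preranked(exp(scores) + 3, set, weight = 0, n_perm = 20, seed = 1)
  expect_equal(a$es, b$es)
})

test_that("exhaustive permutation p matches a brute-force enumeration", {
  scores <- setNames(c(3.2, 2.5, 2.1, 1.4, 0.8, -0.2, -0.9, -1.7),
                     paste0("g", 1:8))
  set <- c("g1", "g2", "g4")
  out <- gsea_preranked(scores, set, weight = 0, exhaustive = TRUE)
  memb <- names(sort(scores, decreasing = TRUE)) %in% set
  es_obs <- ks_oracle(memb)
  all_es <- apply(combn(8, 3), 2, function(idx) {
    flag <- logical(8); flag[idx] <- TRUE
    ks_oracle(flag)
  })
  same <- all_es[sign(all_es) == sign(es_obs) | all_es == 0]
  expect_equal(out$p, mean(abs(same) >= abs(es_obs)), tolerance = 1e-12)
  expect_equal(out$es, es_obs, tolerance = 1e-12)
})

test_that("gsea is reproducible under a fixed seed", {
  set.seed(99)
  scores <- setNames(rnorm(30), paste0("g", 1:30))
  set <- paste0("g", c(2, 5, 8, 11, 19, 22, 28))
  a <- gsea_preranked(scores, set, n_perm = 200, seed = 42)
  b <- gsea_preranked(scores, set, n_perm = 200, seed = 42)
  expect_identical(a, b)
})

test_that("null permutation p-values are close to uniform", {
  set.seed(7)
  n <- 12; k <- 3
  genes <- paste0("g", 1:n)
  pvals <- replicate(600, {
    scores <- setNames(rnorm(n), genes)
    gsea_preranked(scores, sample(genes, k), weight = 1,
                   exhaustive = TRUE)$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("collection scoring attaches BH q-values and survives filtering", {
  set.seed(12)
  scores <- setNames(rnorm(40), paste0("g", 1:40))
  scores[1:8] <- scores[1:8] + 4
  sets <- list(top = paste0("g", 1:8),
               rand = paste0("g", c(11, 15, 19, 23, 27, 31, 35)),
               tiny = paste0("g", 1:3))
  res <- gsea_collection(scores, sets, n_perm = 300, seed = 5)
  expect_setequal(res$set, c("top", "rand"))  # tiny filtered out
  expect_true(all(res$q >= res$p - 1e-12))
  expect_lt(res$p[res$set == "top"], 0.05)
})

test_that("the enrichment matrix clusters combinations and sets", {
  # one term separates synergistic from non-synergistic combinations
  combos <- c(paste0("syn", 1:3), paste0("non", 1:3))
  res <- tidyr::expand_grid(combination = combos,
                            set = paste0("GO", 1:4))
  set.seed(8)
  res$nes <- rnorm(nrow(res), 0, 0.05) +
    ifelse(res$set == "GO1" & grepl("^syn", res$combination), 2.5, 0) +
    ifelse(res$set == "GO2" & grepl("^non", res$combination), 2.5, 0)
  em <- enrichment_matrix(
    res, synergy = tibble::tibble(combination = combos,
                                  synergistic = grepl("^syn", combos)))
  expect_equal(dim(em$matrix), c(6, 4))
  grp <- stats::cutree(em$combinations, k = 2)
  expect_equal(length(unique(grp[grepl("^syn", names(grp))])), 1)
  expect_equal(length(unique(grp[grepl("^non", names(grp))])), 1)
  expect_false(grp[["syn1"]] == grp[["non1"]])
  expect_s3_class(autoplot(em), "ggplot")

  # single combination: 1 x K matrix, no clustering
  em1 <- enrichment_matrix(dplyr::filter(res, combination == "syn1"))
  expect_equal(nrow(em1$matrix), 1)
  expect_null(em1$combinations)
})
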