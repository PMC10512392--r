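# Gene-set enrichment of combination profiles: genes ranked by combination
# sensitivity epsilon, scored against GO-style sets (size 6-199) with a
# weighted Kolmogorov-Smirnov running-sum statistic and gene-label
# permutation p-values.

#' Read / write gene sets in GMT format
#'
#' `read_gmt()` parses a standard GMT file (set name, description,
#' tab-separated members) via [fgsea::gmtPathways()]; `write_gmt()` writes
#' a named list of character vectors back out.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: named list of member-gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled `NA` -> set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Filter a gene-set collection against a score universe
#'
#' Intersects every set with the scored universe, then keeps sets with
#' more than `min_size` and fewer than `max_size` members (strict on both
#' ends: the defaults keep sizes 6-199).
#'
#' @param sets Named list of member-gene vectors.
#' @param universe Character vector of scored genes.
#' @param min_size,max_size Open interval bounds on set size (defaults 5
#'   and 200).
#' @return The filtered collection.
#' @export
filter_sets <- function(sets, universe, min_size = 5, max_size = 200) {
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  keep(sets, function(s) length(s) > min_size && length(s) < max_size)
}

# Weighted KS enrichment score for one set given a named, sorted score
# vector. Hit increments are proportional to |score|^p, miss decrements
# uniform; the ES is the running-sum extremum of largest magnitude
# (earliest on ties).
ks_enrichment_score <- function(sorted_scores, in_set, p = 1) {
  n <- length(sorted_scores)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) return(0)
  w <- abs(sorted_scores)^p
  inc <- numeric(n)
  inc[in_set] <- if (sum(w[in_set]) > 0) w[in_set] / sum(w[in_set]) else 1 / nh
  inc[!in_set] <- -1 / (n - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment (weighted KS)
#'
#' Genes are ranked by score (descending; here typically the combination
#' sensitivity epsilon or a robust Z). The enrichment score is the
#' extremum of a running sum that steps up by `|score|^weight`
#' (normalized) at member genes and down uniformly elsewhere. The p-value
#' comes from gene-label permutations: random same-size sets, either
#' `n_perm` sampled draws or every possible placement when
#' `exhaustive = TRUE` (feasible for small universes). NES is the ES
#' divided by the mean magnitude of same-sign permutation scores.
#'
#' @param scores Named numeric vector (gene -> score), or a tibble with
#'   columns `gene` and `score`. At least 5 genes.
#' @param set Character vector of member genes.
#' @param weight KS weight exponent `p` (default 1; 0 gives the classic
#'   unweighted statistic).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the permutation draw.
#' @param exhaustive Enumerate all `choose(n, |set|)` placements instead
#'   of sampling (refused above `max_exhaustive` placements).
#' @param max_exhaustive Guard for `exhaustive` (default 1e5).
#' @return One-row tibble: `size`, `es`, `nes`, `p`, `direction`,
#'   `n_perm`.
#' @export
gsea_preranked <- function(scores, set, weight = 1, n_perm = 1000,
                           seed = NULL, exhaustive = FALSE,
                           max_exhaustive = 1e5) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene)
  if (length(scores) < 5) {
    abort("Preranked GSEA needs at least 5 scored genes.",
          class = "synergyscreen_invalid_input")
  }
  ord <- order(scores, names(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  s <- scores[ord]
  memb <- names(s) %in% set
  k <- sum(memb)
  if (k == 0 || k == length(s)) {
    inform("Set is empty or spans the whole universe after filtering: skipped.")
    return(tibble(size = k, es = NA_real_, nes = NA_real_, p = NA_real_,
                  direction = NA_character_, n_perm = 0L))
  }
  es <- ks_enrichment_score(s, memb, p = weight)
  n <- length(s)
  if (exhaustive) {
    if (choose(n, k) > max_exhaustive) {
      abort("Too many placements for exhaustive enumeration.",
            class = "synergyscreen_invalid_input")
    }
    picks <- combn(n, k, simplify = FALSE)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    picks <- lapply(seq_len(n_perm), function(i) sample.int(n, k))
  }
  perm_es <- vapply(picks, function(idx) {
    flag <- logical(n); flag[idx] <- TRUE
    ks_enrichment_score(s, flag, p = weight)
  }, numeric(1))
  same_sign <- perm_es[sign(perm_es) == sign(es) | perm_es == 0]
  pval <- if (exhaustive) {
    # the observed placement is one of the enumerated ones, so p >= 1/M
    mean(abs(same_sign) >= abs(es))
  } else {
    (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  }
  denom <- mean(abs(same_sign))
  tibble(size = k, es = es,
         nes = if (is.finite(denom) && denom > 0) es / denom else NA_real_,
         p = pval,
         direction = if (es >= 0) "enriched_high" else "enriched_low",
         n_perm = length(perm_es))
}

#' Enrichment of a whole collection
#'
#' Runs [gsea_preranked()] for every set surviving [filter_sets()] and
#' appends Benjamini-Hochberg q-values.
#'
#' @inheritParams gsea_preranked
#' @param sets Named list of gene sets.
#' @param min_size,max_size Passed to [filter_sets()].
#' @return Tibble with one row per set: `set`, `size`, `es`, `nes`, `p`,
#'   `q`, `direction`.
#' @export
gsea_collection <- function(scores, sets, weight = 1, n_perm = 1000,
                            seed = NULL, min_size = 5, max_size = 200) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene)
  sets <- filter_sets(sets, names(scores), min_size, max_size)
  if (!length(sets)) {
    return(tibble(set = character(), size = integer(), es = numeric(),
                  nes = numeric(), p = numeric(), q = numeric(),
                  direction = character()))
  }
  res <- imap(sets, function(s, nm) {
    mutate(gsea_preranked(scores, s, weight = weight, n_perm = n_perm,
                          seed = seed),
           set = nm)
  }) |>
    bind_rows() |>
    select("set", "size", "es", "nes", "p", "direction")
  mutate(res, q = p.adjust(.data$p, method = "BH"), .after = "p")
}

#' Combination-by-set enrichment matrix
#'
#' Collects per-combination enrichment results into a combinations x sets
#' NES matrix and clusters both margins with the Pearson-distance
#' average-linkage procedure used for screen profiles. The per-combination
#' synergy annotation, if provided, is carried along for plotting.
#'
#' @param results Tibble with columns `combination`, `set`, `nes` (rows
#'   from [gsea_collection()] tagged by combination).
#' @param synergy Optional tibble `combination`, `synergistic` (logical).
#' @return An `enrichment_matrix` object: `matrix`, `combinations`
#'   (hclust or NULL), `sets` (hclust or NULL), `annotation`.
#' @export
enrichment_matrix <- function(results, synergy = NULL) {
  need <- c("combination", "set", "nes")
  if (!all(need %in% names(results))) {
    abort("`results` needs columns combination, set, nes.",
          class = "synergyscreen_invalid_input")
  }
  m <- results |>
    pivot_wider(id_cols = "combination", names_from = "set",
                values_from = "nes") |>
    tibble::column_to_rownames("combination") |>
    as.matrix()
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  cl_rows <- cl_cols <- NULL
  if (nrow(m) >= 3) {
    d <- 1 - suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
    d[!is.finite(d)] <- 1
    cl_rows <- hclust(as.dist(d), method = "average")
  }
  if (ncol(m) >= 3) {
    d <- 1 - suppressWarnings(cor(m, use = "pairwise.complete.obs"))
    d[!is.finite(d)] <- 1
    cl_cols <- hclust(as.dist(d), method = "average")
  }
  structure(list(matrix = m, combinations = cl_rows, sets = cl_cols,
                 annotation = synergy),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix>", nrow(x$matrix), "combinations x",
      ncol(x$matrix), "sets\n")
  invisible(x)
}

#' @rdname enrichment_matrix
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "combination") |>
    pivot_longer(-"combination", names_to = "set", values_to = "nes")
}
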