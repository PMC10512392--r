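# End-to-end runs tying the stages together: checkerboard synergy scoring
# from plate files, the packaged heterozygote-fitness reanalysis, and the
# five-screen HIP-HOP combination analysis. Each run can write TSV/JSON
# outputs plus a machine-readable provenance record.

provenance <- function(params) {
  list(package = "synergyscreen",
       version = as.character(utils::packageVersion("synergyscreen")),
       config_hash = rlang::hash(params),
       params = params,
       timestamp = format(Sys.time(), tz = "UTC"))
}

write_outputs <- function(out_dir, tables = list(), json = list(),
                          params = list()) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  for (nm in names(json)) {
    jsonlite::write_json(json[[nm]], file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(provenance(params),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Score one drug pair from plate data
#'
#' Reads (or accepts) a plate of growth curves and its plate map, builds
#' the checkerboard, computes the Bliss epsilon grid and AvgS, and applies
#' the four-model consensus. Optionally writes the per-pair call record
#' (JSON), the epsilon heatmap grid (TSV) and a provenance record.
#'
#' @param plate Long plate tibble (`well`, `time`, `od`) or a CSV path
#'   (see [read_plate()]).
#' @param plate_map Plate-map tibble or TSV path (see [read_plate_map()]).
#' @param out_dir Optional output directory.
#' @param mode,avg_threshold,cell_threshold Passed to [call_bliss()] via
#'   [consensus_call()].
#' @param window Smoothing window.
#' @return List: `matrix` (`dose_matrix`), `epsilon` (`epsilon_matrix`),
#'   `calls` (one-row tibble).
#' @export
run_synergy <- function(plate, plate_map, out_dir = NULL,
                        mode = c("avg", "min_cell"), avg_threshold = -0.05,
                        cell_threshold = -0.20, window = 5L) {
  mode <- match.arg(mode)
  if (is.character(plate)) plate <- read_plate(plate)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  m <- assemble_dose_matrix(plate, plate_map, window = window)
  e <- epsilon_matrix(m)
  calls <- consensus_call(m, avg_threshold = avg_threshold,
                          cell_threshold = cell_threshold, mode = mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dose_matrix(e, file.path(out_dir, "epsilon_matrix.tsv"))
    write_dose_matrix(m, file.path(out_dir, "w_matrix.tsv"))
    write_outputs(out_dir, json = list(synergy_calls = as.list(calls)),
                  params = list(mode = mode, avg_threshold = avg_threshold,
                                cell_threshold = cell_threshold,
                                window = window))
  }
  list(matrix = m, epsilon = e, calls = calls)
}

#' Reanalyze the packaged heterozygote fitness table
#'
#' Applies the negative-interaction calling rules to the packaged 10 x 11
#' fitness matrix: the inclusive >=10% defect rule (fitness <= `cutoff`)
#' and the strict >30% rule (fitness < `strict_cutoff`), partitions calls
#' into expected (known-target) and novel, and reports the counts.
#'
#' @param out_dir Optional output directory for the call report TSV.
#' @param cutoff Inclusive cutoff (default 0.90).
#' @param strict_cutoff Strict cutoff (default 0.70).
#' @return List: `report` (per-cell calls at `cutoff` with class),
#'   `strict_report`, `counts` (named list: `n_tested`, `n_negative`,
#'   `n_expected`, `n_novel`, `n_strict`).
#' @export
run_table2_report <- function(out_dir = NULL, cutoff = 0.90,
                              strict_cutoff = 0.70) {
  fitness <- het_fitness_table()
  map <- drug_target_map()
  calls <- partition_expected(call_negative(fitness, cutoff, strict = FALSE),
                              map)
  strict <- partition_expected(call_negative(fitness, strict_cutoff,
                                             strict = TRUE), map)
  counts <- list(n_tested = nrow(fitness),
                 n_negative = nrow(calls),
                 n_expected = sum(calls$class == "expected"),
                 n_novel = sum(calls$class == "novel"),
                 n_strict = nrow(strict))
  write_outputs(out_dir,
                tables = list(interaction_calls = calls,
                              interaction_calls_strict = strict),
                json = list(interaction_counts = counts),
                params = list(cutoff = cutoff,
                              strict_cutoff = strict_cutoff))
  list(report = calls, strict_report = strict, counts = counts)
}

#' Analyze a five-screen HIP-HOP combination assay
#'
#' Runs the full barcode pipeline (saturation correction, quantile
#' normalization, log2, supervised batch removal, tag selection, robust
#' Z), bundles the five screens, calls combination-specific strains,
#' computes sensitivity epsilons, clusters the Z profiles, and (when gene
#' sets are supplied) ranks epsilon-based gene-set enrichment.
#'
#' @param table Barcode intensity table (tibble or TSV path) covering all
#'   five screens.
#' @param design Named character vector mapping the five roles `combo`,
#'   `a_ic20`, `a_combo`, `b_ic20`, `b_combo` to treatment labels in
#'   `table`.
#' @param out_dir Optional output directory (profiles, combination report,
#'   Newick trees, scatterplot PDF, GSEA table).
#' @param gene_sets Optional named list of gene sets (strain identifiers)
#'   or a GMT path.
#' @param threshold Combination-specific Z threshold (default 2).
#' @param eps_mode Ranking epsilon for enrichment: `"product"` (default)
#'   or `"sum"`.
#' @param ceiling Saturation ceiling passed to [saturation_correct()].
#' @param n_perm,seed Permutation settings for [gsea_collection()].
#' @return List: `profiles`, `result` (`combination_result`), `report`,
#'   `clustering`, `enrichment` (or NULL).
#' @export
run_hiphop <- function(table, design, out_dir = NULL, gene_sets = NULL,
                       threshold = 2.0, eps_mode = c("product", "sum"),
                       ceiling = NULL, n_perm = 1000, seed = NULL) {
  eps_mode <- match.arg(eps_mode)
  if (is.character(table)) {
    table <- readr::read_tsv(table, show_col_types = FALSE, progress = FALSE)
  }
  roles <- c("combo", "a_ic20", "a_combo", "b_ic20", "b_combo")
  miss <- setdiff(roles, names(design))
  if (length(miss)) {
    abort(paste0("Design is missing screen role(s): ",
                 paste(miss, collapse = ", ")),
          class = "synergyscreen_invalid_input")
  }
  absent <- setdiff(unname(design[roles]), unique(table$treatment))
  if (length(absent)) {
    abort(paste0("Intensity table has no arrays for treatment(s): ",
                 paste(absent, collapse = ", ")),
          class = "synergyscreen_invalid_input")
  }
  profiles <- process_screens(table, ceiling = ceiling)
  res <- combination_result(profiles[[design[["combo"]]]],
                            profiles[[design[["a_ic20"]]]],
                            profiles[[design[["a_combo"]]]],
                            profiles[[design[["b_ic20"]]]],
                            profiles[[design[["b_combo"]]]])
  report <- combination_report(res, threshold = threshold)
  zlong <- bind_rows(lapply(profiles, function(p) {
    select(as_tibble(p), "strain", "treatment", value = "z")
  }))
  clustering <- cluster_profiles(zlong)
  enrichment <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    eps_col <- if (eps_mode == "product") "eps_product" else "eps_sum"
    scores <- setNames(report[[eps_col]], report$strain)
    enrichment <- gsea_collection(scores, gene_sets, n_perm = n_perm,
                                  seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- c(list(combination_report = report),
              setNames(lapply(profiles, as_tibble),
                       paste0("profile_", names(profiles))))
    if (!is.null(enrichment)) tabs$gsea <- enrichment
    clustering_newick(clustering, "strains",
                      file.path(out_dir, "strain_clustering.nwk"))
    clustering_newick(clustering, "treatments",
                      file.path(out_dir, "treatment_clustering.nwk"))
    ggplot2::ggsave(file.path(out_dir, "hiphop_scatter.pdf"),
                    plot_hiphop_scatter(report, threshold = threshold),
                    width = 9, height = 4)
    write_outputs(out_dir, tables = tabs,
                  params = list(design = as.list(design),
                                threshold = threshold, eps_mode = eps_mode,
                                n_perm = n_perm, seed = seed))
  }
  list(profiles = profiles, result = res, report = report,
       clustering = clustering, enrichment = enrichment)
}
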