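# End-to-end orchestration: simulate/read -> preprocess -> markers ->
# homology (-> signatures), with every intermediate table written out and a
# machine-readable run summary.

#' Pipeline run configuration
#'
#' Collects the thresholds printed on the analysis (F-test alpha, CAT list
#' size L, CPM eligibility rule, HVG set size) together with input/output
#' locations. Inputs are either a [simulation_config()] (`simulate =`) or
#' file paths to the six on-disk artifacts.
#'
#' @param out_dir Output directory.
#' @param simulate Optional [simulation_config()]; when given, inputs are
#'   generated rather than read.
#' @param counts_a,counts_b,meta_a,meta_b,ortholog_path Input file paths
#'   (TSV dialects of the io layer) when not simulating.
#' @param species_a,species_b Species labels for file-based input.
#' @param alpha Overall-F BH gate (default 0.05).
#' @param l CAT list-size cap (default 1000).
#' @param min_cpm,min_samples CPM filter rule (default > 1 CPM in >= 3
#'   samples).
#' @param hvg_top Per-species HVG set size (default 2000).
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param signatures Optional signature-table path (TSV) to score.
#' @param seed Seed recorded in the summary (the simulation carries its own
#'   seed; the rest of the pipeline is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       counts_a = NULL, counts_b = NULL,
                       meta_a = NULL, meta_b = NULL,
                       ortholog_path = NULL,
                       species_a = "speciesA", species_b = "speciesB",
                       alpha = 0.05, l = 1000,
                       min_cpm = 1, min_samples = 3, hvg_top = 2000,
                       df_method = "residual",
                       signatures = NULL,
                       seed = 1L) {
  stopifnot(alpha > 0, l > 0, min_cpm > 0, min_samples > 0, hvg_top > 0)
  if (is.null(simulate)) {
    paths <- c(counts_a = counts_a, counts_b = counts_b,
               meta_a = meta_a, meta_b = meta_b,
               orthologs = ortholog_path)
    if (length(paths) < 5) {
      abort("Provide either `simulate` or all five input paths.")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("Missing input file(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  structure(list(
    out_dir = out_dir, simulate = simulate,
    counts_a = counts_a, counts_b = counts_b,
    meta_a = meta_a, meta_b = meta_b, ortholog_path = ortholog_path,
    species_a = species_a, species_b = species_b,
    alpha = alpha, l = l, min_cpm = min_cpm, min_samples = min_samples,
    hvg_top = hvg_top, df_method = df_method, signatures = signatures,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full cross-species homology pipeline
#'
#' Executes simulate/read -> preprocess -> marker scoring (per species,
#' medians on quantile-normalized values, mixed-model tests on VST values)
#' -> CAT homology (-> signature profiles when configured), writes every
#' intermediate table under `out_dir` and emits `summary.json` with the
#' parameters, seed, per-stage gene/sample counts, homolog assignments and
#' singular-fit tallies. Never mutates its input files.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly; side effect: files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      cohort <- simulate_cohort(config$simulate)
      write_cohort(cohort, file.path(config$out_dir, "simulated_inputs"))
      cohort
    } else {
      list(
        counts_a = read_counts(config$counts_a, species = config$species_a),
        counts_b = read_counts(config$counts_b, species = config$species_b),
        meta_a = read_sample_meta(config$meta_a),
        meta_b = read_sample_meta(config$meta_b),
        orthologs = read_ortholog_map(config$ortholog_path),
        truth = NULL
      )
    }
  })

  prep <- stage("preprocess", suppressWarnings(
    preprocess_cross_species(
      inputs$counts_a, inputs$counts_b, inputs$meta_a, inputs$meta_b,
      inputs$orthologs,
      min_cpm = config$min_cpm, min_samples = config$min_samples,
      hvg_top = config$hvg_top
    )
  ))
  qn_tab <- as_tibble(prep$qn$values, rownames = "gene_id")
  write_result_table(qn_tab, file.path(config$out_dir,
                                       "normalized_quantile.tsv"))
  write_result_table(prep$qn$flags, file.path(config$out_dir, "flags.tsv"))
  writeLines(prep$hvg, file.path(config$out_dir, "hvg_shared.txt"))

  qn_a <- subset_samples(prep$qn, inputs$meta_a$sample_id)
  qn_b <- subset_samples(prep$qn, inputs$meta_b$sample_id)
  markers_a <- stage("markers_a", marker_scores(
    qn_a, inputs$meta_a, alpha = config$alpha,
    df_method = config$df_method, test_values = prep$vst_a
  ))
  markers_b <- stage("markers_b", marker_scores(
    qn_b, inputs$meta_b, alpha = config$alpha,
    df_method = config$df_method, test_values = prep$vst_b
  ))
  write_result_table(markers_a, file.path(config$out_dir, "markers_a.tsv"))
  write_result_table(markers_b, file.path(config$out_dir, "markers_b.tsv"))

  hom <- stage("homology", suppressWarnings(
    cat_homology(markers_a, markers_b, l = config$l)
  ))
  write_result_table(hom$curves, file.path(config$out_dir,
                                           "cat_curves.tsv"))
  write_result_table(
    as_tibble(hom$mean_cat, rownames = "ref_subtype"),
    file.path(config$out_dir, "mean_cat.tsv")
  )
  write_result_table(
    as_tibble(hom$scaled, rownames = "ref_subtype"),
    file.path(config$out_dir, "mean_cat_scaled.tsv")
  )
  write_result_table(hom$assignment_ab,
                     file.path(config$out_dir, "assignment_ab.tsv"))
  write_result_table(hom$assignment_ba,
                     file.path(config$out_dir, "assignment_ba.tsv"))

  sig_profile <- NULL
  if (!is.null(config$signatures)) {
    sig_profile <- stage("signatures", {
      sig <- read_signature_table(config$signatures)
      sets <- top_n_signature(sig, rownames(prep$qn$values))
      prof <- signature_profile(sets, prep$qn,
                                bind_rows(inputs$meta_a, inputs$meta_b))
      write_result_table(prof, file.path(config$out_dir,
                                         "signature_profile.tsv"))
      prof
    })
  }

  summary <- list(
    parameters = list(
      alpha = config$alpha, l = config$l, min_cpm = config$min_cpm,
      min_samples = config$min_samples, hvg_top = config$hvg_top,
      df_method = config$df_method
    ),
    seed = config$seed,
    stage_counts = as.data.frame(prep$log),
    n_genes_analyzed = nrow(prep$qn$values),
    n_samples = ncol(prep$qn$values),
    n_hvg_shared = length(prep$hvg),
    singular_fit_fallbacks = sum(prep$qn$flags$singular_fit_fallback),
    n_eligible_markers_a = sum(markers_a$eligible),
    n_eligible_markers_b = sum(markers_b$eligible),
    l_effective = hom$l_effective,
    assignment_ab = as.data.frame(hom$assignment_ab),
    assignment_ba = as.data.frame(hom$assignment_ba)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, markers_a = markers_a,
                 markers_b = markers_b, homology = hom,
                 preprocess = prep, signature_profile = sig_profile,
                 truth = inputs$truth))
}
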