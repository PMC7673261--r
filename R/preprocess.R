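#' Construct a normalized expression matrix
#'
#' Continuous gene x sample values at one of three forward-only stages:
#' `vst` -> `subject_regressed` -> `quantile_normalized`. Carries per-gene
#' provenance flags (currently: whether the subject-regression mixed model
#' hit a singular fit and the original values were retained).
#'
#' @param values Numeric matrix with dimnames, finite values.
#' @param stage One of `"vst"`, `"subject_regressed"`, `"quantile_normalized"`.
#' @param species Species label (or `"combined"` after cross-species
#'   quantile normalization).
#' @param flags Tibble with `gene_id` and `singular_fit_fallback`.
#' @return A `normalized_matrix`.
#' @export
normalized_matrix <- function(values, stage, species = "unspecified",
                              flags = NULL) {
  stages <- c("vst", "subject_regressed", "quantile_normalized")
  stage <- match.arg(stage, stages)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(!is.finite(values))) abort("Normalized values must be finite.")
  if (is.null(flags)) {
    flags <- tibble(gene_id = rownames(values),
                    singular_fit_fallback = FALSE)
  }
  structure(list(values = values, stage = stage, species = species,
                 flags = flags),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %s [%s]: %d genes x %d samples\n",
              x$species, x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

stage_rank <- function(stage) {
  match(stage, c("vst", "subject_regressed", "quantile_normalized"))
}

#' Subset the samples of a normalized matrix
#'
#' @param nm A `normalized_matrix`.
#' @param samples Sample IDs to keep (order preserved as given).
#' @return A `normalized_matrix` at the same stage.
#' @export
subset_samples <- function(nm, samples) {
  missing <- setdiff(samples, colnames(nm$values))
  if (length(missing) > 0) {
    abort(paste0("Unknown samples: ", paste(missing, collapse = ", ")))
  }
  normalized_matrix(nm$values[, samples, drop = FALSE], nm$stage,
                    species = nm$species, flags = nm$flags)
}

#' Restrict two count matrices to their 1:1 ortholog pairs
#'
#' Re-indexes both matrices to the mapped gene set in identical pair order;
#' genes absent from either matrix (or from the map) are dropped. Rownames
#' of both outputs become the shared ortholog-pair IDs, the coordinate
#' system used by all cross-species steps.
#'
#' @param cm_a,cm_b [count_matrix()] objects for species A and B.
#' @param map 1:1 ortholog map tibble (`gene_a`, `gene_b`).
#' @return List with elements `a`, `b` (re-indexed count matrices) and
#'   `map` (the retained pairs).
#' @export
restrict_to_orthologs <- function(cm_a, cm_b, map) {
  keep <- map$gene_a %in% rownames(cm_a$counts) &
    map$gene_b %in% rownames(cm_b$counts)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0) {
    abort("No ortholog pairs present in both count matrices.")
  }
  ca <- cm_a$counts[map$gene_a, , drop = FALSE]
  cb <- cm_b$counts[map$gene_b, , drop = FALSE]
  pid <- pair_ids(map)
  rownames(ca) <- pid
  rownames(cb) <- pid
  list(a = count_matrix(ca, species = cm_a$species),
       b = count_matrix(cb, species = cm_b$species),
       map = map)
}

#' CPM expression-eligibility filter
#'
#' A gene is retained iff its counts exceed `min_cpm` counts per million
#' (relative to the sample's column sum) in at least `min_samples` samples.
#'
#' @param cm A [count_matrix()].
#' @param min_cpm CPM threshold (strict inequality).
#' @param min_samples Minimum number of samples above threshold.
#' @return Character vector of retained gene IDs.
#' @export
cpm_filter <- function(cm, min_cpm = 1, min_samples = 3) {
  libsize <- colSums(cm$counts)
  zero <- names(libsize)[libsize == 0]
  if (length(zero) > 0) {
    abort(paste0("Zero library size for sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  cpm <- sweep(cm$counts, 2, libsize, `/`) * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  rownames(cm$counts)[keep]
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors relative to the geometric-mean reference computed
#' over genes with all-positive counts. When no such gene exists, falls back
#' to library size over the median library size, with a warning.
#'
#' @param counts Count matrix (genes x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    warn("No gene with all-positive counts; using library-size factors.")
    libsize <- colSums(counts)
    return(libsize / median(libsize))
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)
  # median taken on the log scale (DESeq2 convention; differs from the
  # ratio-scale median only when averaging the two middle values)
  apply(lc - ref, 2, function(v) exp(median(v)))
}

#' Variance-stabilizing transform of counts
#'
#' The default transform is `log2(count / size_factor + 1)` with
#' median-of-ratios size factors: downstream statistics (medians, ranks,
#' mixed-model contrasts) need only a monotone variance-stabilizing
#' transform. The interface is pluggable: `method = "deseq"` uses
#' `DESeq2::varianceStabilizingTransformation()` instead, and custom size
#' factors can be supplied.
#'
#' @param cm A [count_matrix()] (typically CPM-filtered).
#' @param method `"log2-mor"` (default) or `"deseq"`.
#' @param size_factors Optional per-sample size factors overriding the
#'   median-of-ratios estimate (`"log2-mor"` only).
#' @return A [normalized_matrix()] at stage `"vst"`.
#' @export
vst_counts <- function(cm, method = c("log2-mor", "deseq"),
                       size_factors = NULL) {
  method <- match.arg(method)
  if (method == "deseq") {
    if (!requireNamespace("DESeq2", quietly = TRUE)) {
      abort("method = \"deseq\" requires the DESeq2 package.")
    }
    m <- matrix(as.integer(round(cm$counts)), nrow(cm$counts),
                dimnames = dimnames(cm$counts))
    vals <- DESeq2::varianceStabilizingTransformation(m, blind = TRUE)
    return(normalized_matrix(vals, "vst", species = cm$species))
  }
  sf <- size_factors %||% size_factors_mor(cm$counts)
  stopifnot(length(sf) == ncol(cm$counts), all(sf > 0))
  vals <- log2(sweep(cm$counts, 2, sf, `/`) + 1)
  normalized_matrix(vals, "vst", species = cm$species)
}

#' Regress subject effects out of expression values
#'
#' Per gene, fits an intercept-only fixed effect plus a random intercept per
#' subject, and returns the overall intercept plus residuals (i.e. the
#' values minus the subject BLUPs). When the random-intercept variance is
#' estimated at zero (singular fit) or the gene has zero variance, the
#' original values are retained and the gene's `singular_fit_fallback` flag
#' is set. Run per species: mixing species in `meta` is an error.
#'
#' @param nm A `normalized_matrix` at stage `"vst"` (or later within
#'   species).
#' @param meta Sample metadata (needs `sample_id`, `species`, `subject_id`).
#' @return A `normalized_matrix` at stage `"subject_regressed"`.
#' @export
regress_subject <- function(nm, meta) {
  meta <- align_sample_meta(meta, nm)
  if (length(unique(meta$species)) > 1) {
    abort("regress_subject() must be run on a single species at a time.")
  }
  y <- nm$values
  fit <- lmm_fit_genes(y, matrix(1, ncol(y), 1), meta$subject_id)
  blup <- lmm_blups(fit, y)
  adjusted <- y - blup[, fit$z_idx, drop = FALSE]
  fallback <- fit$singular
  adjusted[fallback, ] <- y[fallback, , drop = FALSE]
  flags <- tibble(gene_id = rownames(y), singular_fit_fallback = fallback)
  normalized_matrix(adjusted, "subject_regressed", species = nm$species,
                    flags = flags)
}

#' Quantile-normalize two species' matrices over the combined sample set
#'
#' Classic quantile normalization: every sample's k-th order statistic is
#' replaced by the mean k-th order statistic across ALL samples of both
#' species; ties within a sample receive the mean of the reference values
#' they span. Inputs must be row-aligned on ortholog-pair IDs.
#'
#' @param nm_a,nm_b `normalized_matrix` objects sharing rownames (pair IDs).
#' @return One combined `normalized_matrix` at stage
#'   `"quantile_normalized"` containing both species' samples.
#' @export
quantile_normalize <- function(nm_a, nm_b) {
  if (!identical(rownames(nm_a$values), rownames(nm_b$values))) {
    abort("Matrices are not row-aligned on the same ortholog pairs.")
  }
  if (stage_rank(nm_a$stage) > 2 || stage_rank(nm_b$stage) > 2) {
    abort("Inputs are already quantile-normalized.")
  }
  combined <- cbind(nm_a$values, nm_b$values)
  qn <- limma::normalizeQuantiles(combined, ties = TRUE)
  dimnames(qn) <- dimnames(combined)
  flags <- tibble(
    gene_id = rownames(combined),
    singular_fit_fallback = nm_a$flags$singular_fit_fallback |
      nm_b$flags$singular_fit_fallback
  )
  normalized_matrix(qn, "quantile_normalized", species = "combined",
                    flags = flags)
}

#' Shared highly variable genes across species
#'
#' Ranks genes by variance of the (log-scale) values within each species,
#' takes the top `n_top` per species and intersects via the ortholog-pair
#' alignment. Variance ranking is invariant to the log base, so the values
#' are used as-is. Ties are broken deterministically (higher variance, then
#' lexicographic gene ID).
#'
#' @param nm_a,nm_b Row-aligned `normalized_matrix` objects (stage >= vst).
#' @param n_top Number of top-variance genes per species.
#' @return Character vector of shared pair IDs (possibly empty, with a
#'   warning when empty).
#' @export
select_hvg <- function(nm_a, nm_b, n_top = 2000) {
  if (!identical(rownames(nm_a$values), rownames(nm_b$values))) {
    abort("Matrices are not row-aligned on the same ortholog pairs.")
  }
  g <- nrow(nm_a$values)
  if (n_top > g) {
    warn(sprintf("n_top = %d exceeds gene count %d; using all genes.",
                 n_top, g))
    n_top <- g
  }
  top_set <- function(vals) {
    v <- apply(vals, 1, var)
    ord <- order(-v, rownames(vals))
    rownames(vals)[ord][seq_len(n_top)]
  }
  shared <- intersect(top_set(nm_a$values), top_set(nm_b$values))
  if (length(shared) == 0) {
    warn("No shared highly variable genes between the species.")
  }
  sort(shared)
}

#' Full cross-species preprocessing chain
#'
#' Ortholog restriction -> CPM eligibility filter (a gene must pass in both
#' species so the cross-species matrix stays row-aligned) -> VST -> per-gene
#' subject regression (per species) -> quantile normalization over the
#' combined sample set -> shared-HVG selection. Deterministic given inputs.
#'
#' @param cm_a,cm_b [count_matrix()] objects.
#' @param meta_a,meta_b Metadata tibbles.
#' @param orthologs 1:1 ortholog map tibble.
#' @param min_cpm,min_samples CPM filter parameters.
#' @param hvg_top Per-species top-variance set size.
#' @param vst_method Passed to [vst_counts()].
#' @return List: `vst_a`, `vst_b`, `regressed_a`, `regressed_b`, `qn`
#'   (combined quantile-normalized matrix), `hvg`, `map` (retained pairs),
#'   `log` (per-stage gene/sample counts).
#' @export
preprocess_cross_species <- function(cm_a, cm_b, meta_a, meta_b, orthologs,
                                     min_cpm = 1, min_samples = 3,
                                     hvg_top = 2000,
                                     vst_method = "log2-mor") {
  restricted <- restrict_to_orthologs(cm_a, cm_b, orthologs)
  keep_a <- cpm_filter(restricted$a, min_cpm, min_samples)
  keep_b <- cpm_filter(restricted$b, min_cpm, min_samples)
  keep <- intersect(keep_a, keep_b)
  if (length(keep) == 0) abort("No genes pass the CPM filter in both species.")
  ca <- count_matrix(restricted$a$counts[keep, , drop = FALSE],
                     species = cm_a$species)
  cb <- count_matrix(restricted$b$counts[keep, , drop = FALSE],
                     species = cm_b$species)

  vst_a <- vst_counts(ca, method = vst_method)
  vst_b <- vst_counts(cb, method = vst_method)
  reg_a <- regress_subject(vst_a, meta_a)
  reg_b <- regress_subject(vst_b, meta_b)
  qn <- quantile_normalize(reg_a, reg_b)
  hvg <- select_hvg(reg_a, reg_b, n_top = min(hvg_top, length(keep)))

  log <- tibble(
    stage = c("input_a", "input_b", "ortholog_restricted", "cpm_filtered",
              "hvg_shared"),
    n_genes = c(nrow(cm_a$counts), nrow(cm_b$counts), nrow(restricted$map),
                length(keep), length(hvg)),
    n_samples = c(ncol(cm_a$counts), ncol(cm_b$counts),
                  ncol(ca$counts) + ncol(cb$counts),
                  ncol(ca$counts) + ncol(cb$counts),
                  ncol(ca$counts) + ncol(cb$counts))
  )
  list(vst_a = vst_a, vst_b = vst_b,
       regressed_a = reg_a, regressed_b = reg_b,
       qn = qn, hvg = hvg, map = restricted$map, log = log)
}
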