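# Shared fixtures and independent oracles for the test suite.

# small paired cohort for fast end-to-end tests
small_cohort_config <- function(seed = 7, ...) {
  simulation_config(
    n_genes = 600, n_subtypes_a = 5, n_subtypes_b = 4,
    markers_per_subtype = 20, samples_per_subtype = 3,
    n_donors = 3, seed = seed, ...
  )
}

# criterion-scale recovery design: 8 subtypes per species, 4 planted pairs
recovery_config <- function(seed, rho = 1, effect = 4, n_genes = 2000) {
  simulation_config(
    n_genes = n_genes, n_subtypes_a = 8, n_subtypes_b = 8,
    homolog_pairs = data.frame(subtype_a = sprintf("A%02d", 1:4),
                               subtype_b = sprintf("B%02d", 1:4)),
    samples_per_subtype = 4, markers_per_subtype = 50,
    conservation_fraction = rho, marker_log2_effect = effect,
    seed = seed
  )
}

# run preprocess + marker scoring + homology on a cohort
run_homology <- function(cohort, hvg_top = 500, l = 1000) {
  prep <- suppressWarnings(preprocess_cross_species(
    cohort$counts_a, cohort$counts_b, cohort$meta_a, cohort$meta_b,
    cohort$orthologs, hvg_top = hvg_top
  ))
  qa <- subset_samples(prep$qn, cohort$meta_a$sample_id)
  qb <- subset_samples(prep$qn, cohort$meta_b$sample_id)
  ma <- marker_scores(qa, cohort$meta_a, test_values = prep$vst_a)
  mb <- marker_scores(qb, cohort$meta_b, test_values = prep$vst_b)
  hom <- suppressWarnings(cat_homology(ma, mb, l = l))
  list(prep = prep, markers_a = ma, markers_b = mb, homology = hom)
}

# assignment matches the planted homolog pairs in both directions
recovers_truth <- function(hom, truth_pairs) {
  ab <- hom$assignment_ab
  ba <- hom$assignment_ba
  ok_ab <- all(!is.na(match(truth_pairs$subtype_a, ab$ref_subtype))) &&
    all(ab$assigned[match(truth_pairs$subtype_a, ab$ref_subtype)] ==
          truth_pairs$subtype_b)
  ok_ba <- all(ba$assigned[match(truth_pairs$subtype_b, ba$ref_subtype)] ==
                 truth_pairs$subtype_a)
  ok_ab && ok_ba
}

# naive per-k set-intersection CAT oracle
naive_cat_curve <- function(ref, cand, l) {
  l_eff <- min(l, length(ref), length(cand))
  vapply(seq_len(l_eff), function(k) {
    length(intersect(ref[seq_len(k)], cand[seq_len(k)])) / k
  }, numeric(1))
}

# brute-force pairwise-comparison AUC oracle (ties count one half)
brute_auc <- function(x, y) {
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# 1-D transport oracle: L1 distance between quantile functions on the
# n1*n2 common refinement grid
brute_emd <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  qs <- (seq_len(n1 * n2) - 0.5) / (n1 * n2)
  q1 <- sort(x)[ceiling(qs * n1)]
  q2 <- sort(y)[ceiling(qs * n2)]
  mean(abs(q1 - q2))
}

# toy expression matrix: k subtypes x r replicates, deterministic jitter so
# within-subtype variance is positive but identical across genes
toy_subtype_matrix <- function(values_by_subtype, r = 3, jitter = 0.01) {
  k <- ncol(values_by_subtype)
  g <- nrow(values_by_subtype)
  n <- k * r
  jit <- rep(seq_len(r) - (r + 1) / 2, times = k) * jitter
  m <- values_by_subtype[, rep(seq_len(k), each = r), drop = FALSE] +
    matrix(jit, g, n, byrow = TRUE)
  rownames(m) <- rownames(values_by_subtype) %||%
    sprintf("g%02d", seq_len(g))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  meta <- tibble::tibble(
    sample_id = colnames(m),
    species = "toy",
    tissue = "toy",
    subtype = rep(colnames(values_by_subtype) %||%
                    sprintf("st%d", seq_len(k)), each = r),
    subject_id = sprintf("d%d", rep(seq_len(r), times = k))
  )
  list(nm = normalized_matrix(m, "quantile_normalized", species = "toy"),
       meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
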