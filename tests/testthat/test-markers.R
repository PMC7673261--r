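test_that("scaled medians equal hand-computed median ratios", {
  vals <- cbind(st1 = c(4, 0, 2), st2 = c(1, 0, 2), st3 = c(1, 0, 2))
  rownames(vals) <- c("gA", "gB", "gC")
  toy <- toy_subtype_matrix(vals, r = 2, jitter = 0)
  m1 <- scaled_median(toy$nm, toy$meta, "st1")
  # gA: median(st1) = 4, overall median = 1
  expect_equal(unname(m1["gA"]), 4 / (1 + 1e-8))
  # gB: zero everywhere -> 0
  expect_equal(unname(m1["gB"]), 0)
  # gC: constant 2 -> ~1 for every subtype
  expect_equal(unname(m1["gC"]), 2 / (2 + 1e-8))
  expect_error(scaled_median(toy$nm, toy$meta, "nope"), "Unknown subtype")
})

test_that("combine_z matches the normal-quantile closed forms", {
  expect_equal(combine_z(c(0.5, 0.5), c(1, 1)), 0, tolerance = 1e-9)
  expect_equal(combine_z(0.05, 1), qnorm(0.95), tolerance = 1e-9)
  expect_equal(combine_z(c(0.05, 0.05), c(1, 1)), 2 * qnorm(0.95) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(combine_z(0.05, -1), -qnorm(0.95), tolerance = 1e-9)
  # zero-sign effects use the conservative max(p, 1-p) branch
  expect_equal(combine_z(0.2, 0), qnorm(0.8, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(combine_z(numeric(0), numeric(0)), "at least one")
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(orthocat:::bh_adjust(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03), tolerance = 1e-12)
  expect_equal(orthocat:::bh_adjust(0.2), 0.2)
})

test_that("the F-test needs two subtypes and adjusts a single gene to itself", {
  y <- matrix(rnorm(8), 1, 8, dimnames = list("g1", sprintf("s%d", 1:8)))
  nm <- normalized_matrix(y, "vst", "sp")
  meta1 <- tibble::tibble(sample_id = colnames(y), species = "sp",
                          tissue = "t", subtype = "only",
                          subject_id = rep(c("d1", "d2"), 4))
  expect_error(overall_f_test(nm, meta1), "2 subtypes")
  meta2 <- meta1
  meta2$subtype <- rep(c("u", "v"), 4)
  ft <- overall_f_test(nm, meta2)
  expect_equal(ft$p_adjusted, ft$p_value)
})

test_that("two subtypes give one contrast agreeing with the overall test", {
  set.seed(12)
  y <- matrix(rnorm(40), 5, 8,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  nm <- normalized_matrix(y, "vst", "sp")
  meta <- tibble::tibble(sample_id = colnames(y), species = "sp",
                         tissue = "t", subtype = rep(c("u", "v"), each = 4),
                         subject_id = rep(c("d1", "d2", "d3", "d4"), 2))
  ct <- pairwise_contrast_p(nm, meta, "u")
  expect_equal(nrow(ct), 5)
  expect_setequal(unique(ct$other_subtype), "v")
  ft <- overall_f_test(nm, meta)
  # one contrast: squared t equals the F statistic
  expect_equal(ct$p_value, ft$p_value, tolerance = 1e-9)
})

test_that("planted markers get all-positive contrast signs and tiny p", {
  coh <- simulate_cohort(small_cohort_config(
    seed = 15, marker_log2_effect = 6, donor_sd = 0
  ))
  prep <- suppressWarnings(preprocess_cross_species(
    coh$counts_a, coh$counts_b, coh$meta_a, coh$meta_b, coh$orthologs,
    hvg_top = 100
  ))
  truth <- dplyr::filter(coh$truth$markers,
                         species == coh$counts_a$species,
                         subtype == "A01")
  ct <- pairwise_contrast_p(prep$vst_a, coh$meta_a, "A01")
  planted <- dplyr::filter(ct, gene_id %in% truth$pair_id)
  expect_true(all(planted$sign > 0))
  expect_true(all(planted$p_value < 0.05))
})

test_that("marker scores multiply m and Z and gate on eligibility", {
  coh <- simulate_cohort(small_cohort_config(seed = 16))
  res <- run_homology(coh)
  ma <- res$markers_a
  expect_equal(ma$score, ma$scaled_median * ma$z)
  expect_true(all(is.na(ma$rank[!ma$eligible])))
  expect_true(all(ma$eligible == (ma$p_adjusted <= 0.05 & ma$z > 0)))
  # ranks are 1..K and unique within subtype, ordered by decreasing score
  for (st in unique(ma$subtype)) {
    rows <- dplyr::arrange(dplyr::filter(ma, subtype == st,
                                         !is.na(rank)), rank)
    expect_identical(rows$rank, seq_len(nrow(rows)))
    expect_true(all(diff(rows$score) <= 1e-12))
  }
})

test_that("subtype relabeling permutes the marker table identically", {
  coh <- simulate_cohort(small_cohort_config(seed = 19))
  prep <- suppressWarnings(preprocess_cross_species(
    coh$counts_a, coh$counts_b, coh$meta_a, coh$meta_b, coh$orthologs,
    hvg_top = 100
  ))
  qa <- subset_samples(prep$qn, coh$meta_a$sample_id)
  ma <- marker_scores(qa, coh$meta_a, test_values = prep$vst_a)
  # relabel subtypes bijectively
  relab <- setNames(paste0("Z", seq_along(unique(coh$meta_a$subtype))),
                    sort(unique(coh$meta_a$subtype)))
  meta2 <- dplyr::mutate(coh$meta_a, subtype = unname(relab[subtype]))
  ma2 <- marker_scores(qa, meta2, test_values = prep$vst_a)
  ma2_back <- dplyr::mutate(ma2,
                            subtype = names(relab)[match(subtype, relab)])
  key <- function(t) dplyr::arrange(t, subtype, gene_id)
  expect_equal(key(ma2_back)$score, key(ma)$score, tolerance = 1e-12)
  expect_equal(key(ma2_back)$rank, key(ma)$rank)
})

test_that("marker scoring is deterministic", {
  coh <- simulate_cohort(small_cohort_config(seed = 23))
  r1 <- run_homology(coh)
  r2 <- run_homology(coh)
  expect_identical(r1$markers_a, r2$markers_a)
  expect_identical(r1$homology$mean_cat, r2$homology$mean_cat)
})

test_that("genes shared between two subtypes score below exclusive markers", {
  # noise-free construction (deterministic replicate jitter only):
  # one gene elevated in st1 only, one in st2 only, one in both
  vals <- rbind(
    only1 = c(3, 1, 1, 1),
    only2 = c(1, 3, 1, 1),
    both  = c(3, 3, 1, 1),
    flat  = c(1, 1, 1, 1)
  )
  colnames(vals) <- paste0("st", 1:4)
  toy <- toy_subtype_matrix(vals, r = 3, jitter = 0.01)
  ms <- marker_scores(toy$nm, toy$meta)
  sc <- function(g, st) ms$score[ms$gene_id == g & ms$subtype == st]
  zz <- function(g, st) ms$z[ms$gene_id == g & ms$subtype == st]
  expect_lt(zz("both", "st1"), zz("only1", "st1"))
  expect_lt(zz("both", "st2"), zz("only2", "st2"))
  expect_lt(sc("both", "st1"), sc("only1", "st1"))
  expect_lt(sc("both", "st2"), sc("only2", "st2"))
  # the flat gene is no marker for anything
  expect_true(all(ms$z[ms$gene_id == "flat"] < 1))
})

test_that("ranked marker lists follow the stored ranks", {
  coh <- simulate_cohort(small_cohort_config(seed = 27))
  res <- run_homology(coh)
  lst <- ranked_marker_list(res$markers_a, "A01")
  top <- dplyr::arrange(dplyr::filter(res$markers_a, subtype == "A01",
                                      !is.na(rank)), rank)
  expect_identical(lst, top$gene_id)
  expect_identical(ranked_marker_list(res$markers_a, "A01", max_len = 5),
                   top$gene_id[1:5])
})
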