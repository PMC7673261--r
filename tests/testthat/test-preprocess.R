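mk_cm <- function(m, species = "sp") count_matrix(m, species = species)

test_that("ortholog restriction aligns both matrices in pair order", {
  ca <- mk_cm(matrix(1:10, 5, 2, dimnames = list(paste0("a", 1:5),
                                                 c("s1", "s2"))), "A")
  cb <- mk_cm(matrix(1:10, 5, 2, dimnames = list(paste0("b", 1:5),
                                                 c("t1", "t2"))), "B")
  map_all <- tibble::tibble(gene_a = paste0("a", 5:1),
                            gene_b = paste0("b", 5:1))
  res <- restrict_to_orthologs(ca, cb, map_all)
  expect_equal(dim(res$a$counts), c(5, 2))
  expect_identical(rownames(res$a$counts), rownames(res$b$counts))
  expect_identical(rownames(res$a$counts), pair_ids(map_all))

  map2 <- map_all[2:3, ]
  res2 <- restrict_to_orthologs(ca, cb, map2)
  expect_equal(nrow(res2$a$counts), 2)
  expect_identical(res2$a$counts[1, ], ca$counts["a4", ])

  map_none <- tibble::tibble(gene_a = "zz", gene_b = "yy")
  expect_error(restrict_to_orthologs(ca, cb, map_none), "No ortholog")
})

test_that("restricted gene count equals the simulated ortholog pairs", {
  coh <- simulate_cohort(small_cohort_config(seed = 1))
  res <- restrict_to_orthologs(coh$counts_a, coh$counts_b, coh$orthologs)
  expect_equal(nrow(res$a$counts), nrow(coh$orthologs))
})

test_that("CPM filter applies the >1 CPM in >=3 samples rule", {
  m <- rbind(
    allzero = rep(0L, 6),
    kept    = c(2L, 2L, 2L, 0L, 0L, 0L),
    dropped = c(2L, 2L, 0L, 0L, 0L, 0L),
    filler  = rep(1000000L - 1004L, 6) + c(1002L, 1002L, 1000L, 1004L,
                                           1004L, 1004L)
  )
  # pad so every library sums to exactly 1e6
  m["filler", ] <- 1e6 - colSums(m[c("allzero", "kept", "dropped"), ])
  colnames(m) <- sprintf("s%d", 1:6)
  keep <- cpm_filter(mk_cm(m))
  expect_true("kept" %in% keep)
  expect_false("dropped" %in% keep)
  expect_false("allzero" %in% keep)

  m0 <- m
  m0[, 1] <- 0L
  expect_error(cpm_filter(mk_cm(m0)), "s1")
})

test_that("the VST removes exact multiplicative depth differences", {
  # counts that are exactly baseline x depth: size factors recover the
  # depths and every VST column is identical
  q <- c(10L, 25L, 40L, 80L, 160L)
  d <- c(1L, 2L, 3L, 5L)
  m <- outer(q, d)
  dimnames(m) <- list(sprintf("g%d", seq_along(q)),
                      sprintf("s%d", seq_along(d)))
  sf <- size_factors_mor(m)
  expect_equal(unname(sf / sf[1]), d / d[1], tolerance = 1e-12)
  v <- vst_counts(mk_cm(m))
  expect_lt(max(abs(v$values - v$values[, 1])), 1e-12)
  # zero counts map to zero; identical samples get identical columns
  set.seed(8)
  m3 <- matrix(rpois(60, 50) + 1L, 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  m3[1, ] <- 0L
  m3[, 2] <- m3[, 1]
  v3 <- vst_counts(mk_cm(m3))
  expect_true(all(v3$values[1, ] == 0))
  expect_identical(v3$values[, 1], v3$values[, 2])
})

test_that("median-of-ratios size factors match the direct formula and DESeq2", {
  set.seed(21)
  m <- matrix(rnbinom(200, mu = 100, size = 5) + 1L, 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  sf <- size_factors_mor(m)
  # direct formula oracle: log-scale median of ratios to the
  # geometric-mean reference
  ref <- exp(rowMeans(log(m)))
  oracle <- apply(log(m / ref), 2, function(v) exp(median(v)))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
  skip_if_not_installed("DESeq2")
  ds <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ds), tolerance = 1e-10)
})

test_that("size factors fall back to library size without all-positive genes", {
  m <- matrix(c(0L, 5L, 3L, 0L, 0L, 8L), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_warning(sf <- size_factors_mor(m), "library-size")
  libs <- colSums(m)
  expect_equal(unname(sf), unname(libs / median(libs)))
})

test_that("subject regression falls back on unidentified or constant genes", {
  n <- 8
  y <- rbind(
    normal = rnorm(n),
    constant = rep(2, n)
  )
  colnames(y) <- sprintf("s%d", 1:n)
  nm <- normalized_matrix(y, "vst", species = "sp")
  meta <- tibble::tibble(sample_id = colnames(y), species = "sp",
                         tissue = "t", subtype = rep(c("u", "v"), 4),
                         subject_id = sprintf("d%d", 1:n))
  reg <- regress_subject(nm, meta)
  # one sample per subject: every gene is returned unchanged and flagged
  expect_identical(reg$values, y)
  expect_true(all(reg$flags$singular_fit_fallback))
  expect_equal(reg$stage, "subject_regressed")

  meta_mixed <- meta
  meta_mixed$species[1] <- "other"
  expect_error(regress_subject(nm, meta_mixed), "single species")
})

test_that("subject regression matches the per-donor-centering oracle", {
  set.seed(17)
  n_don <- 20; spd <- 4; n <- n_don * spd; g <- 80
  donor_sd <- 1
  subject <- rep(sprintf("d%02d", seq_len(n_don)), each = spd)
  y <- matrix(0, g, n, dimnames = list(sprintf("g%03d", 1:g),
                                       sprintf("s%03d", 1:n)))
  for (gi in seq_len(g)) {
    off <- rnorm(n_don, 0, donor_sd)
    y[gi, ] <- 4 + off[rep(seq_len(n_don), each = spd)] + rnorm(n, 0, 0.2)
  }
  nm <- normalized_matrix(y, "vst", species = "sp")
  meta <- tibble::tibble(sample_id = colnames(y), species = "sp",
                         tissue = "t",
                         subtype = rep(c("u", "v"), n / 2),
                         subject_id = subject)
  reg <- regress_subject(nm, meta)
  oracle <- y
  for (gi in seq_len(g)) {
    dm <- tapply(y[gi, ], subject, mean)
    oracle[gi, ] <- y[gi, ] - dm[subject] + mean(dm)
  }
  keep <- !reg$flags$singular_fit_fallback
  expect_gt(mean(keep), 0.9)
  rmse <- sqrt(mean((reg$values[keep, ] - oracle[keep, ])^2))
  expect_lt(rmse, 0.05 * donor_sd)
  # grand means preserved up to the intercept estimate
  expect_lt(max(abs(rowMeans(reg$values[keep, ]) - rowMeans(y[keep, ]))),
            1e-6)
})

test_that("quantile normalization equalizes distributions with the tie rule", {
  m1 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  m2 <- matrix(c(4, 5, 6), 3, 1, dimnames = list(paste0("g", 1:3), "s2"))
  qn <- quantile_normalize(normalized_matrix(m1, "vst", "A"),
                           normalized_matrix(m2, "vst", "B"))
  expect_equal(unname(qn$values[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, "s2"]), c(2.5, 3.5, 4.5))

  set.seed(4)
  a <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("a%d", 1:6)))
  b <- matrix(rexp(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("b%d", 1:4)))
  qn2 <- quantile_normalize(normalized_matrix(a, "vst", "A"),
                            normalized_matrix(b, "vst", "B"))
  sorted <- apply(qn2$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # within-sample ranks preserved
  for (j in seq_len(ncol(a))) {
    expect_identical(rank(qn2$values[, j]), rank(a[, j]))
  }
  # misaligned rows -> error
  b2 <- b
  rownames(b2) <- rev(rownames(b2))
  expect_error(quantile_normalize(normalized_matrix(a, "vst", "A"),
                                  normalized_matrix(b2, "vst", "B")),
               "row-aligned")
})

test_that("shared HVG selection intersects per-species top-variance sets", {
  set.seed(2)
  base <- matrix(rnorm(200, sd = 0.1), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
  hv <- sprintf("g%02d", 1:5)
  a <- base
  a[hv, ] <- rnorm(50, sd = 5)
  nm_a <- normalized_matrix(a, "vst", "A")
  # identical matrices: intersection is the top set itself
  expect_setequal(select_hvg(nm_a, nm_a, n_top = 5), hv)
  # disjoint top sets: empty + warning
  b <- base
  b[sprintf("g%02d", 6:10), ] <- rnorm(50, sd = 5)
  nm_b <- normalized_matrix(b, "vst", "B")
  expect_warning(sh <- select_hvg(nm_a, nm_b, n_top = 5), "No shared")
  expect_length(sh, 0)
  # n_top beyond the gene count warns and uses all genes
  expect_warning(all_g <- select_hvg(nm_a, nm_a, n_top = 100), "exceeds")
  expect_length(all_g, 20)
})

test_that("planted high-variance genes are recovered across species", {
  set.seed(14)
  g <- 300
  hv <- sprintf("pair%03d", 1:30)
  ids <- sprintf("pair%03d", 1:g)
  mk <- function() {
    m <- matrix(rnorm(g * 12, sd = 0.2), g, 12,
                dimnames = list(ids, sprintf("s%02d", 1:12)))
    m[hv, ] <- matrix(rnorm(30 * 12, sd = 3), 30, 12)
    m
  }
  sh <- select_hvg(normalized_matrix(mk(), "vst", "A"),
                   normalized_matrix(mk(), "vst", "B"), n_top = 40)
  expect_gte(mean(hv %in% sh), 0.9)
})

test_that("the full preprocessing chain is deterministic and staged", {
  coh <- simulate_cohort(small_cohort_config(seed = 6))
  p1 <- suppressWarnings(preprocess_cross_species(
    coh$counts_a, coh$counts_b, coh$meta_a, coh$meta_b, coh$orthologs,
    hvg_top = 100
  ))
  p2 <- suppressWarnings(preprocess_cross_species(
    coh$counts_a, coh$counts_b, coh$meta_a, coh$meta_b, coh$orthologs,
    hvg_top = 100
  ))
  expect_identical(p1$qn$values, p2$qn$values)
  expect_identical(p1$hvg, p2$hvg)
  expect_equal(p1$qn$stage, "quantile_normalized")
  expect_true(all(rownames(p1$qn$values) %in% pair_ids(coh$orthologs)))
})
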