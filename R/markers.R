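# Subtype-specific marker-gene scoring.
#
# score(gene, subtype) = m * Z where
#   m = median expression in the subtype / (species-wide median + eps)
#   Z = Stouffer combination over all pairwise subtype contrasts from a
#       per-gene random-intercept mixed model, with p_i used as-is when the
#       subtype of interest is higher and max(p_i, 1 - p_i) when lower —
#       so genes elevated in several subtypes (core signature genes) are
#       penalized and single-subtype markers rise to the top.
# Genes enter the ranking only when the overall F-test survives BH
# adjustment (p.adj <= alpha) and Z > 0.

bh_adjust <- function(p) p.adjust(p, method = "BH")

fit_subtype_model <- function(nm, meta) {
  meta <- align_sample_meta(meta, nm)
  if (length(unique(meta$species)) > 1) {
    abort("Marker scoring must be run on a single species at a time.")
  }
  subtype <- factor(meta$subtype)
  if (nlevels(subtype) < 2) abort("Need at least 2 subtypes.")
  if (nlevels(factor(meta$subject_id)) < 2) {
    abort("Need at least 2 subjects.")
  }
  x <- stats::model.matrix(~subtype)
  fit <- lmm_fit_genes(nm$values, x, meta$subject_id)
  fit$subtype_levels <- levels(subtype)
  fit
}

#' Median expression scaled by the species-wide median
#'
#' For each gene, the median over the subtype's samples divided by the
#' median over all samples of the species (plus a small epsilon to avoid
#' 0/0). Scaling by the overall median separates genes expressed primarily
#' in a minority of subtypes from uniformly high housekeeping genes. A gene
#' whose subtype median is 0 gets m = 0; a gene whose overall median is 0
#' but subtype median positive gets the subtype median itself.
#'
#' @param nm A `normalized_matrix` (quantile-normalized in the standard
#'   pipeline).
#' @param meta Sample metadata for the species.
#' @param subtype Subtype label of interest.
#' @return Named numeric vector of m values per gene.
#' @export
scaled_median <- function(nm, meta, subtype) {
  meta <- align_sample_meta(meta, nm)
  if (!subtype %in% meta$subtype) {
    abort(paste0("Unknown subtype: ", subtype))
  }
  in_st <- meta$subtype == subtype
  med_st <- apply(nm$values[, in_st, drop = FALSE], 1, median)
  med_all <- apply(nm$values, 1, median)
  m <- ifelse(
    med_st == 0, 0,
    ifelse(med_all == 0, med_st, med_st / (med_all + .ORTHOCAT_EPS))
  )
  setNames(m, rownames(nm$values))
}

#' Overall mixed-model F-test for any subtype effect
#'
#' Per gene, fits expression ~ subtype (fixed) + subject (random intercept)
#' and tests all subtype coefficients jointly with a Wald F statistic.
#' The default `"kenward-roger"` uses the Kackar-Harville-adjusted
#' coefficient covariance with Kenward-Roger moment-matched scale and
#' denominator df, computed natively from the REML fit -- calibrated at the
#' boundary where the random-intercept variance is truly zero, a common
#' case in sorted-population compendia. Singular fits reduce to the exact
#' OLS F.
#' `"satterthwaite"` uses the unadjusted covariance with Satterthwaite df
#' (matching lmerTest), `"residual"` always uses n - k, and `"lmertest"`
#' refits each gene with lmerTest (slow; intended as a cross-check).
#' P-values are BH-adjusted across genes. Degenerate genes (zero variance)
#' get p = 1.
#'
#' @param nm A `normalized_matrix` for one species.
#' @param meta Sample metadata.
#' @param df_method `"kenward-roger"` (default), `"satterthwaite"`,
#'   `"residual"` or `"lmertest"`.
#' @return Tibble: `gene_id`, `statistic`, `df1`, `df2`, `p_value`,
#'   `p_adjusted`, `singular_fit`.
#' @export
overall_f_test <- function(nm, meta,
                           df_method = c("kenward-roger", "satterthwaite",
                                         "residual", "lmertest")) {
  df_method <- match.arg(df_method)
  if (df_method == "lmertest") {
    return(overall_f_test_lmertest(nm, meta))
  }
  fit <- fit_subtype_model(nm, meta)
  res <- wald_f_subtype(fit, df_method)
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}

wald_f_subtype <- function(fit, df_method = "kenward-roger") {
  p <- fit$p
  r <- p - 1L
  g <- length(fit$sigma2)
  l_rows <- cbind(0, diag(r))
  stat <- rep(NA_real_, g)
  ddf <- rep(as.numeric(fit$df_resid), g)
  pv <- rep(NA_real_, g)
  if (df_method == "kenward-roger") fit <- ensure_kr_cache(fit)
  if (df_method == "satterthwaite") fit <- ensure_satt_cache(fit)
  for (gi in seq_len(g)) {
    if (fit$zero_variance[gi] || fit$sigma2[gi] <= 0) next
    if (df_method == "kenward-roger") {
      res <- kr_f_test(fit, gi, l_rows)
      stat[gi] <- res[1]; ddf[gi] <- res[2]; pv[gi] <- res[3]
    } else {
      b <- fit$beta[gi, -1]
      vc <- fit$cov_unscaled[-1, -1, gi] * fit$sigma2[gi]
      stat[gi] <- drop(crossprod(b, solve(vc, b))) / r
      if (df_method == "satterthwaite" && !fit$singular[gi]) {
        ddf[gi] <- satt_f_ddf(fit, gi, l_rows)
      }
      pv[gi] <- pf(stat[gi], r, ddf[gi], lower.tail = FALSE)
    }
  }
  pv[is.na(pv)] <- 1
  tibble(
    gene_id = fit$gene_ids,
    statistic = stat,
    df1 = r,
    df2 = ddf,
    p_value = pv,
    singular_fit = fit$singular
  )
}

overall_f_test_lmertest <- function(nm, meta) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    abort("df_method = \"lmertest\" requires the lmerTest package.")
  }
  meta <- align_sample_meta(meta, nm)
  subtype <- factor(meta$subtype)
  if (nlevels(subtype) < 2) abort("Need at least 2 subtypes.")
  subject <- factor(meta$subject_id)
  rows <- purrr::map(rownames(nm$values), function(gid) {
    dat <- data.frame(y = nm$values[gid, ], subtype = subtype,
                      subject = subject)
    out <- tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(y ~ subtype + (1 | subject), data = dat)
      ))
      an <- suppressWarnings(stats::anova(fit, ddf = "Satterthwaite"))
      tibble(gene_id = gid, statistic = an[["F value"]][1],
             df1 = an[["NumDF"]][1], df2 = an[["DenDF"]][1],
             p_value = an[["Pr(>F)"]][1],
             singular_fit = lme4::isSingular(fit))
    }, error = function(e) {
      tibble(gene_id = gid, statistic = NA_real_, df1 = NA_real_,
             df2 = NA_real_, p_value = 1, singular_fit = TRUE)
    })
    out
  })
  res <- bind_rows(rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}

#' Pairwise subtype contrasts for one subtype of interest
#'
#' Tests the coefficient contrast (subtype of interest minus each other
#' subtype) in the per-gene mixed model: two-sided p-value and the sign of
#' the estimated effect. Uses the same fitted model as [overall_f_test()].
#'
#' @inheritParams overall_f_test
#' @param subtype Subtype of interest.
#' @return Tibble: `gene_id`, `other_subtype`, `estimate`, `p_value`,
#'   `sign`.
#' @export
pairwise_contrast_p <- function(nm, meta, subtype,
                                df_method = c("kenward-roger",
                                              "satterthwaite", "residual",
                                              "lmertest")) {
  df_method <- match.arg(df_method)
  if (df_method == "lmertest") {
    meta <- align_sample_meta(meta, nm)
    return(pairwise_contrast_lmertest(nm, meta, subtype))
  }
  fit <- fit_subtype_model(nm, meta)
  contrast_table(fit, subtype, df_method)
}

# All (gene, other subtype) contrasts for one subtype of interest, from a
# shared fit, as genes x contrasts matrices. Reference-coded design: the
# reference level's coefficient is implicit zero, handled through the
# contrast vector.
contrast_matrices <- function(fit, subtype, df_method = "kenward-roger") {
  lv <- fit$subtype_levels
  if (!subtype %in% lv) abort(paste0("Unknown subtype: ", subtype))
  others <- setdiff(lv, subtype)
  g <- length(fit$sigma2)
  p <- fit$p
  cu <- matrix(fit$cov_unscaled, p * p, g)   # vec'd per-gene covariances
  if (df_method == "kenward-roger") fit <- ensure_kr_cache(fit)
  if (df_method == "satterthwaite" && is.null(fit$satt)) {
    fit <- ensure_satt_cache(fit)
  }
  coef_of <- function(st) {
    v <- numeric(p)
    j <- match(st, lv)
    if (j > 1) v[j] <- 1
    v
  }
  ci <- coef_of(subtype)
  est <- pmat <- smat <- matrix(NA_real_, g, length(others),
                                dimnames = list(fit$gene_ids, others))
  for (oi in seq_along(others)) {
    cv <- ci - coef_of(others[oi])
    e <- drop(fit$beta %*% cv)
    quad <- drop(crossprod(as.vector(tcrossprod(cv)), cu))
    se <- sqrt(pmax(fit$sigma2 * quad, 0))
    tt <- ifelse(se > 0, e / se, 0)
    ddf <- rep(as.numeric(fit$df_resid), g)
    if (df_method == "kenward-roger") {
      pv <- 2 * pt(-abs(tt), df = ddf)
      for (gi in which(!fit$singular & fit$sigma2 > 0)) {
        res <- kr_contrast(fit, gi, cv)
        pv[gi] <- res[2]
      }
    } else {
      if (df_method == "satterthwaite") {
        for (gi in which(!fit$singular & fit$sigma2 > 0)) {
          ddf[gi] <- satt_contrast_df(fit, gi, cv)
        }
      }
      pv <- 2 * pt(-abs(tt), df = ddf)
    }
    pv[se == 0] <- 1
    est[, oi] <- e
    pmat[, oi] <- pv
    smat[, oi] <- sign(e)
  }
  list(estimate = est, p = pmat, sign = smat, others = others)
}

contrast_table <- function(fit, subtype, df_method = "kenward-roger") {
  cm <- contrast_matrices(fit, subtype, df_method)
  bind_rows(lapply(seq_along(cm$others), function(oi) {
    tibble(gene_id = fit$gene_ids, other_subtype = cm$others[oi],
           estimate = unname(cm$estimate[, oi]),
           p_value = unname(cm$p[, oi]),
           sign = unname(cm$sign[, oi]))
  }))
}

#' Stouffer combination of directional pairwise p-values
#'
#' Each two-sided pairwise p-value enters as p_i when the subtype of
#' interest was higher (positive sign) and as max(p_i, 1 - p_i) when lower
#' or when the estimated effect is exactly zero (conservative for
#' markerhood). Then z_i = qnorm(1 - p'_i) and Z = sum(z_i)/sqrt(m)
#' (unweighted). P-values are clipped to [1e-300, 1 - 1e-16] before
#' inversion.
#'
#' @param p Numeric vector of two-sided p-values in (0, 1).
#' @param sign Numeric vector of effect signs (+1 / 0 / -1).
#' @return The combined Z (scalar).
#' @export
combine_z <- function(p, sign) {
  if (length(p) == 0) abort("Need at least one pairwise contrast.")
  stopifnot(length(p) == length(sign))
  p_dir <- ifelse(sign > 0, p, pmax(p, 1 - p))
  p_dir <- pmin(pmax(p_dir, 1e-300), 1 - 1e-16)
  z <- qnorm(p_dir, lower.tail = FALSE)
  sum(z) / sqrt(length(z))
}

# vectorized over genes: p and sgn are genes x contrasts matrices
combine_z_matrix <- function(p, sgn) {
  p_dir <- ifelse(sgn > 0, p, pmax(p, 1 - p))
  p_dir <- pmin(pmax(p_dir, 1e-300), 1 - 1e-16)
  z <- qnorm(p_dir, lower.tail = FALSE)
  rowSums(z) / sqrt(ncol(z))
}

#' Marker-gene scores for every (gene, subtype) of one species
#'
#' Combines the scaled median m, the combined contrast Z and the overall
#' F-test gate into the final marker table. Within each subtype, genes are
#' ranked by decreasing score s = m * Z among eligible genes (BH-adjusted
#' overall-F p <= alpha AND Z > 0); ties break by higher m, then gene ID.
#'
#' The mixed-model route (F-test and contrasts) can run on a different
#' matrix than the median route via `test_values`: the standard pipeline
#' computes medians on quantile-normalized values and fits the models on
#' the VST values.
#'
#' @param nm `normalized_matrix` used for the scaled medians
#'   (quantile-normalized in the standard pipeline), one species' samples.
#' @param meta Sample metadata for that species.
#' @param alpha BH-adjusted significance gate for the overall F-test.
#' @param df_method `"kenward-roger"` (default, native), `"satterthwaite"`,
#'   `"residual"` or `"lmertest"` (slow cross-check).
#' @param test_values Optional `normalized_matrix` with the same genes and
#'   samples used for the mixed-model tests (defaults to `nm`).
#' @return A tibble of class `marker_table`: `gene_id`, `subtype`,
#'   `scaled_median`, `z`, `p_value`, `p_adjusted`, `score`, `eligible`,
#'   `rank` (NA for ineligible rows).
#' @export
marker_scores <- function(nm, meta, alpha = 0.05,
                          df_method = c("kenward-roger", "satterthwaite",
                                        "residual", "lmertest"),
                          test_values = NULL) {
  df_method <- match.arg(df_method)
  tv <- test_values %||% nm
  if (!identical(rownames(tv$values), rownames(nm$values))) {
    abort("`test_values` must share genes (and order) with `nm`.")
  }
  meta <- align_sample_meta(meta, nm)
  tv <- subset_samples(tv, meta$sample_id)

  if (df_method != "lmertest") {
    fit <- fit_subtype_model(tv, meta)
    if (df_method == "kenward-roger") fit <- ensure_kr_cache(fit)
    if (df_method == "satterthwaite") fit <- ensure_satt_cache(fit)
    ftab <- wald_f_subtype(fit, df_method)
    ftab$p_adjusted <- bh_adjust(ftab$p_value)
  } else {
    fit <- NULL
    ftab <- overall_f_test(tv, meta, df_method = "lmertest")
  }
  subtypes <- sort(unique(meta$subtype))

  per_subtype <- purrr::map(subtypes, function(st) {
    m <- scaled_median(nm, meta, st)
    if (df_method != "lmertest") {
      cmats <- contrast_matrices(fit, st, df_method)
      pmat <- cmats$p
      smat <- cmats$sign
    } else {
      ct <- pairwise_contrast_lmertest(tv, meta, st)
      others <- unique(ct$other_subtype)
      g <- nrow(nm$values)
      # rows come gene-block-wise: k-1 contrasts per gene
      pmat <- t(matrix(ct$p_value, length(others), g))
      smat <- t(matrix(ct$sign, length(others), g))
      stopifnot(identical(unique(ct$gene_id), rownames(nm$values)))
    }
    z <- unname(combine_z_matrix(pmat, smat))
    tibble(
      gene_id = rownames(nm$values),
      subtype = st,
      scaled_median = unname(m),
      z = z,
      p_value = ftab$p_value,
      p_adjusted = ftab$p_adjusted,
      score = unname(m) * z
    )
  })
  tab <- bind_rows(per_subtype) |>
    mutate(eligible = .data$p_adjusted <= alpha & .data$z > 0) |>
    group_by(.data$subtype) |>
    arrange(desc(.data$score), desc(.data$scaled_median), .data$gene_id,
            .by_group = TRUE) |>
    mutate(rank = if_else(.data$eligible,
                          cumsum(.data$eligible), NA_integer_)) |>
    ungroup()
  class(tab) <- c("marker_table", class(tab))
  attr(tab, "species") <- unique(meta$species)
  attr(tab, "alpha") <- alpha
  tab
}

pairwise_contrast_lmertest <- function(nm, meta, subtype) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    abort("df_method = \"lmertest\" requires the lmerTest package.")
  }
  fac <- factor(meta$subtype)
  lv <- levels(fac)
  others <- setdiff(lv, subtype)
  subject <- factor(meta$subject_id)
  p <- length(lv)
  coef_of <- function(st) {
    v <- numeric(p); j <- match(st, lv); if (j > 1) v[j] <- 1; v
  }
  rows <- purrr::map(rownames(nm$values), function(gid) {
    dat <- data.frame(y = nm$values[gid, ], subtype = fac, subject = subject)
    tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(y ~ subtype + (1 | subject), data = dat)
      ))
      bind_rows(lapply(others, function(ot) {
        cv <- coef_of(subtype) - coef_of(ot)
        ct <- as.data.frame(lmerTest::contest1D(fit, cv))
        tibble(gene_id = gid, other_subtype = ot,
               estimate = ct$Estimate, p_value = ct$`Pr(>|t|)`,
               sign = sign(ct$Estimate))
      }))
    }, error = function(e) {
      tibble(gene_id = gid, other_subtype = others, estimate = NA_real_,
             p_value = 1, sign = 0)
    })
  })
  bind_rows(rows)
}

#' Ranked marker list for one subtype
#'
#' @param markers A `marker_table`.
#' @param subtype Subtype label.
#' @param max_len Optional truncation length.
#' @return Character vector of gene (pair) IDs in rank order.
#' @export
ranked_marker_list <- function(markers, subtype, max_len = Inf) {
  rows <- markers |>
    filter(.data$subtype == !!subtype, !is.na(.data$rank)) |>
    arrange(.data$rank)
  head(rows$gene_id, max_len)
}
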