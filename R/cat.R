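# Correspondence-at-the-top (CAT) homology assignment.
#
# For two ranked marker lists on the shared ortholog-pair coordinate system,
# overlap_k = |top_k(ref) intersect top_k(cand)| / k. The homology statistic
# is the mean of overlap_k over k = 1..L (L = 1000 by default); each
# reference subtype is assigned the candidate subtype of the other species
# maximizing that mean. Assignment need not be reciprocal.

#' CAT overlap curve between two ranked lists
#'
#' Computed incrementally: a shared gene enters the running intersection at
#' k = max(position in ref, position in cand), so one `tabulate` +
#' `cumsum` yields every k at once (equivalent to per-k set intersection).
#'
#' @param ref,cand Character vectors of ranked gene IDs (no duplicates),
#'   decreasing score.
#' @param l Maximum list size L; the curve runs to
#'   `min(l, length(ref), length(cand))`, with a warning when shorter than
#'   `l`.
#' @return Numeric vector `overlap_k`, k = 1..L'.
#' @export
cat_curve <- function(ref, cand, l = 1000) {
  if (length(ref) == 0 || length(cand) == 0) {
    abort("Ranked lists must be non-empty.")
  }
  if (anyDuplicated(ref) || anyDuplicated(cand)) {
    abort("Ranked lists must not contain duplicate genes.")
  }
  l_eff <- min(l, length(ref), length(cand))
  if (l_eff < l) {
    warn(sprintf("Lists support only L = %d (< %d requested).", l_eff, l))
  }
  pos <- match(ref[seq_len(l_eff)], cand)
  enter <- pmax(seq_len(l_eff), pos)
  enter <- enter[!is.na(enter) & enter <= l_eff]
  cumsum(tabulate(enter, nbins = l_eff)) / seq_len(l_eff)
}

#' Mean CAT overlap of a curve
#'
#' Arithmetic mean of overlap_k over the available k (k = 1..L').
#'
#' @param overlap Numeric overlap curve from [cat_curve()].
#' @param l Nominal L; a warning records the effective L when shorter.
#' @return Scalar mean overlap in [0, 1].
#' @export
mean_cat <- function(overlap, l = 1000) {
  if (length(overlap) < l) {
    warn(sprintf("Averaging over effective L = %d (< %d).",
                 length(overlap), l))
  }
  mean(overlap)
}

#' Min-max scale each row of a matrix to [0, 1]
#'
#' Emphasizes each row's strongest correspondence. Constant rows become all
#' zeros, with a warning.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with rows spanning [0, 1].
#' @export
scale_rows_minmax <- function(m) {
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warn(sprintf("%d constant row(s) scaled to all zeros.", sum(const)))
    span[const] <- 1
  }
  out <- (m - rng[1, ]) / span
  out[const, ] <- 0
  dimnames(out) <- dimnames(m)
  out
}

#' Assign each reference subtype its best-matching candidate
#'
#' Per row of the mean-CAT matrix, the candidate with the maximal mean
#' overlap. Exact ties are all reported (lexicographic candidate order).
#'
#' @param mean_cat_matrix Numeric matrix, rows = reference subtypes,
#'   columns = candidate subtypes.
#' @return Tibble: `ref_subtype`, `assigned`, `mean_cat`, `tie`.
#' @export
assign_homologs <- function(mean_cat_matrix) {
  purrr::map_dfr(rownames(mean_cat_matrix), function(ref) {
    row <- mean_cat_matrix[ref, ]
    best <- max(row)
    winners <- sort(colnames(mean_cat_matrix)[row == best])
    tibble(ref_subtype = ref, assigned = winners, mean_cat = best,
           tie = length(winners) > 1)
  })
}

#' Cross-species homology by mean CAT overlap of ranked marker lists
#'
#' Builds the ranked marker list of every subtype in each species from the
#' marker tables (ortholog-pair gene IDs), computes CAT curves for every
#' cross-species subtype pair, averages them over k = 1..L, and assigns
#' homologs in both directions by the row maximum.
#'
#' @param markers_a,markers_b `marker_table` tibbles from [marker_scores()]
#'   for the two species (gene IDs must be the shared pair IDs).
#' @param l List-size cap L (default 1000).
#' @return A `homology_result`: list with `curves` (long tibble: ref
#'   species/subtype, cand subtype, k, overlap, for both directions),
#'   `mean_cat` (matrix, rows = species-A subtypes), `scaled` (row
#'   min-max-scaled `mean_cat`), `assignment_ab`, `assignment_ba`, `l`,
#'   `l_effective`.
#' @export
cat_homology <- function(markers_a, markers_b, l = 1000) {
  sts_a <- sort(unique(markers_a$subtype))
  sts_b <- sort(unique(markers_b$subtype))
  lists_a <- lapply(setNames(sts_a, sts_a), function(st) {
    ranked_marker_list(markers_a, st)
  })
  lists_b <- lapply(setNames(sts_b, sts_b), function(st) {
    ranked_marker_list(markers_b, st)
  })
  empty_a <- names(lists_a)[lengths(lists_a) == 0]
  empty_b <- names(lists_b)[lengths(lists_b) == 0]
  if (length(empty_a) > 0 || length(empty_b) > 0) {
    abort(paste0("Subtype(s) with no eligible marker genes: ",
                 paste(c(empty_a, empty_b), collapse = ", ")))
  }

  m <- matrix(NA_real_, length(sts_a), length(sts_b),
              dimnames = list(sts_a, sts_b))
  l_eff <- Inf
  curve_rows <- list()
  for (sa in sts_a) {
    for (sb in sts_b) {
      curve <- suppressWarnings(cat_curve(lists_a[[sa]], lists_b[[sb]], l))
      l_eff <- min(l_eff, length(curve))
      m[sa, sb] <- mean(curve)
      curve_rows[[paste(sa, sb)]] <- tibble(
        ref_subtype = sa, cand_subtype = sb,
        k = seq_along(curve), overlap = curve
      )
    }
  }
  if (l_eff < l) {
    warn(sprintf("Shortest marker list supports L = %d (< %d requested).",
                 l_eff, l))
  }
  structure(list(
    curves = bind_rows(curve_rows),
    mean_cat = m,
    scaled = suppressWarnings(scale_rows_minmax(m)),
    assignment_ab = assign_homologs(m),
    assignment_ba = assign_homologs(t(m)),
    l = l,
    l_effective = l_eff
  ), class = "homology_result")
}

#' @export
print.homology_result <- function(x, ...) {
  cat(sprintf(
    "<homology_result> %d x %d subtypes, mean CAT over k = 1..%d\n",
    nrow(x$mean_cat), ncol(x$mean_cat), x$l_effective
  ))
  ab <- filter(x$assignment_ab, !duplicated(.data$ref_subtype))
  for (i in seq_len(nrow(ab))) {
    cat(sprintf("  %s -> %s (%.1f%%)\n", ab$ref_subtype[i], ab$assigned[i],
                100 * ab$mean_cat[i]))
  }
  invisible(x)
}

#' Tidy a homology result into one row per subtype pair
#'
#' @param x A `homology_result`.
#' @param ... Unused.
#' @return Tibble: `ref_subtype`, `cand_subtype`, `mean_cat`, `scaled`,
#'   `best_ab` (candidate is the ref's assigned homolog), `best_ba`.
#' @export
tidy.homology_result <- function(x, ...) {
  ab <- x$assignment_ab
  ba <- x$assignment_ba
  tidyr::expand_grid(ref_subtype = rownames(x$mean_cat),
                     cand_subtype = colnames(x$mean_cat)) |>
    mutate(
      mean_cat = x$mean_cat[cbind(.data$ref_subtype, .data$cand_subtype)],
      scaled = x$scaled[cbind(.data$ref_subtype, .data$cand_subtype)],
      best_ab = paste(.data$ref_subtype, .data$cand_subtype) %in%
        paste(ab$ref_subtype, ab$assigned),
      best_ba = paste(.data$cand_subtype, .data$ref_subtype) %in%
        paste(ba$ref_subtype, ba$assigned)
    )
}

#' One-row summary of a homology result
#'
#' @param x A `homology_result`.
#' @param ... Unused.
#' @return Tibble with subtype counts, effective L, the range of assigned
#'   mean CAT overlaps, and the number of reciprocal assignments.
#' @export
glance.homology_result <- function(x, ...) {
  ab <- filter(x$assignment_ab, !duplicated(.data$ref_subtype))
  ba <- filter(x$assignment_ba, !duplicated(.data$ref_subtype))
  recip <- sum(paste(ab$ref_subtype, ab$assigned) %in%
                 paste(ba$assigned, ba$ref_subtype))
  tibble(
    n_ref = nrow(x$mean_cat),
    n_cand = ncol(x$mean_cat),
    l = x$l,
    l_effective = x$l_effective,
    min_assigned_cat = min(ab$mean_cat),
    max_assigned_cat = max(ab$mean_cat),
    n_reciprocal = recip
  )
}

#' CAT curve panels for a homology result
#'
#' One panel per reference subtype; each line is a candidate subtype of the
#' other species, the assigned homolog highlighted, with a vertical line at
#' the list-size cap L.
#'
#' @param object A `homology_result`.
#' @param direction `"ab"` (species-A references, default) or `"ba"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.homology_result <- function(object, direction = c("ab", "ba"),
                                     ...) {
  direction <- match.arg(direction)
  curves <- object$curves
  assign <- object$assignment_ab
  if (direction == "ba") {
    curves <- rename(curves, ref_subtype = "cand_subtype",
                     cand_subtype = "ref_subtype")
    assign <- object$assignment_ba
  }
  curves <- curves |>
    mutate(best = paste(.data$ref_subtype, .data$cand_subtype) %in%
             paste(assign$ref_subtype, assign$assigned))
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$k, y = 100 * .data$overlap,
    group = .data$cand_subtype, colour = .data$best
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$l_effective,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "#D55E00"),
      labels = c(`FALSE` = "other", `TRUE` = "best match"),
      name = NULL
    ) +
    ggplot2::facet_wrap(~ref_subtype) +
    ggplot2::labs(x = "list size k", y = "CAT overlap (%)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Heatmap of the row-scaled mean CAT matrix
#'
#' @param x A `homology_result`.
#' @param scaled Use the row min-max-scaled matrix (default) or raw means.
#' @return A ggplot object.
#' @export
plot_mean_cat <- function(x, scaled = TRUE) {
  tab <- tidy(x)
  fill <- if (scaled) "scaled" else "mean_cat"
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$cand_subtype, y = .data$ref_subtype,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (scaled) "row-scaled\nmean CAT"
                                  else "mean CAT") +
    ggplot2::labs(x = "candidate subtype", y = "reference subtype") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Spearman-correlation subtype correspondence (comparison utility)
#'
#' The rejected-alternative baseline: mean expression profile per subtype,
#' Spearman correlation across species. Provided for comparison with the
#' CAT assignment, not as the homology method.
#'
#' @param nm Combined quantile-normalized `normalized_matrix`.
#' @param meta_a,meta_b Per-species metadata.
#' @return Matrix of Spearman correlations (A subtypes x B subtypes).
#' @export
spearman_correspondence <- function(nm, meta_a, meta_b) {
  prof <- function(meta) {
    sts <- sort(unique(meta$subtype))
    vapply(sts, function(st) {
      ids <- meta$sample_id[meta$subtype == st]
      rowMeans(nm$values[, ids, drop = FALSE])
    }, numeric(nrow(nm$values)))
  }
  stats::cor(prof(meta_a), prof(meta_b), method = "spearman")
}
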