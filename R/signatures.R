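# Scoring external signature gene sets against the compendium.

#' Top-N signature sets after universe filtering
#'
#' Per cluster: genes outside the analysis universe are removed, genes
#' occurring more than once within the cluster are dropped entirely, the
#' remainder is sorted by decreasing ranking statistic (ties broken by gene
#' ID) and truncated to the top `n`.
#'
#' @param table Signature tibble (`gene_id`, `cluster`, `rank_stat`).
#' @param universe Character vector of genes present in the compendium.
#' @param n Set size (default 20).
#' @return Tibble: `cluster`, `gene_id`, `rank_stat`, `signature_rank`.
#'   Clusters with no surviving genes are absent, with a warning.
#' @export
top_n_signature <- function(table, universe, n = 20) {
  if (length(universe) == 0) abort("Universe must be non-empty.")
  if (any(!is.finite(table$rank_stat))) {
    abort("Signature rank_stat must be finite.")
  }
  out <- table |>
    group_by(.data$cluster) |>
    filter(!.data$gene_id %in% .data$gene_id[duplicated(.data$gene_id)]) |>
    ungroup() |>
    filter(.data$gene_id %in% universe) |>
    arrange(.data$cluster, desc(.data$rank_stat), .data$gene_id) |>
    group_by(.data$cluster) |>
    slice_head(n = n) |>
    mutate(signature_rank = row_number()) |>
    ungroup()
  lost <- setdiff(unique(table$cluster), unique(out$cluster))
  if (length(lost) > 0) {
    warn(paste0("Cluster(s) with no surviving genes: ",
                paste(lost, collapse = ", ")))
  }
  out
}

#' Earth mover's distance between two one-dimensional samples
#'
#' Wasserstein-1 distance between the empirical distributions, computed as
#' the integral of |F_in(x) - F_out(x)| over the merged support.
#'
#' @param x,y Numeric vectors.
#' @return Non-negative scalar.
#' @export
emd_1d <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  grid <- sort(unique(c(x, y)))
  if (length(grid) == 1) return(0)
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  widths <- diff(grid)
  sum(abs(fx - fy)[-length(grid)] * widths)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney U / (n_in * n_out) with in-group values as positives; ties
#' count one half. AUC > 0.5 means the in-group runs higher.
#'
#' @param x In-group values (positives).
#' @param y Out-group values.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' EMD x AUC signature gene score
#'
#' The per-gene cluster score: the product of the earth mover's distance
#' between the in-cluster and out-of-cluster expression distributions and
#' the rank AUC of the same comparison. Zero iff the distributions agree as
#' multisets or the gene carries no discrimination (AUC = 0).
#'
#' @param values_in Expression values of in-cluster samples.
#' @param values_out Expression values of out-of-cluster samples.
#' @return Tibble with `emd`, `auc`, `score`.
#' @export
emd_auc_score <- function(values_in, values_out) {
  e <- emd_1d(values_in, values_out)
  a <- auc_rank(values_in, values_out)
  tibble(emd = e, auc = a, score = e * a)
}

#' EMD x AUC scores for every gene against one cluster
#'
#' @param nm A `normalized_matrix`.
#' @param in_cluster Logical vector (or sample IDs) marking the in-cluster
#'   samples among `nm`'s columns.
#' @return Tibble: `gene_id`, `emd`, `auc`, `score`.
#' @export
emd_auc_scores <- function(nm, in_cluster) {
  if (is.character(in_cluster)) {
    in_cluster <- colnames(nm$values) %in% in_cluster
  }
  stopifnot(length(in_cluster) == ncol(nm$values))
  if (!any(in_cluster) || all(in_cluster)) {
    abort("Both groups must be non-empty.")
  }
  rows <- purrr::map(seq_len(nrow(nm$values)), function(gi) {
    emd_auc_score(nm$values[gi, in_cluster], nm$values[gi, !in_cluster])
  })
  bind_rows(rows) |>
    mutate(gene_id = rownames(nm$values), .before = 1)
}

#' Mean scaled expression of signature sets per subtype
#'
#' For heatmap-style comparison of external signatures against the
#' compendium: each signature gene's expression is min-max scaled to [0, 1]
#' across samples, then averaged per (cluster, subtype).
#'
#' @param signature_sets Output of [top_n_signature()].
#' @param nm A `normalized_matrix` (quantile-normalized values).
#' @param meta Sample metadata for `nm`'s samples.
#' @return Tibble: `cluster`, `subtype`, `mean_scaled_expression`,
#'   `n_genes`.
#' @export
signature_profile <- function(signature_sets, nm, meta) {
  meta <- align_sample_meta(meta, nm)
  genes <- intersect(unique(signature_sets$gene_id), rownames(nm$values))
  if (length(genes) == 0) abort("No signature gene is in the matrix.")
  vals <- nm$values[genes, , drop = FALSE]
  rng <- apply(vals, 1, range)
  span <- pmax(rng[2, ] - rng[1, ], .ORTHOCAT_EPS)
  scaled <- (vals - rng[1, ]) / span
  long <- as_tibble(scaled, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "scaled") |>
    left_join(select(meta, "sample_id", "subtype"), by = "sample_id") |>
    inner_join(select(signature_sets, "cluster", "gene_id"),
               by = "gene_id", relationship = "many-to-many")
  long |>
    group_by(.data$cluster, .data$subtype) |>
    summarise(
      mean_scaled_expression = mean(.data$scaled),
      n_genes = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    )
}
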