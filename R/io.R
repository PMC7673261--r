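#' Construct a validated count matrix
#'
#' The basic container for one species' gene x sample counts. Genes are rows,
#' samples are columns; both must carry unique names. Counts must be
#' non-negative integers (featureCounts-style unique-read quantification).
#'
#' @param counts Numeric matrix of non-negative integers with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param species Species label stored with the matrix.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, species = "unspecified") {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have both rownames (genes) and colnames (samples).")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate gene IDs: ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample IDs: ", paste(dup_s, collapse = ", ")))
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("Counts must be integers; non-integer entries found.")
  }
  storage.mode(counts) <- "double"
  structure(
    list(counts = counts, species = as.character(species)[1]),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %s: %d genes x %d samples\n",
    x$species, nrow(x$counts), ncol(x$counts)
  ))
  invisible(x)
}

#' Gene and sample identifiers of a container
#'
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) rownames(values_of(x))

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(values_of(x))

values_of <- function(x) {
  if (inherits(x, "count_matrix")) x$counts
  else if (inherits(x, "normalized_matrix")) x$values
  else if (is.matrix(x)) x
  else abort("Expected a count_matrix, normalized_matrix or matrix.")
}

#' Read a count matrix from disk
#'
#' Two on-disk dialects are supported: a dense TSV with a `gene_id` first
#' column and one column per sample, and a MatrixMarket triplet file with
#' `.rownames` / `.colnames` sidecar files (one ID per line).
#'
#' @param path File path (the `.mtx` file itself for `format = "mtx"`).
#' @param format `"tsv"` or `"mtx"`.
#' @param species Species label to attach.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        species = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Count file not found: ", path))
  }
  if (format == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE)
    if (!"gene_id" %in% names(tab)) {
      abort("Dense TSV counts must have a `gene_id` first column.")
    }
    m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
    rownames(m) <- tab$gene_id
  } else {
    m <- as.matrix(Matrix::readMM(path))
    base <- sub("\\.mtx$", "", path)
    rn <- readLines(paste0(base, ".rownames"))
    cn <- readLines(paste0(base, ".colnames"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
      abort("MatrixMarket dimensions do not match sidecar name files.")
    }
    rownames(m) <- rn
    colnames(m) <- cn
  }
  count_matrix(m, species = species)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; the TSV dialect round-trips byte-identically.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(cm, "count_matrix"))
  if (format == "tsv") {
    tab <- tibble(gene_id = rownames(cm$counts)) |>
      bind_cols(as_tibble(cm$counts))
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    base <- sub("\\.mtx$", "", path)
    writeLines(rownames(cm$counts), paste0(base, ".rownames"))
    writeLines(colnames(cm$counts), paste0(base, ".colnames"))
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `species`, `tissue`, `subtype`,
#'   `subject_id`.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("sample_id", "species", "tissue", "subtype", "subject_id")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Metadata missing columns: ", paste(missing, collapse = ", ")))
  }
  meta
}

#' @rdname read_sample_meta
#' @param meta Metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Check metadata against a count matrix
#'
#' Every sample in the matrix must have exactly one metadata row; a subject
#' may contribute samples to several subtypes.
#'
#' @param meta Metadata tibble (see [read_sample_meta()]).
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return The metadata rows for `x`'s samples, in column order.
#' @export
align_sample_meta <- function(meta, x) {
  ids <- sample_ids(x)
  if (anyDuplicated(meta$sample_id)) {
    abort("Metadata has duplicated sample_id rows.")
  }
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples without metadata: ", paste(missing, collapse = ", ")))
  }
  meta[match(ids, meta$sample_id), , drop = FALSE]
}

#' Read a 1:1 ortholog map
#'
#' Accepts a BioMart-style export: first two columns are the species-A and
#' species-B gene IDs; optional third/fourth columns carry per-gene chromosome
#' names. Rows are collapsed to the strict 1:1 subset by dropping every gene
#' participating in more than one pair, and pairs touching a sex chromosome
#' are removed whenever chromosome annotation is present (sorted-donor sex
#' would otherwise drive cross-species differences).
#'
#' @param path Two- or four-column TSV (with header).
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2) abort("Ortholog map needs at least two columns.")
  pairs <- tibble(gene_a = tab[[1]], gene_b = tab[[2]])
  if (ncol(tab) >= 4) {
    chrom_a <- tab[[3]]
    chrom_b <- tab[[4]]
    pairs <- filter_sex_chromosomes(pairs, chrom_a, chrom_b)
  }
  ortholog_map(pairs)
}

filter_sex_chromosomes <- function(pairs, chrom_a, chrom_b) {
  is_sex <- function(chr) {
    tolower(sub("^chr", "", chr)) %in% c("x", "y")
  }
  drop <- is_sex(chrom_a) | is_sex(chrom_b)
  if (any(drop)) {
    warn(sprintf("Dropping %d sex-chromosome ortholog pair(s).", sum(drop)))
  }
  pairs[!drop, , drop = FALSE]
}

#' Construct a validated 1:1 ortholog map
#'
#' Collapses many-to-many rows by dropping every gene that participates in
#' more than one pair, then checks bijectivity.
#'
#' @param pairs Tibble/data frame with columns `gene_a`, `gene_b`.
#' @return Tibble of the 1:1 pairs.
#' @export
ortholog_map <- function(pairs) {
  pairs <- tibble(gene_a = as.character(pairs$gene_a),
                  gene_b = as.character(pairs$gene_b))
  pairs <- distinct(pairs)
  multi_a <- pairs$gene_a[duplicated(pairs$gene_a)]
  multi_b <- pairs$gene_b[duplicated(pairs$gene_b)]
  bad <- pairs$gene_a %in% multi_a | pairs$gene_b %in% multi_b
  if (any(bad)) {
    warn(sprintf(
      "Dropping %d row(s) involved in non-1:1 ortholog relations.", sum(bad)
    ))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    abort("No ortholog pairs remain after 1:1/sex-chromosome filtering.")
  }
  stopifnot(
    !anyDuplicated(pairs$gene_a),
    !anyDuplicated(pairs$gene_b)
  )
  pairs
}

#' @rdname read_ortholog_map
#' @param map Ortholog map tibble.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Ortholog-pair identifiers
#'
#' The shared gene coordinate system across species: `"<gene_a>|<gene_b>"`.
#'
#' @param map Ortholog map tibble.
#' @return Character vector, one ID per pair.
#' @export
pair_ids <- function(map) paste(map$gene_a, map$gene_b, sep = "|")

#' Read or write a signature table
#'
#' A signature table lists externally published per-cluster gene rankings:
#' columns `gene_id`, `cluster`, `rank_stat` (e.g. an AUC, an average log
#' fold change, or an EMD x AUC score).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_signature_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    cluster = readr::col_character(),
    rank_stat = readr::col_double()
  ), progress = FALSE)
  need <- c("gene_id", "cluster", "rank_stat")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Signature table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(tab$rank_stat))) {
    abort("Signature rank_stat must be finite.")
  }
  tab
}

#' @rdname read_signature_table
#' @param tab Signature tibble.
#' @export
write_signature_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Generic TSV result-table round-trip helpers
#'
#' All result tables are written as UTF-8 TSV with `.` decimal separator and
#' the column order of the tibble; doubles use shortest round-trippable
#' formatting so write -> read is an identity.
#'
#' @param tab A tibble.
#' @param path Output path.
#' @export
write_result_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @param col_types A readr cols() spec; defaults to guessing.
#' @export
read_result_table <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}
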