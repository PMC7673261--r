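#' Configuration for a synthetic two-species cohort
#'
#' Defines the study design the generator emulates: two species sharing a
#' 1:1 ortholog set, each with sorted subtypes measured in a few replicate
#' samples, donors contributing several subtypes each, negative-binomial
#' counts with gene-specific baselines and library-size variation, and
#' per-subtype planted marker programs whose cross-species conservation is
#' controlled by `conservation_fraction`.
#'
#' Defaults mirror a two-species sorted-population compendium: 15 and 9
#' subtypes, 4 replicate samples per subtype, 6 donors per species, ~12000
#' ortholog genes, 50 markers per subtype elevated 2^4-fold, a donor
#' intercept SD of 0.3 on the log2 scale, NB dispersion 0.1 and library
#' sizes uniform in [5e5, 2e6].
#'
#' @param n_genes Number of ortholog gene pairs.
#' @param n_subtypes_a,n_subtypes_b Subtype counts per species.
#' @param homolog_pairs Tibble with columns `subtype_a`, `subtype_b` naming
#'   the true homolog pairs; default pairs subtype i of A with subtype i of B
#'   for `i <= min(n_subtypes_a, n_subtypes_b)`.
#' @param n_donors Donors per species; donors are crossed with subtypes
#'   (replicate r of every subtype comes from donor `1 + (r-1) mod
#'   n_donors`), as in sorts where one donor's tissue yields every
#'   population.
#' @param samples_per_subtype Replicate samples per subtype.
#' @param markers_per_subtype Planted marker genes per subtype (disjoint
#'   within a species).
#' @param conservation_fraction rho in [0,1]: fraction of each homolog pair's
#'   markers that are the same ortholog in both species; the rest are
#'   species-private. `round(rho * markers_per_subtype)` genes are conserved.
#' @param marker_log2_effect log2 fold elevation of a marker in its subtype.
#' @param donor_sd SD of the per-donor normal intercept on the log2 mean,
#'   shared across all genes of that donor's samples.
#' @param nb_dispersion NB dispersion alpha, with Var = mu + alpha * mu^2;
#'   0 gives Poisson counts.
#' @param library_size_range Length-2 integer range for uniform library sizes.
#' @param baseline_log2_sd SD of the per-species gene baseline on log2 scale.
#' @param species_labels Length-2 character vector of species names.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 12000,
                              n_subtypes_a = 15,
                              n_subtypes_b = 9,
                              homolog_pairs = NULL,
                              n_donors = 4,
                              samples_per_subtype = 4,
                              markers_per_subtype = 50,
                              conservation_fraction = 1,
                              marker_log2_effect = 4,
                              donor_sd = 0.3,
                              nb_dispersion = 0.1,
                              library_size_range = c(5e5, 2e6),
                              baseline_log2_sd = 1.5,
                              species_labels = c("speciesA", "speciesB"),
                              seed = 1L) {
  subtypes_a <- sprintf("A%02d", seq_len(n_subtypes_a))
  subtypes_b <- sprintf("B%02d", seq_len(n_subtypes_b))
  if (is.null(homolog_pairs)) {
    m <- min(n_subtypes_a, n_subtypes_b)
    homolog_pairs <- tibble(subtype_a = subtypes_a[seq_len(m)],
                            subtype_b = subtypes_b[seq_len(m)])
  }
  homolog_pairs <- as_tibble(homolog_pairs)
  stopifnot(
    all(homolog_pairs$subtype_a %in% subtypes_a),
    all(homolog_pairs$subtype_b %in% subtypes_b),
    !anyDuplicated(homolog_pairs$subtype_a),
    !anyDuplicated(homolog_pairs$subtype_b),
    conservation_fraction >= 0, conservation_fraction <= 1,
    marker_log2_effect >= 0, donor_sd >= 0, nb_dispersion >= 0,
    samples_per_subtype >= 1, n_donors >= 1,
    length(library_size_range) == 2,
    library_size_range[1] > 0,
    library_size_range[2] >= library_size_range[1]
  )
  if (markers_per_subtype * max(n_subtypes_a, n_subtypes_b) > n_genes) {
    abort("Infeasible marker allocation: markers_per_subtype x subtypes > n_genes.")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_subtypes_a = as.integer(n_subtypes_a),
    n_subtypes_b = as.integer(n_subtypes_b),
    subtypes_a = subtypes_a, subtypes_b = subtypes_b,
    homolog_pairs = homolog_pairs,
    n_donors = as.integer(n_donors),
    samples_per_subtype = as.integer(samples_per_subtype),
    markers_per_subtype = as.integer(markers_per_subtype),
    conservation_fraction = conservation_fraction,
    marker_log2_effect = marker_log2_effect,
    donor_sd = donor_sd,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    baseline_log2_sd = baseline_log2_sd,
    species_labels = species_labels,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

#' Simulate a paired two-species cohort with known homology
#'
#' Generates count matrices, sample metadata and the ortholog map for two
#' species, plus a ground-truth record of the planted markers and homolog
#' pairs. Genes are 1:1 orthologs by construction; baselines are drawn
#' independently per species so cross-species correspondence can only come
#' from the planted marker structure, not shared absolute levels.
#'
#' For each subtype, its marker genes gain `marker_log2_effect` on the log2
#' mean in that subtype only. For a homolog pair with conservation rho, a
#' fraction rho of markers use the same ortholog in both species. Counts are
#' NB(mean = libsize x baseline proportion x 2^(marker effect + donor
#' intercept), dispersion alpha); marker and donor effects multiply the mean
#' without per-sample renormalization.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mp_cohort` with elements `counts_a`, `meta_a`,
#'   `counts_b`, `meta_b`, `orthologs` and `truth` (list: `markers` tibble
#'   with species/subtype/gene/pair/conserved, `homolog_pairs`, `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_preserved_rng({
    set.seed(config$seed)
    genes_a <- sprintf("gA%05d", seq_len(config$n_genes))
    genes_b <- sprintf("gB%05d", seq_len(config$n_genes))
    orthologs <- tibble(gene_a = genes_a, gene_b = genes_b)

    alloc <- allocate_markers(config)

    sim_a <- simulate_species(
      config, genes_a, config$subtypes_a, alloc$markers_a,
      species = config$species_labels[1]
    )
    sim_b <- simulate_species(
      config, genes_b, config$subtypes_b, alloc$markers_b,
      species = config$species_labels[2]
    )

    pid <- pair_ids(orthologs)
    truth_markers <- bind_rows(
      mutate(alloc$markers_a,
             species = config$species_labels[1],
             gene_id = genes_a[.data$gene_index],
             pair_id = pid[.data$gene_index]),
      mutate(alloc$markers_b,
             species = config$species_labels[2],
             gene_id = genes_b[.data$gene_index],
             pair_id = pid[.data$gene_index])
    ) |>
      select("species", "subtype", "gene_id", "pair_id", "conserved")

    structure(list(
      counts_a = sim_a$counts, meta_a = sim_a$meta,
      counts_b = sim_b$counts, meta_b = sim_b$meta,
      orthologs = orthologs,
      truth = list(
        markers = truth_markers,
        homolog_pairs = config$homolog_pairs,
        config = config
      )
    ), class = "mp_cohort")
  })
}

# Draw disjoint marker gene sets per subtype in each species; conserved
# markers of a homolog pair use the same ortholog index in both species.
allocate_markers <- function(config) {
  mps <- config$markers_per_subtype
  n_cons <- round(config$conservation_fraction * mps)
  pool_a <- seq_len(config$n_genes)
  pool_b <- seq_len(config$n_genes)
  take <- function(pool, n) {
    if (length(pool) < n) abort("Infeasible marker allocation.")
    picked <- sample(pool, n)
    list(picked = picked, pool = setdiff(pool, picked))
  }
  rows_a <- list(); rows_b <- list()
  hp <- config$homolog_pairs
  for (i in seq_len(nrow(hp))) {
    shared_pool <- intersect(pool_a, pool_b)
    if (length(shared_pool) < n_cons) abort("Infeasible marker allocation.")
    cons <- sample(shared_pool, n_cons)
    pool_a <- setdiff(pool_a, cons)
    pool_b <- setdiff(pool_b, cons)
    pa <- take(pool_a, mps - n_cons); pool_a <- pa$pool
    pb <- take(pool_b, mps - n_cons); pool_b <- pb$pool
    rows_a[[length(rows_a) + 1]] <- tibble(
      subtype = hp$subtype_a[i],
      gene_index = c(cons, pa$picked),
      conserved = rep(c(TRUE, FALSE), c(n_cons, mps - n_cons))
    )
    rows_b[[length(rows_b) + 1]] <- tibble(
      subtype = hp$subtype_b[i],
      gene_index = c(cons, pb$picked),
      conserved = rep(c(TRUE, FALSE), c(n_cons, mps - n_cons))
    )
  }
  for (st in setdiff(config$subtypes_a, hp$subtype_a)) {
    pa <- take(pool_a, mps); pool_a <- pa$pool
    rows_a[[length(rows_a) + 1]] <- tibble(
      subtype = st, gene_index = pa$picked, conserved = FALSE
    )
  }
  for (st in setdiff(config$subtypes_b, hp$subtype_b)) {
    pb <- take(pool_b, mps); pool_b <- pb$pool
    rows_b[[length(rows_b) + 1]] <- tibble(
      subtype = st, gene_index = pb$picked, conserved = FALSE
    )
  }
  list(markers_a = bind_rows(rows_a), markers_b = bind_rows(rows_b))
}

simulate_species <- function(config, gene_names, subtypes, markers, species) {
  g <- config$n_genes
  k <- length(subtypes)
  spp <- config$samples_per_subtype
  n <- k * spp

  # species-private baselines -> expected proportions
  w <- 2^rnorm(g, 0, config$baseline_log2_sd)
  q <- w / sum(w)

  # design: donors are crossed with subtypes (replicate r of every subtype
  # comes from the same donor), mirroring sorts where each donor's tissue
  # yields all populations at once
  subtype <- rep(subtypes, each = spp)
  replicate_idx <- rep(seq_len(spp), times = k)
  donor_idx <- (replicate_idx - 1) %% config$n_donors + 1
  donor <- sprintf("%s_d%02d", species, donor_idx)
  sample_id <- sprintf("%s_%s_r%d", species, subtype, replicate_idx)

  donor_offsets <- rnorm(config$n_donors, 0, config$donor_sd)
  libsize <- round(runif(n, config$library_size_range[1],
                         config$library_size_range[2]))

  # log2 effect matrix genes x subtypes
  eff <- matrix(0, g, k, dimnames = list(gene_names, subtypes))
  eff[cbind(markers$gene_index, match(markers$subtype, subtypes))] <-
    config$marker_log2_effect

  mu <- q * 2^(eff[, match(subtype, subtypes), drop = FALSE] +
                 rep(donor_offsets[donor_idx], each = g))
  mu <- sweep(mu, 2, libsize, `*`)

  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(g * n, mu = mu, size = 1 / config$nb_dispersion), g, n)
  } else {
    matrix(rpois(g * n, lambda = mu), g, n)
  }
  dimnames(counts) <- list(gene_names, sample_id)

  meta <- tibble(
    sample_id = sample_id,
    species = species,
    tissue = "simulated",
    subtype = subtype,
    subject_id = donor
  )
  list(counts = count_matrix(counts, species = species), meta = meta)
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat(sprintf(
    "<mp_cohort> %s: %d genes x %d samples | %s: %d genes x %d samples | %d homolog pairs\n",
    x$counts_a$species, nrow(x$counts_a$counts), ncol(x$counts_a$counts),
    x$counts_b$species, nrow(x$counts_b$counts), ncol(x$counts_b$counts),
    nrow(x$truth$homolog_pairs)
  ))
  invisible(x)
}

#' Write all cohort artifacts to a directory
#'
#' Emits the six input artifacts in the package's on-disk formats plus
#' `truth.json` (planted markers, homolog pairs, config).
#'
#' @param cohort An `mp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$counts_a, file.path(dir, "counts_a.tsv"))
  write_counts(cohort$counts_b, file.path(dir, "counts_b.tsv"))
  write_sample_meta(cohort$meta_a, file.path(dir, "meta_a.tsv"))
  write_sample_meta(cohort$meta_b, file.path(dir, "meta_b.tsv"))
  write_ortholog_map(cohort$orthologs, file.path(dir, "orthologs.tsv"))
  cfg <- unclass(cohort$truth$config)
  cfg$homolog_pairs <- as.data.frame(cfg$homolog_pairs)
  jsonlite::write_json(
    list(
      markers = as.data.frame(cohort$truth$markers),
      homolog_pairs = as.data.frame(cohort$truth$homolog_pairs),
      config = cfg
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
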