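# End-to-end ortholog family inference over a panel: all-vs-all directed
# searches per genome pair, reciprocal best hits, two-stage clustering,
# and the augmented presence/absence matrix.

#' Infer ortholog families across a genome panel
#'
#' For every ordered pair of strains, runs the thresholded protein search
#' ([pairwise_search()]), derives reciprocal best hits per unordered pair,
#' pools the RBH edges (weighted by bit score) and clusters them with
#' single linkage followed by Markov clustering ([cluster_orthologs()]).
#'
#' @param genes Tibble of gene models with `gene_id`, `strain`, `protein`
#'   (e.g. `panel$genes`), or a `genome_panel`.
#' @param min_identity,min_query_cov,min_bitscore Search thresholds
#'   (defaults 40, 0.5, 50).
#' @param inflation,min_cluster_size Clustering parameters (defaults 3, 2).
#' @param exhaustive Use exhaustive rather than k-mer-seeded search.
#' @return An `ortholog_families` object.
#' @export
infer_ortholog_families <- function(genes,
                                    min_identity = 40, min_query_cov = 0.5,
                                    min_bitscore = 50,
                                    inflation = 3, min_cluster_size = 2,
                                    exhaustive = FALSE) {
  if (inherits(genes, "genome_panel")) genes <- genes$genes
  assert_that(all(c("gene_id", "strain", "protein") %in% names(genes)),
              "genes needs gene_id, strain, protein columns")
  strains <- sort(unique(genes$strain))
  assert_that(length(strains) >= 2, "need at least 2 strains")
  proteomes <- lapply(setNames(strains, strains), function(s) {
    g <- genes[genes$strain == s, ]
    as_proteome(setNames(g$protein, g$gene_id), s)
  })
  seed_k <- 6L
  kmer_tables <- if (exhaustive) {
    NULL
  } else {
    lapply(proteomes, protein_kmer_table, k = seed_k)
  }
  edges <- list()
  for (i in seq_along(strains)) {
    for (j in seq_len(i - 1L)) {
      hits <- search_pair_bidirectional(
        proteomes[[strains[i]]], proteomes[[strains[j]]],
        min_identity = min_identity, min_query_cov = min_query_cov,
        min_bitscore = min_bitscore, exhaustive = exhaustive,
        seed_k = seed_k,
        kt_a = kmer_tables[[strains[i]]], kt_b = kmer_tables[[strains[j]]]
      )
      edges[[length(edges) + 1L]] <- reciprocal_best_hits(hits$ab, hits$ba)
    }
  }
  rbb <- dplyr::bind_rows(edges)
  cluster_orthologs(rbb, genes = genes, inflation = inflation,
                    min_cluster_size = min_cluster_size)
}

#' Run the full pan-genome pipeline on a panel
#'
#' Convenience wrapper: family inference, presence/absence matrix, core
#' genome, and rarefaction with a Heaps-law openness fit.
#'
#' @param panel A `genome_panel` (or gene tibble).
#' @param n_permutations Rarefaction permutations (default 100).
#' @param seed Seed for the rarefaction permutations.
#' @param ... Passed to [infer_ortholog_families()].
#' @return List: `families`, `matrix` (pa_matrix), `core` (column ids),
#'   `rarefaction`, `heaps`.
#' @export
pan_genome_pipeline <- function(panel, n_permutations = 100, seed = 1L, ...) {
  genes <- if (inherits(panel, "genome_panel")) panel$genes else panel
  fams <- infer_ortholog_families(genes, ...)
  meta <- if ("replicon_class" %in% names(genes)) {
    genes[, c("gene_id", "replicon_class")]
  } else {
    NULL
  }
  pa <- build_presence_absence(fams, strains = sort(unique(genes$strain)),
                               gene_meta = meta)
  core <- core_genome(pa)
  rar <- rarefaction(pa, n_permutations = n_permutations, seed = seed)
  heaps <- fit_heaps(rar)
  list(families = fams, matrix = pa, core = core, rarefaction = rar,
       heaps = heaps)
}

#' Adjusted Rand index between two gene partitions
#'
#' Compares an inferred family partition with a reference partition (e.g.
#' the simulated truth); 1.0 means identical partitions. Genes missing
#' from either partition are an error.
#'
#' @param partition_a,partition_b Tibbles with `gene_id` and a partition
#'   label column (`family_id`), or named vectors mapping gene to label.
#' @return The adjusted Rand index (numeric scalar).
#' @export
partition_ari <- function(partition_a, partition_b) {
  as_labels <- function(x) {
    if (is.data.frame(x)) {
      lab <- intersect(c("family_id", "label"), names(x))[1]
      setNames(x[[lab]], x$gene_id)
    } else {
      x
    }
  }
  a <- as_labels(partition_a)
  b <- as_labels(partition_b)
  common <- intersect(names(a), names(b))
  assert_that(length(common) == length(a) && length(common) == length(b),
              "partitions cover different gene sets")
  a <- a[common]
  b <- b[common]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(length(common))
  expected <- sum_i * sum_j / n
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Family partition of an `ortholog_families` object
#'
#' Returns the gene-to-label map induced by a family set: clustered genes
#' take their family id, singletons their own gene id.
#'
#' @param families An `ortholog_families` object.
#' @return Named character vector (gene_id -> partition label).
#' @export
family_partition <- function(families) {
  stopifnot(inherits(families, "ortholog_families"))
  c(setNames(families$families$family_id, families$families$gene_id),
    setNames(families$singletons$gene_id, families$singletons$gene_id))
}
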