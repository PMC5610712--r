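# Whole-genome pairwise metrics: fragment-based ANI and POCP, species
# classification, and complete-linkage clustering of metric matrices.

#' ANI parameters
#'
#' Parameters of the fragment-based ANI protocol: the query genome is cut
#' into consecutive fragments of `fragment_length`, each fragment is
#' aligned to the other genome, and fragments are retained when they align
#' at `min_fragment_identity` percent identity or better over at least
#' `min_fragment_coverage` of their length. The directed ANI is the mean
#' identity of retained fragments; the reported ANI averages the two
#' directions.
#'
#' @param fragment_length Fragment size in nt (default 1020).
#' @param min_fragment_identity Retention identity threshold, percent
#'   (default 30).
#' @param min_fragment_coverage Retention coverage threshold, fraction of
#'   the fragment length (default 0.7).
#' @param min_retained_fragments Below this count in either direction the
#'   result is flagged unreliable (default 10).
#' @param min_tail_fragment Final partial fragment at a replicon end is
#'   kept if at least this long, else dropped (default 100).
#' @export
ani_params <- function(fragment_length = 1020L,
                       min_fragment_identity = 30,
                       min_fragment_coverage = 0.7,
                       min_retained_fragments = 10L,
                       min_tail_fragment = 100L) {
  assert_that(fragment_length >= 100, "fragment_length must be >= 100")
  assert_that(min_fragment_identity >= 0 && min_fragment_identity <= 100,
              "min_fragment_identity must be a percent")
  assert_that(min_fragment_coverage > 0 && min_fragment_coverage <= 1,
              "min_fragment_coverage must be a fraction")
  list(fragment_length = as.integer(fragment_length),
       min_fragment_identity = min_fragment_identity,
       min_fragment_coverage = min_fragment_coverage,
       min_retained_fragments = as.integer(min_retained_fragments),
       min_tail_fragment = as.integer(min_tail_fragment))
}

as_genome <- function(x, arg = "genome") {
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (is.data.frame(x)) {
    assert_that(all(c("replicon_id", "sequence") %in% names(x)),
                sprintf("%s data frame needs replicon_id and sequence", arg))
    x <- setNames(x$sequence, x$replicon_id)
  }
  assert_that(is.character(x) && length(x) > 0 && all(nzchar(x)),
              sprintf("%s must be one or more non-empty sequences", arg))
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  x
}

cut_fragments <- function(genome, params) {
  frags <- purrr::imap(genome, function(seq, id) {
    n <- nchar(seq)
    starts <- seq(1L, n, by = params$fragment_length)
    ends <- pmin(starts + params$fragment_length - 1L, n)
    keep <- (ends - starts + 1L) >= pmin(params$fragment_length,
                                         params$min_tail_fragment)
    tibble::tibble(
      fragment_id = sprintf("%s_frag%05d", id, seq_along(starts)[keep]),
      sequence = substring(seq, starts[keep], ends[keep])
    )
  })
  dplyr::bind_rows(frags)
}

# Run blastn of query sequences against subject sequences, returning the
# standard 12-column tabular hit format as a tibble. Scoring mirrors the
# classic fragment-ANI setup: reward 1 / penalty -1, gap x-dropoff 150,
# no dusting.
blastn_table <- function(queries, subjects, evalue = 1e-15, task = "blastn",
                         extra_args = character()) {
  makeblastdb <- find_tool("makeblastdb")
  blastn <- find_tool("blastn")
  dir <- tempfile("blastn")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fna")
  sf <- file.path(dir, "subject.fna")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(queries), qf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(subjects), sf)
  out <- system2(makeblastdb, c("-in", sf, "-dbtype", "nucl"),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  assert_that(status == 0L,
              paste("makeblastdb failed:", paste(out, collapse = "\n")))
  hits_file <- file.path(dir, "hits.tsv")
  args <- c("-task", task, "-query", qf, "-db", sf,
            "-reward", "1", "-penalty", "-1", "-xdrop_gap", "150",
            "-dust", "no", "-evalue", format(evalue),
            "-outfmt", "6", "-out", hits_file, extra_args)
  out <- system2(blastn, args, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  assert_that(status == 0L,
              paste("blastn failed:", paste(out, collapse = "\n")))
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  if (file.size(hits_file) == 0) {
    return(tibble::as_tibble(setNames(
      as.list(c(rep(list(character()), 2), rep(list(numeric()), 10))), cols)))
  }
  readr::read_tsv(hits_file, col_names = cols, show_col_types = FALSE)
}

ani_directed <- function(genome_q, genome_s, params) {
  frags <- cut_fragments(genome_q, params)
  n_frag <- nrow(frags)
  hits <- blastn_table(setNames(frags$sequence, frags$fragment_id), genome_s)
  if (nrow(hits) == 0) {
    return(list(ani = NA_real_, n_fragments = n_frag, n_retained = 0L))
  }
  frag_len <- setNames(nchar(frags$sequence), frags$fragment_id)
  best <- hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score)) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::mutate(coverage = .data$alignment_length /
                    frag_len[.data$query_id]) |>
    dplyr::filter(.data$percent_identity >= params$min_fragment_identity,
                  .data$coverage >= params$min_fragment_coverage)
  list(ani = if (nrow(best) > 0) mean(best$percent_identity) else NA_real_,
       n_fragments = n_frag, n_retained = nrow(best))
}

#' Average nucleotide identity between two genomes
#'
#' Fragment-based ANI: see [ani_params()] for the protocol. When fewer
#' than `min_retained_fragments` fragments survive retention in either
#' direction the value is still reported but flagged unreliable.
#'
#' @param genome_a,genome_b Genomes as named character vectors of replicon
#'   sequences, `DNAStringSet`s, or data frames with `replicon_id` and
#'   `sequence` columns.
#' @param params An [ani_params()] list.
#' @return One-row tibble: `ani`, `ani_ab`, `ani_ba`, fragment counts per
#'   direction, and a `reliable` flag.
#' @export
ani_pair <- function(genome_a, genome_b, params = ani_params()) {
  a <- as_genome(genome_a, "genome_a")
  b <- as_genome(genome_b, "genome_b")
  ab <- ani_directed(a, b, params)
  ba <- ani_directed(b, a, params)
  vals <- c(ab$ani, ba$ani)
  tibble::tibble(
    ani = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
    ani_ab = ab$ani, ani_ba = ba$ani,
    fragments_ab = ab$n_fragments, retained_ab = ab$n_retained,
    fragments_ba = ba$n_fragments, retained_ba = ba$n_retained,
    reliable = ab$n_retained >= params$min_retained_fragments &&
      ba$n_retained >= params$min_retained_fragments
  )
}

#' Percentage of conserved proteins between two proteomes
#'
#' `POCP = (C1 + C2) / (T1 + T2) * 100`, where `Ti` is the protein count
#' of genome i and `Ci` the number of its proteins with at least one hit
#' in the other proteome passing all thresholds (e-value, identity, and
#' alignable region over half the query length). The formula is symmetric
#' in the two genomes.
#'
#' @param proteome_a,proteome_b Proteomes (see [pairwise_search()] input
#'   formats).
#' @param max_evalue Maximum e-value (default 1e-5).
#' @param min_identity Minimum percent identity (default 40).
#' @param min_query_cov Minimum aligned fraction of the query protein's
#'   full length (default 0.5).
#' @param exhaustive Passed on to [pairwise_search()].
#' @return One-row tibble: `pocp`, `c1`, `c2`, `t1`, `t2`.
#' @export
pocp_pair <- function(proteome_a, proteome_b, max_evalue = 1e-5,
                      min_identity = 40, min_query_cov = 0.5,
                      exhaustive = FALSE) {
  a <- as_proteome(proteome_a, "proteome_a")
  b <- as_proteome(proteome_b, "proteome_b")
  conserved <- function(q, s) {
    hits <- pairwise_search(q, s, min_identity = min_identity,
                            min_query_cov = min_query_cov, min_bitscore = 0,
                            exhaustive = exhaustive)
    hits <- hits[hits$e_value <= max_evalue, ]
    length(unique(hits$query_id))
  }
  c1 <- conserved(a, b)
  c2 <- conserved(b, a)
  tibble::tibble(pocp = pocp_value(c1, c2, length(a), length(b)),
                 c1 = c1, c2 = c2, t1 = length(a), t2 = length(b))
}

#' @rdname pocp_pair
#' @param c1,c2,t1,t2 Conserved and total protein counts of the two
#'   genomes.
#' @export
pocp_value <- function(c1, c2, t1, t2) {
  assert_that(t1 > 0 && t2 > 0, "empty proteome")
  (c1 + c2) / (t1 + t2) * 100
}

#' Classify a genome pair as conspecific from its ANI value
#'
#' @param ani_value ANI percent in `[0, 100]`.
#' @param cutoff Species boundary (default 95); the boundary itself counts
#'   as same-species.
#' @return Logical: same species?
#' @export
classify_species <- function(ani_value, cutoff = 95) {
  assert_that(all(ani_value >= 0 & ani_value <= 100),
              "ani_value must lie in [0, 100]")
  ani_value >= cutoff
}

#' Pairwise metric matrix over a panel
#'
#' Computes the symmetric strain-by-strain ANI or POCP matrix of a panel
#' (diagonal fixed at 100).
#'
#' @param panel A `genome_panel`.
#' @param metric `"ani"` or `"pocp"`.
#' @param params [ani_params()] for the ANI protocol.
#' @param ... Further arguments to [pocp_pair()].
#' @return A numeric matrix with a `metric` attribute.
#' @export
metric_matrix <- function(panel, metric = c("ani", "pocp"),
                          params = ani_params(), ...) {
  stopifnot(inherits(panel, "genome_panel"))
  metric <- match.arg(metric)
  strains <- unique(panel$replicons$strain)
  m <- matrix(100, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (i in seq_along(strains)) {
    for (j in seq_len(i - 1L)) {
      v <- if (metric == "ani") {
        ani_pair(panel$replicons[panel$replicons$strain == strains[i], ],
                 panel$replicons[panel$replicons$strain == strains[j], ],
                 params)$ani
      } else {
        gi <- panel$genes[panel$genes$strain == strains[i], ]
        gj <- panel$genes[panel$genes$strain == strains[j], ]
        pocp_pair(gi, gj, ...)$pocp
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "metric") <- metric
  m
}

#' Complete-linkage clustering of a pairwise metric matrix
#'
#' Rows of the (symmetric) similarity matrix are treated as feature
#' vectors; strains are agglomerated by complete linkage on Euclidean
#' row distances, as used for ANI heatmap ordering. Deterministic for a
#' fixed matrix.
#'
#' @param matrix Symmetric numeric matrix with identical row/column names.
#' @return A `metric_clustering`: the `hclust` object, the leaf order, and
#'   the dendrogram as an `ape::phylo` tree (writable as Newick).
#' @export
cluster_metric_matrix <- function(matrix) {
  assert_that(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
              "matrix must be square")
  assert_that(nrow(matrix) >= 2, "need at least 2 strains")
  assert_that(isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-6,
                               check.attributes = FALSE)),
              "matrix must be symmetric")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "complete")
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 phylo = ape::as.phylo(hc)),
            class = "metric_clustering")
}

#' @export
print.metric_clustering <- function(x, ...) {
  cat(sprintf("<metric_clustering> %d strains, complete linkage; leaf order: %s\n",
              length(x$leaf_order),
              paste(head(x$leaf_order, 5), collapse = ", ")))
  invisible(x)
}
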