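# Internal protein similarity search engine.
#
# Local alignment (Smith-Waterman via Biostrings) under BLOSUM62 with
# affine gaps (open 11, extend 1); raw scores are converted to bit scores
# and e-values with the standard Karlin-Altschul constants for that
# scoring system (lambda = 0.267, K = 0.041). Candidate pairs are
# pre-selected by shared amino-acid k-mers (a word seed, as in seeded
# search tools); `exhaustive = TRUE` aligns every pair.

ka_lambda <- 0.267
ka_k      <- 0.041

aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYBZX"

bit_score_from_raw <- function(raw) (ka_lambda * raw - log(ka_k)) / log(2)

evalue_from_raw <- function(raw, m, n) ka_k * m * n * exp(-ka_lambda * raw)

# Normalise a proteome to a named character vector of AA sequences.
as_proteome <- function(x, arg = "proteome") {
  if (inherits(x, "AAStringSet")) {
    x <- setNames(as.character(x), names(x))
  } else if (is.data.frame(x)) {
    id_col <- intersect(c("gene_id", "id"), names(x))[1]
    assert_that(!is.na(id_col) && "protein" %in% names(x),
                sprintf("%s must have an id/gene_id and a protein column", arg))
    x <- setNames(x$protein, x[[id_col]])
  }
  assert_that(is.character(x) && length(x) > 0,
              sprintf("%s must be a non-empty set of protein sequences", arg))
  assert_that(!is.null(names(x)) && all(nzchar(names(x))),
              sprintf("%s sequences must be named", arg))
  assert_that(!anyDuplicated(names(x)), sprintf("duplicate ids in %s", arg))
  bad <- grepl(sprintf("[^%s]", aa_alphabet), x)
  if (any(bad)) {
    abort(sprintf("illegal residue in protein '%s'", names(x)[bad][1]))
  }
  x
}

protein_kmer_table <- function(seqs, k) {
  n <- nchar(seqs)
  kept <- n >= k
  out <- purrr::map2(names(seqs)[kept], seqs[kept], function(id, s) {
    tibble::tibble(id = id,
                   kmer = unique(substring(s, 1:(nchar(s) - k + 1),
                                           k:nchar(s))))
  })
  dplyr::bind_rows(out)
}

# Candidate (query, subject) id pairs sharing at least one k-mer; short
# sequences (< k) are paired against everything. Precomputed k-mer tables
# (from protein_kmer_table) can be passed to amortise indexing across many
# searches over the same proteomes.
seed_candidates <- function(queries, subjects, k,
                            qt = NULL, st = NULL) {
  qt <- qt %||% protein_kmer_table(queries, k)
  st <- st %||% protein_kmer_table(subjects, k)
  cand <- dplyr::inner_join(qt, st, by = "kmer", suffix = c("_q", "_s"),
                            relationship = "many-to-many") |>
    dplyr::distinct(query_id = .data$id_q, subject_id = .data$id_s)
  shortq <- names(queries)[nchar(queries) < k]
  shorts <- names(subjects)[nchar(subjects) < k]
  if (length(shortq) > 0 || length(shorts) > 0) {
    extra <- dplyr::bind_rows(
      tidyr::expand_grid(query_id = shortq, subject_id = names(subjects)),
      tidyr::expand_grid(query_id = names(queries), subject_id = shorts)
    )
    cand <- dplyr::distinct(dplyr::bind_rows(cand, extra))
  }
  cand
}

#' All-vs-all protein similarity search
#'
#' Searches every query protein against a subject proteome by local
#' alignment (BLOSUM62, gap open 11 / extend 1) and reports, per
#' (query, subject) pair, the best local hit passing all thresholds.
#' E-values use the subject proteome's total residue count as the database
#' size; only identity, query coverage and bit score gate the hits.
#'
#' @param queries,subjects Proteomes: named character vectors,
#'   `AAStringSet`s, or data frames with `gene_id`/`id` and `protein`
#'   columns.
#' @param min_identity Minimum percent identity over the aligned region
#'   (default 40).
#' @param min_query_cov Minimum aligned fraction of the query length
#'   (default 0.5).
#' @param min_bitscore Minimum bit score (default 50).
#' @param exhaustive Align every pair instead of only k-mer-seeded
#'   candidate pairs. The seeded search can miss borderline-threshold hits
#'   between highly diverged sequences; exhaustive mode cannot.
#' @param seed_k K-mer length of the word seed (default 6).
#'
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `query_coverage`,
#'   `bit_score`, `e_value`, sorted by query then descending bit score.
#' @export
pairwise_search <- function(queries, subjects,
                            min_identity = 40, min_query_cov = 0.5,
                            min_bitscore = 50,
                            exhaustive = FALSE, seed_k = 6L) {
  queries <- as_proteome(queries, "queries")
  subjects <- as_proteome(subjects, "subjects")

  cand <- if (exhaustive) {
    tidyr::expand_grid(query_id = names(queries), subject_id = names(subjects))
  } else {
    seed_candidates(queries, subjects, seed_k)
  }
  hits <- align_candidates(cand, queries, subjects,
                           db_residues = sum(nchar(subjects)))
  hits |>
    dplyr::filter(.data$percent_identity >= min_identity,
                  .data$query_coverage >= min_query_cov,
                  .data$bit_score >= min_bitscore) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                   .data$subject_id)
}

# Align given candidate id pairs and compute hit statistics (no filtering).
align_candidates <- function(cand, queries, subjects, db_residues) {
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          percent_identity = numeric(),
                          alignment_length = integer(),
                          query_coverage = numeric(),
                          bit_score = numeric(), e_value = numeric())
  if (nrow(cand) == 0) return(empty)
  p <- Biostrings::AAStringSet(queries[cand$query_id])
  s <- Biostrings::AAStringSet(subjects[cand$subject_id])
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  raw <- Biostrings::score(aln)
  alen <- Biostrings::nchar(aln)
  ok <- raw > 0 & alen > 0
  if (!any(ok)) return(empty)
  pat <- Biostrings::pattern(aln)
  qspan <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
  qlen <- unname(nchar(queries[cand$query_id]))
  tibble::tibble(
    query_id = cand$query_id,
    subject_id = cand$subject_id,
    percent_identity = Biostrings::pid(aln, type = "PID1"),
    alignment_length = alen,
    query_coverage = qspan / qlen,
    bit_score = bit_score_from_raw(raw),
    e_value = evalue_from_raw(raw, qlen, db_residues)
  )[ok, ]
}

# Search both directions of one genome pair from a single set of
# alignments (local alignment is symmetric in the two sequences; only the
# query-relative statistics differ). Used by the panel-scale pipeline,
# where precomputed k-mer tables amortise the seeding.
search_pair_bidirectional <- function(a, b, min_identity = 40,
                                      min_query_cov = 0.5, min_bitscore = 50,
                                      exhaustive = FALSE, seed_k = 6L,
                                      kt_a = NULL, kt_b = NULL) {
  cand <- if (exhaustive) {
    tidyr::expand_grid(query_id = names(a), subject_id = names(b))
  } else {
    seed_candidates(a, b, seed_k, qt = kt_a, st = kt_b)
  }
  empty <- align_candidates(cand[0, ], a, b, 1)
  if (nrow(cand) == 0) return(list(ab = empty, ba = empty))
  p <- Biostrings::AAStringSet(a[cand$query_id])
  s <- Biostrings::AAStringSet(b[cand$subject_id])
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  raw <- Biostrings::score(aln)
  alen <- Biostrings::nchar(aln)
  ok <- raw > 0 & alen > 0
  pat <- Biostrings::pattern(aln)
  subj <- Biostrings::subject(aln)
  aspan <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
  bspan <- BiocGenerics::end(subj) - BiocGenerics::start(subj) + 1L
  alens <- unname(nchar(a[cand$query_id]))
  blens <- unname(nchar(b[cand$subject_id]))
  ident <- Biostrings::pid(aln, type = "PID1")
  bits <- bit_score_from_raw(raw)
  direction <- function(qid, sid, qspan, qlen, db) {
    tibble::tibble(
      query_id = qid, subject_id = sid,
      percent_identity = ident, alignment_length = alen,
      query_coverage = qspan / qlen,
      bit_score = bits,
      e_value = evalue_from_raw(raw, qlen, db)
    )[ok, ] |>
      dplyr::filter(.data$percent_identity >= min_identity,
                    .data$query_coverage >= min_query_cov,
                    .data$bit_score >= min_bitscore) |>
      dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                     .data$subject_id)
  }
  list(ab = direction(cand$query_id, cand$subject_id, aspan, alens,
                      sum(nchar(b))),
       ba = direction(cand$subject_id, cand$query_id, bspan, blens,
                      sum(nchar(a))))
}
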