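# Gene-call reconciliation across predictors, thresholded best-hit
# annotation transfer, and the LPXTG sorting-signal scan.

#' Reconcile gene calls from multiple predictors
#'
#' Prokaryotic gene callers typically agree on a gene's stop codon and
#' disagree on its start. Calls sharing strand and stop-side coordinate
#' (the 3' end) are merged into one gene taking the longest extent; calls
#' unique to a single predictor are retained, minimising false-negative
#' predictions.
#'
#' @param callsets A single tibble of calls with columns `predictor_id`,
#'   `replicon_id`, `start`, `end`, `strand`, or a list of per-predictor
#'   tibbles (each with those columns, `predictor_id` optional per table).
#' @param replicon_lengths Optional named vector of replicon lengths used
#'   to validate coordinates; a call exceeding its replicon's bounds is an
#'   error naming the call.
#' @return Tibble of merged gene models (`replicon_id`, `start`, `end`,
#'   `strand`, `n_predictors`, `predictors`) sorted by replicon then start.
#' @export
reconcile_gene_calls <- function(callsets, replicon_lengths = NULL) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  assert_that(length(callsets) >= 1, "need at least one callset")
  calls <- dplyr::bind_rows(purrr::imap(callsets, function(cs, nm) {
    cs <- tibble::as_tibble(cs)
    if (!"predictor_id" %in% names(cs)) {
      cs$predictor_id <- if (is.character(nm)) nm else sprintf("predictor%d", nm)
    }
    cs
  }))
  assert_that(all(c("replicon_id", "start", "end", "strand") %in% names(calls)),
              "calls need replicon_id, start, end, strand")
  assert_that(all(calls$start >= 1 & calls$start <= calls$end),
              "call coordinates must satisfy 1 <= start <= end")
  assert_that(all(calls$strand %in% c("+", "-")), "strand must be + or -")
  if (!is.null(replicon_lengths)) {
    over <- calls$end > replicon_lengths[calls$replicon_id]
    if (any(over, na.rm = TRUE)) {
      bad <- calls[which(over)[1], ]
      abort(sprintf("call %s:%d-%d(%s) from %s exceeds replicon bounds",
                    bad$replicon_id, bad$start, bad$end, bad$strand,
                    bad$predictor_id))
    }
  }
  calls |>
    dplyr::mutate(stop_coord = ifelse(.data$strand == "+", .data$end,
                                      .data$start)) |>
    dplyr::group_by(.data$replicon_id, .data$strand, .data$stop_coord) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_predictors = dplyr::n_distinct(.data$predictor_id),
                     predictors = paste(sort(unique(.data$predictor_id)),
                                        collapse = ","),
                     .groups = "drop") |>
    dplyr::select("replicon_id", "start", "end", "strand", "n_predictors",
                  "predictors") |>
    dplyr::arrange(.data$replicon_id, .data$start, .data$end)
}

#' Transfer functional labels by thresholded best hit
#'
#' Searches each gene's protein against a labelled reference set and
#' assigns the label of its best-scoring hit passing all three thresholds
#' (or no label). Best = highest bit score; ties broken by higher identity
#' then lexicographic reference id.
#'
#' @param genes Tibble with `gene_id` and `protein` columns (extra columns
#'   are ignored), or any [pairwise_search()] query format.
#' @param reference Labelled reference proteins: tibble with `id`,
#'   `protein`, `label` columns, or a named character vector of sequences
#'   plus a `labels` vector named by reference id.
#' @param labels Optional named character vector of labels when
#'   `reference` is a plain sequence set.
#' @param min_identity,min_query_cov,min_bitscore Annotation-transfer
#'   thresholds (defaults 40 percent identity, 0.5 query coverage, bit
#'   score 60).
#' @param exhaustive Passed on to [pairwise_search()].
#' @return Tibble with one row per labelled gene: `gene_id`, `label`,
#'   `reference_id`, `percent_identity`, `bit_score`.
#' @export
transfer_annotation <- function(genes, reference, labels = NULL,
                                min_identity = 40, min_query_cov = 0.5,
                                min_bitscore = 60, exhaustive = FALSE) {
  if (is.data.frame(reference)) {
    assert_that(all(c("protein", "label") %in% names(reference)),
                "reference needs protein and label columns")
    id_col <- intersect(c("id", "gene_id"), names(reference))[1]
    assert_that(!is.na(id_col), "reference needs an id column")
    labels <- setNames(reference$label, reference[[id_col]])
    reference <- setNames(reference$protein, reference[[id_col]])
  }
  assert_that(length(reference) > 0, "empty reference set")
  assert_that(!is.null(labels), "reference proteins must carry labels")
  hits <- pairwise_search(genes, reference, min_identity = min_identity,
                          min_query_cov = min_query_cov,
                          min_bitscore = min_bitscore,
                          exhaustive = exhaustive)
  best_hit_per_query(hits) |>
    dplyr::transmute(gene_id = .data$query_id,
                     label = unname(labels[.data$subject_id]),
                     reference_id = .data$subject_id,
                     percent_identity = .data$percent_identity,
                     bit_score = .data$bit_score)
}

#' Scan a protein for a C-terminal LPXTG sorting signal
#'
#' Reports a hit iff the pattern `L-P-x-T-G` begins within the C-terminal
#' `window` residues, where sortase substrates carry their cell-wall
#' sorting signal.
#'
#' @param protein Amino-acid sequence(s), character vector.
#' @param window C-terminal window in residues (default 50).
#' @return Tibble with one row per input: `protein_length`, `hit`,
#'   `position` (start of the motif, NA when absent).
#' @export
scan_lpxtg <- function(protein, window = 50) {
  assert_that(is.character(protein) && all(nzchar(protein)),
              "protein must be non-empty")
  ids <- names(protein) %||% as.character(seq_along(protein))
  res <- purrr::map2(protein, nchar(protein), function(p, n) {
    hits <- gregexpr("LP.TG", p)[[1]]
    hits <- hits[hits > 0]
    in_window <- hits[hits >= n - window + 1L]
    tibble::tibble(protein_length = n,
                   hit = length(in_window) > 0,
                   position = if (length(in_window) > 0) {
                     as.integer(in_window[length(in_window)])
                   } else NA_integer_)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(id = ids, .before = 1)
}
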