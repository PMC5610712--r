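# Replicon assignment of contigs via marker genes and reference homology,
# reference-cluster (e.g. EPS) presence calls, and per-replicon functional
# count matrices.

#' Assign contigs to replicon classes
#'
#' Marker-first rule: a contig carrying at least one repA-type marker gene
#' (e.g. repA, repE, parA) aligned at `min_marker_identity` percent
#' identity or better over (nearly) the marker's full length is assigned
#' to the repA-type megaplasmid class. Remaining contigs take the class of
#' the reference replicon set with the greatest summed homology coverage;
#' contigs whose best class covers less than `min_coverage_floor` of their
#' length stay `unassigned`. This reconstructs a marker+homology
#' assignment protocol with every threshold configurable.
#'
#' @param contigs Named character vector (or `DNAStringSet` / replicons
#'   tibble) of contig sequences.
#' @param markers Named character vector of marker nucleotide sequences
#'   (names e.g. `repA`, `repE`, `parA`).
#' @param references Named list mapping replicon class to a named
#'   character vector of reference replicon sequences of that class.
#' @param min_marker_identity Marker identity threshold, percent
#'   (default 93).
#' @param min_marker_coverage Fraction of the marker length that must
#'   align (default 0.9, "full length").
#' @param min_coverage_floor Minimum homology coverage fraction of the
#'   contig for a class call (default 0.2).
#' @return Tibble: `contig`, `class`, `evidence`, `marker_hits`,
#'   `best_coverage`.
#' @export
assign_replicons <- function(contigs, markers = NULL, references = list(),
                             min_marker_identity = 93,
                             min_marker_coverage = 0.9,
                             min_coverage_floor = 0.2) {
  contigs <- as_genome(contigs, "contigs")
  assert_that(all(nzchar(contigs)), "empty contig sequence")
  assert_that(length(references) > 0 || !is.null(markers),
              "need markers and/or at least one reference class")

  marker_hits <- setNames(rep("", length(contigs)), names(contigs))
  marker_call <- setNames(rep(FALSE, length(contigs)), names(contigs))
  if (!is.null(markers) && length(markers) > 0) {
    hits <- blastn_table(markers, contigs, evalue = 1e-5)
    if (nrow(hits) > 0) {
      mlen <- setNames(nchar(markers), names(markers))
      qual <- hits |>
        dplyr::filter(.data$percent_identity >= min_marker_identity,
                      .data$alignment_length >=
                        min_marker_coverage * mlen[.data$query_id])
      if (nrow(qual) > 0) {
        per_contig <- qual |>
          dplyr::group_by(.data$subject_id) |>
          dplyr::summarise(markers = paste(sort(unique(.data$query_id)),
                                           collapse = ","),
                           .groups = "drop")
        marker_hits[per_contig$subject_id] <- per_contig$markers
        marker_call[per_contig$subject_id] <- TRUE
      }
    }
  }

  # homology coverage of each contig by each reference class
  cov <- matrix(0, nrow = length(contigs), ncol = length(references),
                dimnames = list(names(contigs), names(references)))
  for (cl in names(references)) {
    hits <- blastn_table(contigs, as_genome(references[[cl]], cl),
                         evalue = 1e-5)
    if (nrow(hits) == 0) next
    per <- hits |>
      dplyr::group_by(.data$query_id) |>
      dplyr::group_map(function(h, key) {
        ir <- IRanges::reduce(IRanges::IRanges(
          start = pmin(h$q_start, h$q_end), end = pmax(h$q_start, h$q_end)))
        tibble::tibble(contig = key$query_id,
                       covered = sum(IRanges::width(ir)))
      }) |>
      dplyr::bind_rows()
    cov[per$contig, cl] <- per$covered / nchar(contigs[per$contig])
  }

  purrr::map(names(contigs), function(id) {
    if (marker_call[[id]]) {
      return(tibble::tibble(contig = id, class = "repA_megaplasmid",
                            evidence = sprintf("marker:%s", marker_hits[[id]]),
                            marker_hits = marker_hits[[id]],
                            best_coverage = NA_real_))
    }
    if (length(references) == 0 || all(cov[id, ] < min_coverage_floor)) {
      return(tibble::tibble(contig = id, class = "unassigned",
                            evidence = "below homology floor",
                            marker_hits = "", best_coverage = max(cov[id, ], 0)))
    }
    best <- names(references)[which.max(cov[id, ])]
    tibble::tibble(contig = id, class = best,
                   evidence = sprintf("homology:%.3f", max(cov[id, ])),
                   marker_hits = "", best_coverage = max(cov[id, ]))
  }) |>
    dplyr::bind_rows()
}

#' Call presence of a reference gene cluster in a strain
#'
#' Given annotation-transfer labels mapping a strain's genes to the genes
#' of an ordered reference cluster (e.g. an exopolysaccharide biosynthesis
#' cluster), reports per-gene presence, the total, the cluster-level call
#' (present iff at least `min_genes` reference genes are matched), and the
#' observed order of the matched genes for synteny inspection.
#'
#' @param labels Tibble from [transfer_annotation()] run against the
#'   cluster's reference proteins: columns `gene_id`, `label` (reference
#'   gene id). Extra columns are kept for ordering when present.
#' @param cluster Character vector of reference gene ids in reference
#'   synteny order (>= 2 genes).
#' @param min_genes Minimum matched genes for a cluster-level presence
#'   call (default 18).
#' @param gene_positions Optional tibble (`gene_id`, `replicon_id`,
#'   `start`) used to report the observed order of matched genes.
#' @return A `cluster_presence` list: `per_gene` tibble (reference_gene,
#'   present), `total_present`, `cluster_present`, `observed_order`.
#' @export
call_cluster_presence <- function(labels, cluster, min_genes = 18,
                                  gene_positions = NULL) {
  assert_that(length(cluster) >= 2, "reference cluster needs >= 2 genes")
  assert_that(min_genes <= length(cluster),
              "min_genes exceeds the cluster size")
  matched <- labels[labels$label %in% cluster, , drop = FALSE]
  present <- cluster %in% matched$label
  observed <- character(0)
  if (nrow(matched) > 0) {
    if (!is.null(gene_positions)) {
      ord <- matched |>
        dplyr::left_join(gene_positions, by = "gene_id") |>
        dplyr::arrange(.data$replicon_id, .data$start)
      observed <- ord$label
    } else {
      observed <- matched$label[order(match(matched$label, cluster))]
    }
  }
  structure(list(
    per_gene = tibble::tibble(reference_gene = cluster, present = present),
    total_present = sum(present),
    cluster_present = sum(present) >= min_genes,
    min_genes = min_genes,
    observed_order = observed
  ), class = "cluster_presence")
}

#' @export
print.cluster_presence <- function(x, ...) {
  cat(sprintf("<cluster_presence> %d/%d reference genes matched -> %s (min %d)\n",
              x$total_present, nrow(x$per_gene),
              if (x$cluster_present) "present" else "absent", x$min_genes))
  invisible(x)
}

#' Functional count matrix per strain and replicon class
#'
#' Counts labelled genes per (strain, replicon class, category) and adds
#' within-(strain, replicon class) proportions. A gene with several labels
#' under one scheme is counted once under its best-scoring label (a note
#' records how many were collapsed). Strains lacking a replicon class
#' yield no row for it.
#'
#' @param labelled_genes Tibble with columns `gene_id`, `strain`,
#'   `replicon_class`, `label`, and optionally `bit_score` (used to pick
#'   the best label when a gene has several).
#' @param categories Optional category set fixing the full label universe
#'   (zero-count categories are completed per present strain-class row
#'   when supplied).
#' @return Tibble: `strain`, `replicon_class`, `label`, `n`, `proportion`.
#' @export
feature_count_matrix <- function(labelled_genes, categories = NULL) {
  need <- c("gene_id", "strain", "replicon_class", "label")
  assert_that(all(need %in% names(labelled_genes)),
              paste("labelled_genes needs columns:", paste(need, collapse = ", ")))
  g <- labelled_genes
  if (anyDuplicated(g$gene_id)) {
    n_multi <- sum(duplicated(g$gene_id))
    if ("bit_score" %in% names(g)) {
      g <- g |>
        dplyr::arrange(.data$gene_id, dplyr::desc(.data$bit_score),
                       .data$label) |>
        dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    } else {
      g <- dplyr::distinct(g, .data$gene_id, .keep_all = TRUE)
    }
    rlang::inform(sprintf(
      "%d multi-label genes counted once under their best-scoring label",
      n_multi))
  }
  counts <- g |>
    dplyr::count(.data$strain, .data$replicon_class, .data$label)
  if (!is.null(categories)) {
    counts <- counts |>
      tidyr::complete(tidyr::nesting(strain = .data$strain,
                                     replicon_class = .data$replicon_class),
                      label = categories, fill = list(n = 0L))
  }
  counts |>
    dplyr::group_by(.data$strain, .data$replicon_class) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
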