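# Ortholog family inference: reciprocal best hits over pairwise searches,
# two-stage clustering (single linkage then Markov clustering), and the
# augmented presence/absence matrix.

#' Reciprocal best hits between two genomes
#'
#' Given the two directed hit tables of one genome pair, returns the gene
#' pairs `(a, b)` where `b` is `a`'s unique best subject and `a` is `b`'s
#' unique best subject. "Best" is the highest bit score, ties broken by
#' higher percent identity and then lexicographic subject id, which makes
#' the best hit unique and the result deterministic.
#'
#' @param hits_ab,hits_ba Hit tibbles from [pairwise_search()] run in the
#'   two directions of one genome pair.
#' @return A tibble with columns `gene_a`, `gene_b`, `bit_score` (mean of
#'   the two directed scores).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  dplyr::inner_join(
    best_ab |>
      dplyr::select(gene_a = "query_id", gene_b = "subject_id",
                    bit_ab = "bit_score"),
    best_ba |>
      dplyr::select(gene_a = "subject_id", gene_b = "query_id",
                    bit_ba = "bit_score"),
    by = c("gene_a", "gene_b")
  ) |>
    dplyr::mutate(bit_score = (.data$bit_ab + .data$bit_ba) / 2) |>
    dplyr::select("gene_a", "gene_b", "bit_score") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$percent_identity), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Two-stage clustering of reciprocal-best-hit edges into ortholog families
#'
#' Stage 1 finds connected components of the RBH graph (single linkage);
#' stage 2 runs Markov clustering (expansion power 2, inflation `inflation`)
#' within each component on the bit-score-weighted adjacency. Clusters
#' smaller than `min_cluster_size` are demoted to singletons, as are genes
#' with no edges.
#'
#' @param rbb_edges Tibble of weighted edges: columns `gene_a`, `gene_b`,
#'   and a weight column (`bit_score` or `weight`); weights must be
#'   positive.
#' @param genes Optional tibble attributing genes to strains (columns
#'   `gene_id`, `strain`); also supplies isolated genes absent from the
#'   edge list so they can be reported as singletons.
#' @param inflation MCL inflation parameter (default 3).
#' @param min_cluster_size Minimum family size (default 2).
#' @return An `ortholog_families` object: tibbles `families` (family_id,
#'   gene_id, strain) and `singletons` (gene_id, strain), plus the
#'   clustering parameters.
#' @export
cluster_orthologs <- function(rbb_edges, genes = NULL,
                              inflation = 3, min_cluster_size = 2) {
  wcol <- intersect(c("bit_score", "weight"), names(rbb_edges))[1]
  assert_that(!is.na(wcol), "rbb_edges needs a bit_score or weight column")
  edges <- tibble::tibble(from = as.character(rbb_edges$gene_a),
                          to = as.character(rbb_edges$gene_b),
                          w = as.numeric(rbb_edges[[wcol]]))
  assert_that(all(edges$w > 0), "edge weights must be positive")

  nodes <- union(edges$from, edges$to)
  if (!is.null(genes)) nodes <- union(nodes, genes$gene_id)
  nodes <- sort(nodes)

  clusters <- list()
  if (nrow(edges) > 0) {
    comp <- connected_components(edges, sort(union(edges$from, edges$to)))
    clusters <- unlist(lapply(comp, function(members) {
      if (length(members) <= 2) return(list(members))
      mcl_cluster(members, edges, inflation = inflation)
    }), recursive = FALSE)
  }

  keep <- vapply(clusters, length, integer(1)) >= min_cluster_size
  fam_clusters <- clusters[keep]
  # deterministic family ids: order clusters by their smallest member
  ord <- order(vapply(fam_clusters, function(m) sort(m)[1], character(1)))
  fam_clusters <- fam_clusters[ord]
  singleton_genes <- sort(c(unlist(clusters[!keep]),
                            setdiff(nodes, unlist(clusters))))

  fam_tbl <- if (length(fam_clusters) > 0) {
    tibble::tibble(
      family_id = rep(sprintf("FAM%05d", seq_along(fam_clusters)),
                      lengths(fam_clusters)),
      gene_id = unlist(lapply(fam_clusters, sort))
    )
  } else {
    tibble::tibble(family_id = character(), gene_id = character())
  }
  sing_tbl <- tibble::tibble(gene_id = singleton_genes)
  if (!is.null(genes)) {
    strain_map <- genes |> dplyr::distinct(.data$gene_id, .data$strain)
    fam_tbl <- dplyr::left_join(fam_tbl, strain_map, by = "gene_id")
    sing_tbl <- dplyr::left_join(sing_tbl, strain_map, by = "gene_id")
  } else {
    fam_tbl$strain <- NA_character_
    sing_tbl$strain <- NA_character_
  }

  structure(list(families = fam_tbl, singletons = sing_tbl,
                 inflation = inflation, min_cluster_size = min_cluster_size),
            class = "ortholog_families")
}

#' @export
print.ortholog_families <- function(x, ...) {
  cat(sprintf("<ortholog_families> %d families (%d genes), %d singletons; inflation %.3g, min size %d\n",
              length(unique(x$families$family_id)), nrow(x$families),
              nrow(x$singletons), x$inflation, x$min_cluster_size))
  invisible(x)
}

#' @method glance ortholog_families
#' @export
glance.ortholog_families <- function(x, ...) {
  tibble::tibble(n_families = length(unique(x$families$family_id)),
                 n_clustered_genes = nrow(x$families),
                 n_singletons = nrow(x$singletons),
                 inflation = x$inflation,
                 min_cluster_size = x$min_cluster_size)
}

# Union-find connected components over an edge list.
connected_components <- function(edges, nodes) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  for (k in seq_along(fi)) {
    a <- find(fi[[k]]); b <- find(ti[[k]])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  unname(split(nodes, roots))
}

# Markov clustering on one component. Column-stochastic transition matrix
# with self-loops (loop weight = maximum incident edge weight), expansion
# power 2, inflation r; converged when the largest entry change is below
# 1e-6 or after 100 iterations. Attractors (non-zero diagonal) define the
# clusters; a node attracted by several clusters goes to the one holding
# the most of its column mass (ties: lexicographically smallest attractor).
mcl_cluster <- function(members, edges, inflation,
                        tol = 1e-6, max_iter = 100L) {
  members <- sort(members)
  n <- length(members)
  A <- matrix(0, n, n, dimnames = list(members, members))
  sub <- edges[edges$from %in% members & edges$to %in% members, ]
  for (k in seq_len(nrow(sub))) {
    i <- sub$from[[k]]; j <- sub$to[[k]]
    A[i, j] <- A[i, j] + sub$w[[k]]
    A[j, i] <- A[j, i] + sub$w[[k]]
  }
  diag(A) <- apply(A, 2, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- M2^inflation               # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  attractors <- members[diag(M) > 1e-8]
  if (length(attractors) == 0) return(list(members))
  assign_to <- vapply(members, function(g) {
    mass <- M[attractors, g]
    attractors[which.max(mass)]      # which.max takes the first = smallest id
  }, character(1))
  # merge attractor labels that share members via overlapping attractor rows:
  # two attractors in the same cluster attract each other
  attr_label <- assign_to[attractors]
  lab <- vapply(assign_to, function(a) attr_label[[a]], character(1))
  unname(split(members, lab))
}

#' Build the augmented presence/absence matrix
#'
#' One row per strain; one column per ortholog family plus one column per
#' singleton gene (the unique genes excluded by the minimum cluster size
#' are re-added here as prevalence-1 columns). Entries are binarised:
#' paralogs within a strain still give a single 1.
#'
#' @param families An `ortholog_families` object whose gene records carry
#'   strain attributions.
#' @param strains Character vector fixing the row set and order; defaults
#'   to the strains seen in `families`.
#' @param gene_meta Optional tibble (`gene_id`, `replicon_class`) used to
#'   record each column's modal replicon class.
#' @return A `pa_matrix`: an integer matrix with strain rows and family /
#'   singleton columns, with attributes `column_type` and (optionally)
#'   `replicon_class`.
#' @export
build_presence_absence <- function(families, strains = NULL, gene_meta = NULL) {
  stopifnot(inherits(families, "ortholog_families"))
  all_genes <- dplyr::bind_rows(
    families$families |> dplyr::select("gene_id", "strain"),
    families$singletons |> dplyr::select("gene_id", "strain")
  )
  if (any(is.na(all_genes$strain))) {
    abort(sprintf("gene with unknown strain: %s",
                  all_genes$gene_id[is.na(all_genes$strain)][1]))
  }
  if (is.null(strains)) strains <- sort(unique(all_genes$strain))
  unknown <- setdiff(all_genes$strain, strains)
  assert_that(length(unknown) == 0,
              sprintf("gene attributed to strain outside the panel: %s",
                      unknown[1]))

  fam_cols <- sort(unique(families$families$family_id))
  sing_cols <- families$singletons$gene_id
  cols <- c(fam_cols, sing_cols)
  m <- matrix(0L, nrow = length(strains), ncol = length(cols),
              dimnames = list(strains, cols))
  if (nrow(families$families) > 0) {
    idx <- cbind(match(families$families$strain, strains),
                 match(families$families$family_id, cols))
    m[idx] <- 1L
  }
  if (length(sing_cols) > 0) {
    m[cbind(match(families$singletons$strain, strains),
            match(sing_cols, cols))] <- 1L
  }
  column_type <- c(rep("family", length(fam_cols)),
                   rep("singleton", length(sing_cols)))
  attr(m, "column_type") <- setNames(column_type, cols)
  if (!is.null(gene_meta) && "replicon_class" %in% names(gene_meta)) {
    memb <- dplyr::bind_rows(
      families$families |> dplyr::select(column = "family_id", "gene_id"),
      families$singletons |>
        dplyr::transmute(column = .data$gene_id, gene_id = .data$gene_id)
    ) |>
      dplyr::left_join(gene_meta |>
                         dplyr::distinct(.data$gene_id, .data$replicon_class),
                       by = "gene_id")
    modal <- memb |>
      dplyr::count(.data$column, .data$replicon_class) |>
      dplyr::arrange(.data$column, dplyr::desc(.data$n),
                     .data$replicon_class) |>
      dplyr::distinct(.data$column, .keep_all = TRUE)
    attr(m, "replicon_class") <-
      setNames(modal$replicon_class, modal$column)[cols]
  }
  class(m) <- c("pa_matrix", class(m))
  m
}

#' @export
print.pa_matrix <- function(x, ...) {
  ct <- attr(x, "column_type")
  cat(sprintf("<pa_matrix> %d strains x %d columns (%d families, %d singletons)\n",
              nrow(x), ncol(x), sum(ct == "family"), sum(ct == "singleton")))
  invisible(x)
}

#' Tidy a presence/absence matrix to long format
#'
#' @param x A `pa_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `strain`, `column`, `column_type`,
#'   `present`.
#' @method tidy pa_matrix
#' @export
tidy.pa_matrix <- function(x, ...) {
  ct <- attr(x, "column_type")
  tibble::tibble(
    strain = rep(rownames(x), times = ncol(x)),
    column = rep(colnames(x), each = nrow(x)),
    column_type = rep(unname(ct), each = nrow(x)),
    present = as.integer(x)
  )
}
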