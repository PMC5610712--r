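# Concatenated core-gene alignment, gap-column stripping, SNP distances,
# neighbour-joining trees with bootstrap supports, and outgroup rooting.

#' Concatenate single-copy core genes per strain
#'
#' Restricts the family set to families with exactly one member in every
#' strain (single-copy core), fixes the gene order by sorted family id,
#' and concatenates each strain's sequences in that order. Families missing
#' from a strain or with multiple copies in any strain are excluded (the
#' count is recorded, not an error).
#'
#' @param families An `ortholog_families` object.
#' @param genes Tibble mapping `gene_id` to sequence: columns `gene_id`
#'   and `protein` (or `nt` when `alphabet = "nt"`).
#' @param strains Strains to include; defaults to all strains in
#'   `families`.
#' @param alphabet `"protein"` or `"nt"`.
#' @return A `core_concat` object: named character vector `sequences`, a
#'   `blocks` tibble (family_id, start, end, in concatenation coordinates),
#'   and `n_excluded`.
#' @export
concatenate_core <- function(families, genes, strains = NULL,
                             alphabet = c("protein", "nt")) {
  stopifnot(inherits(families, "ortholog_families"))
  alphabet <- match.arg(alphabet)
  seq_col <- if (alphabet == "protein") "protein" else "nt"
  assert_that(seq_col %in% names(genes),
              sprintf("genes needs a %s column", seq_col))
  fam <- families$families
  if (is.null(strains)) strains <- sort(unique(fam$strain))

  tab <- fam |>
    dplyr::filter(.data$strain %in% strains) |>
    dplyr::count(.data$family_id, .data$strain)
  per_fam <- tab |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(n_strains = dplyr::n(), max_copies = max(.data$n),
                     .groups = "drop")
  keep <- per_fam$family_id[per_fam$n_strains == length(strains) &
                              per_fam$max_copies == 1L]
  keep <- sort(keep)
  n_excluded <- length(unique(fam$family_id)) - length(keep)
  assert_that(length(keep) > 0, "no single-copy core families to concatenate")

  seq_map <- setNames(genes[[seq_col]], genes$gene_id)
  members <- fam |>
    dplyr::filter(.data$family_id %in% keep, .data$strain %in% strains) |>
    dplyr::arrange(.data$family_id)
  members$sequence <- unname(seq_map[members$gene_id])
  assert_that(!any(is.na(members$sequence)),
              "core gene without a sequence in `genes`")

  wide <- members |>
    dplyr::select("family_id", "strain", "sequence") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "sequence")
  wide <- wide[match(keep, wide$family_id), ]
  seqs <- vapply(strains, function(s) paste(wide[[s]], collapse = ""),
                 character(1))

  # block boundaries from the first strain's block lengths (blocks can be
  # ragged across strains before alignment; boundaries are nominal then)
  lens <- nchar(wide[[strains[1]]])
  blocks <- tibble::tibble(family_id = keep,
                           start = cumsum(dplyr::lag(lens, default = 0L)) + 1L,
                           end = cumsum(lens))
  structure(list(sequences = seqs, blocks = blocks,
                 n_excluded = n_excluded, alphabet = alphabet),
            class = "core_concat")
}

#' @export
print.core_concat <- function(x, ...) {
  cat(sprintf("<core_concat> %d strains, %d single-copy core families, %d excluded; %s\n",
              length(x$sequences), nrow(x$blocks), x$n_excluded, x$alphabet))
  invisible(x)
}

#' Align a set of sequences (pluggable engine)
#'
#' The `internal` engine handles the already-colinear case: sequences of
#' equal length are returned unchanged (no gaps needed), unequal lengths
#' are an error directing the user to an external aligner. The `mafft`
#' engine shells out to MAFFT when it is on the PATH.
#'
#' @param sequences Named character vector.
#' @param engine `"internal"` or `"mafft"`.
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_sequences <- function(sequences, engine = c("internal", "mafft")) {
  engine <- match.arg(engine)
  assert_that(length(sequences) >= 2 && !is.null(names(sequences)),
              "need >= 2 named sequences")
  if (engine == "internal") {
    assert_that(length(unique(nchar(sequences))) == 1,
                paste("internal aligner requires equal-length sequences;",
                      "use engine = 'mafft' or align externally"))
    return(sequences)
  }
  mafft <- find_tool("mafft")
  dir <- tempfile("mafft")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  inf <- file.path(dir, "in.fa")
  outf <- file.path(dir, "out.fa")
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), inf)
  system2(mafft, c("--auto", "--quiet", inf), stdout = outf)
  aln <- Biostrings::readBStringSet(outf)
  setNames(toupper(as.character(aln)), names(aln))[names(sequences)]
}

as_alignment <- function(x) {
  if (inherits(x, "core_concat")) x <- x$sequences
  if (inherits(x, c("AAStringSet", "DNAStringSet", "BStringSet"))) {
    x <- setNames(as.character(x), names(x))
  }
  assert_that(is.character(x) && length(x) >= 2 && !is.null(names(x)),
              "expected >= 2 named aligned sequences")
  assert_that(length(unique(nchar(x))) == 1,
              "aligned sequences must have equal length")
  x
}

#' Remove alignment columns containing gaps
#'
#' Keeps exactly the columns in which no sequence has a gap character
#' (`-` or `.`), preserving column order.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (or a `core_concat` / `XStringSet`).
#' @return Named character vector with gapped columns removed, with
#'   attribute `kept_columns` (indices into the input columns).
#' @export
strip_gap_columns <- function(alignment) {
  aln <- as_alignment(alignment)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap <- colSums(m == "-" | m == ".") > 0
  out <- apply(m[, !gap, drop = FALSE], 1, paste, collapse = "")
  out <- setNames(out, names(aln))
  attr(out, "kept_columns") <- which(!gap)
  out
}

#' Pairwise SNP distances on a gap-free alignment
#'
#' Counts, for every strain pair, the alignment columns at which the two
#' sequences differ (case-insensitive; any non-identical pair of symbols
#' counts as a difference).
#'
#' @param alignment Gap-free alignment (see [strip_gap_columns()]).
#' @return Symmetric integer matrix of SNP counts with zero diagonal.
#' @export
snp_distance <- function(alignment) {
  aln <- as_alignment(alignment)
  assert_that(!any(grepl("[-.]", aln)),
              "alignment contains gaps; strip_gap_columns() first")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Builds an unrooted neighbour-joining topology with branch lengths;
#' negative branch lengths (an NJ artefact) are clamped to zero with the
#' deficit moved to the adjacent branch so leaf-to-leaf path lengths are
#' approximately preserved.
#'
#' @param matrix Symmetric, zero-diagonal distance matrix (>= 3 taxa), or
#'   2 taxa for the trivial single-edge tree.
#' @return An `ape::phylo` tree.
#' @export
distance_tree <- function(matrix) {
  assert_that(is.matrix(matrix) && !any(is.na(matrix)),
              "distance matrix must be complete (no NaN/NA)")
  assert_that(all(diag(matrix) == 0), "distance matrix must have zero diagonal")
  n <- nrow(matrix)
  if (n == 2) {
    lab <- rownames(matrix)
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", lab[1],
                                        matrix[1, 2] / 2, lab[2],
                                        matrix[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(matrix))
  fix_negative_edges(tr)
}

# Clamp negative branch lengths to zero, transferring the deficit to the
# adjacent edge below the same node (largest-length neighbour).
fix_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[[1]]
    child <- tree$edge[e, 2]
    adjacent <- which(tree$edge[, 1] == child)
    if (length(adjacent) > 0) {
      a <- adjacent[which.max(tree$edge.length[adjacent])]
      tree$edge.length[a] <- tree$edge.length[a] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrapped neighbour-joining tree from a gap-free alignment
#'
#' Builds the full-data tree via [snp_distance()] + [distance_tree()],
#' then resamples alignment columns with replacement `n_replicates` times;
#' the support of each internal bipartition of the full tree is the
#' percentage of replicate trees containing it.
#'
#' @param alignment Gap-free alignment with >= 4 taxa.
#' @param n_replicates Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return A `support_tree`: list with the `phylo` tree (node labels =
#'   supports), the `supports` vector, and `n_replicates`.
#' @export
bootstrap_tree <- function(alignment, n_replicates = 100, seed = NULL) {
  aln <- as_alignment(alignment)
  assert_that(length(aln) >= 4, "bootstrap needs >= 4 taxa")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  full <- distance_tree(hamming_matrix(m))
  rep_trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      distance_tree(hamming_matrix(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(full, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_replicates, 1)
  full$node.label <- as.character(supports)
  structure(list(phylo = full, supports = supports,
                 n_replicates = n_replicates, seed = seed),
            class = "support_tree")
}

hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("<support_tree> %d leaves, %d bootstrap replicates\n",
              length(x$phylo$tip.label), x$n_replicates))
  invisible(x)
}

#' Root a tree on an outgroup leaf
#'
#' Places the root on the outgroup's pendant edge. For display only, the
#' root branch can be shortened (mirroring the common practice of
#' truncating a long outgroup branch in figures); the returned Newick
#' distances are never altered by that flag, which only sets a
#' `display_root_length` attribute for plotting code.
#'
#' @param tree A `support_tree` or `ape::phylo`.
#' @param outgroup Leaf label to root on.
#' @param shorten_display Optional displayed root-branch length (plotting
#'   hint only).
#' @return Rooted tree of the same class as the input.
#' @export
root_tree <- function(tree, outgroup, shorten_display = NULL) {
  phy <- if (inherits(tree, "support_tree")) tree$phylo else tree
  assert_that(outgroup %in% phy$tip.label,
              sprintf("unknown outgroup '%s'", outgroup))
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(shorten_display)) {
    attr(rooted, "display_root_length") <- shorten_display
  }
  if (inherits(tree, "support_tree")) {
    tree$phylo <- rooted
    tree
  } else {
    rooted
  }
}
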