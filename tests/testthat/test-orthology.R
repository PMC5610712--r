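# Reciprocal best hits, two-stage clustering (single linkage + MCL) and
# the augmented presence/absence matrix.

mk_hits <- function(...) {
  # rows: query, subject, bit, identity
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, "", 1),
    subject_id = vapply(rows, `[[`, "", 2),
    bit_score = as.numeric(vapply(rows, `[[`, "", 3)),
    percent_identity = as.numeric(vapply(rows, `[[`, "", 4))
  )
}

test_that("identical proteomes give the identity RBH mapping", {
  prot <- withr::with_seed(2, setNames(
    vapply(c(90, 110, 130), random_protein, character(1)),
    c("a1", "a2", "a3")))
  protB <- setNames(prot, c("b1", "b2", "b3"))
  ab <- pairwise_search(prot, protB)
  ba <- pairwise_search(protB, prot)
  rbb <- reciprocal_best_hits(ab, ba)
  expect_equal(rbb$gene_a, c("a1", "a2", "a3"))
  expect_equal(rbb$gene_b, c("b1", "b2", "b3"))
})

test_that("RBH requires reciprocity of the unique best hit", {
  # brute-force over the 2x1 hit table: a's best is b1, b1's best is a
  ab <- mk_hits(c("a", "b1", "200", "90"), c("a", "b2", "150", "85"))
  ba <- mk_hits(c("b1", "a", "190", "90"), c("b2", "a", "150", "85"))
  rbb <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(rbb), 1)
  expect_equal(rbb$gene_a, "a")
  expect_equal(rbb$gene_b, "b1")
  # empty inputs give an empty result
  empty <- ab[0, ]
  expect_equal(nrow(reciprocal_best_hits(empty, empty)), 0)
})

test_that("best-hit ties break by identity then lexicographic subject id", {
  hits <- mk_hits(c("q", "r2", "100", "60"), c("q", "r1", "100", "80"),
                  c("q", "r3", "100", "80"))
  best <- panforge:::best_hit_per_query(hits)
  expect_equal(best$subject_id, "r1")  # identity 80 beats 60; r1 < r3
})

test_that("RBH pairs are invariant under swapping genome roles", {
  sim <- toy_sim()
  g <- sim$panel$genes
  a <- g[g$strain == "S01", ]
  b <- g[g$strain == "S02", ]
  ab <- pairwise_search(a, b)
  ba <- pairwise_search(b, a)
  r1 <- reciprocal_best_hits(ab, ba)
  r2 <- reciprocal_best_hits(ba, ab)
  expect_setequal(paste(r1$gene_a, r1$gene_b),
                  paste(r2$gene_b, r2$gene_a))
})

test_that("disjoint edges cluster into size-2 families; isolates are singletons", {
  edges <- tibble::tibble(gene_a = c("g1", "g3", "g5"),
                          gene_b = c("g2", "g4", "g6"),
                          bit_score = c(100, 90, 80))
  genes <- tibble::tibble(gene_id = paste0("g", 1:7),
                          strain = rep(c("A", "B"), length.out = 7))
  fams <- cluster_orthologs(edges, genes = genes)
  expect_equal(length(unique(fams$families$family_id)), 3)
  expect_true(all(table(fams$families$family_id) == 2))
  expect_equal(fams$singletons$gene_id, "g7")
})

test_that("two cliques joined by a weak edge split into two families under inflation", {
  # 8-node graph: two 4-cliques (weight 100) bridged by one weight-1 edge
  cl1 <- t(combn(paste0("a", 1:4), 2))
  cl2 <- t(combn(paste0("b", 1:4), 2))
  edges <- tibble::tibble(
    gene_a = c(cl1[, 1], cl2[, 1], "a1"),
    gene_b = c(cl1[, 2], cl2[, 2], "b1"),
    bit_score = c(rep(100, 12), 1)
  )
  fams <- cluster_orthologs(edges)
  split_fams <- split(fams$families$gene_id, fams$families$family_id)
  expect_equal(partition_signature(split_fams),
               c("a1|a2|a3|a4", "b1|b2|b3|b4"))
  # independent naive MCL oracle run to convergence on the same graph
  orc <- mcl_oracle(unique(c(edges$gene_a, edges$gene_b)),
                    data.frame(from = edges$gene_a, to = edges$gene_b,
                               w = edges$bit_score), inflation = 3)
  expect_equal(partition_signature(split_fams), partition_signature(orc))
})

test_that("clustering equals connected components when components are cliques", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      sizes <- sample(2:5, 3, replace = TRUE)
      nodes <- unlist(lapply(seq_along(sizes), function(i) {
        paste0("c", i, "n", seq_len(sizes[i]))
      }))
      edges <- dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
        members <- paste0("c", i, "n", seq_len(sizes[i]))
        pairs <- t(combn(members, 2))
        tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2],
                       bit_score = runif(nrow(pairs), 50, 150))
      }))
      fams <- cluster_orthologs(edges)
      split_fams <- split(fams$families$gene_id, fams$families$family_id)
      # oracle: igraph connected components
      g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
      comp <- igraph::components(g)
      orc <- split(names(comp$membership), comp$membership)
      expect_equal(partition_signature(split_fams), partition_signature(orc))
    }
  })
})

test_that("non-positive edge weights are rejected", {
  edges <- tibble::tibble(gene_a = "x", gene_b = "y", bit_score = 0)
  expect_error(cluster_orthologs(edges), "positive")
})

test_that("presence/absence matrix binarises paralogs and appends singletons", {
  fams <- structure(list(
    families = tibble::tibble(
      family_id = c("F1", "F1", "F1", "F2", "F2", "F2", "F2"),
      gene_id = c("gA1", "gB1", "gC1", "gA2", "gA3", "gB2", "gC2"),
      strain = c("A", "B", "C", "A", "A", "B", "C")),   # F2: paralogs in A
    singletons = tibble::tibble(
      gene_id = c("uA1", "uA2", "uB1", "uB2", "uC1", "uC2"),
      strain = rep(c("A", "B", "C"), each = 2)),
    inflation = 3, min_cluster_size = 2), class = "ortholog_families")
  pa <- build_presence_absence(fams)
  expect_equal(dim(pa), c(3, 8))
  expect_true(all(pa[, c("F1", "F2")] == 1))       # paralogs -> single 1
  sing_cols <- colnames(pa)[attr(pa, "column_type") == "singleton"]
  expect_length(sing_cols, 6)
  expect_true(all(colSums(pa[, sing_cols]) == 1))
  expect_true(all(colSums(pa[, c("F1", "F2")]) >= 2))
  # total ones = number of (strain, family/column) incidences
  expect_equal(sum(pa), 3 + 3 + 6)
})

test_that("genes without strain attribution are an error", {
  fams <- structure(list(
    families = tibble::tibble(family_id = c("F1", "F1"),
                              gene_id = c("x", "y"),
                              strain = c("A", NA)),
    singletons = tibble::tibble(gene_id = character(), strain = character()),
    inflation = 3, min_cluster_size = 2), class = "ortholog_families")
  expect_error(build_presence_absence(fams), "unknown strain")
})

test_that("modal replicon class is recorded per column", {
  fams <- structure(list(
    families = tibble::tibble(family_id = c("F1", "F1", "F1"),
                              gene_id = c("x", "y", "z"),
                              strain = c("A", "B", "C")),
    singletons = tibble::tibble(gene_id = "u", strain = "A"),
    inflation = 3, min_cluster_size = 2), class = "ortholog_families")
  meta <- tibble::tibble(gene_id = c("x", "y", "z", "u"),
                         replicon_class = c("chromosome", "chromosome",
                                            "small_plasmid", "small_plasmid"))
  pa <- build_presence_absence(fams, gene_meta = meta)
  expect_equal(unname(attr(pa, "replicon_class")[c("F1", "u")]),
               c("chromosome", "small_plasmid"))
})
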