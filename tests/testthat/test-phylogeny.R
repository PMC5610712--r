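# Core concatenation, gap stripping, SNP distances, NJ + bootstrap, rooting.

fam_set <- function(family_id, gene_id, strain) {
  structure(list(
    families = tibble::tibble(family_id = family_id, gene_id = gene_id,
                              strain = strain),
    singletons = tibble::tibble(gene_id = character(), strain = character()),
    inflation = 3, min_cluster_size = 2), class = "ortholog_families")
}

test_that("single-copy core families concatenate in sorted family order", {
  fams <- fam_set(rep(c("F1", "F2", "F3"), each = 2),
                  c("a1", "b1", "a2", "b2", "a3", "b3"),
                  rep(c("A", "B"), 3))
  genes <- tibble::tibble(gene_id = c("a1", "b1", "a2", "b2", "a3", "b3"),
                          protein = c("MA", "MA", "KRR", "KRK", "WYF", "WYF"))
  cc <- concatenate_core(fams, genes)
  expect_equal(unname(cc$sequences["A"]), "MAKRRWYF")
  expect_equal(unname(cc$sequences["B"]), "MAKRKWYF")
  expect_equal(cc$blocks$family_id, c("F1", "F2", "F3"))
  expect_equal(cc$blocks$start, c(1, 3, 6))
  expect_equal(cc$blocks$end, c(2, 5, 8))
})

test_that("multi-copy and partial families are excluded with a count", {
  fams <- fam_set(c("F1", "F1", "F2", "F2", "F2", "F3"),
                  c("a1", "b1", "a2", "a2b", "b2", "a3"),
                  c("A", "B", "A", "A", "B", "A"))
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "a2", "a2b", "b2", "a3"),
    protein = c("MA", "MA", "KR", "KK", "KR", "WW"))
  cc <- concatenate_core(fams, genes)
  expect_equal(cc$blocks$family_id, "F1")   # F2 multi-copy, F3 partial
  expect_equal(cc$n_excluded, 2)
})

test_that("simulated all-core panel concatenates to the truth lengths", {
  sim <- toy_sim()
  truth <- sim$truth$membership
  core_ids <- names(which(table(truth$family_id) == 4))
  core_ids <- core_ids[grepl("^core", core_ids)]
  fams <- fam_set(truth$family_id[truth$family_id %in% core_ids],
                  truth$gene_id[truth$family_id %in% core_ids],
                  truth$strain[truth$family_id %in% core_ids])
  cc <- concatenate_core(fams, sim$panel$genes)
  lens <- unique(nchar(cc$sequences))
  expect_length(lens, 1)
  plen <- setNames(nchar(sim$panel$genes$protein), sim$panel$genes$gene_id)
  one_strain <- truth[truth$strain == "S01" & truth$family_id %in% core_ids, ]
  expect_equal(lens, sum(plen[one_strain$gene_id]))
})

test_that("gap-column stripping keeps exactly the gap-free columns", {
  aln <- c(s1 = "AC-GT", s2 = "ACCGT", s3 = "AC-GT")
  out <- strip_gap_columns(aln)
  expect_equal(unname(out), rep("ACGT", 3), ignore_attr = TRUE)
  expect_equal(attr(out, "kept_columns"), c(1, 2, 4, 5))
  gapless <- c(a = "ACGT", b = "TGCA")
  expect_equal(unname(strip_gap_columns(gapless)), unname(gapless),
               ignore_attr = TRUE)
  # random toy alignments vs a brute-force column filter
  withr::with_seed(23, {
    for (rep in 1:5) {
      m <- matrix(sample(c("A", "C", "G", "T", "-"), 8 * 30, TRUE,
                         prob = c(rep(0.22, 4), 0.12)), 8, 30)
      aln <- setNames(apply(m, 1, paste, collapse = ""), paste0("t", 1:8))
      keep <- which(apply(m, 2, function(col) all(col != "-")))
      oracle <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
      expect_equal(unname(strip_gap_columns(aln)), unname(oracle),
                   ignore_attr = TRUE)
    }
  })
})

test_that("SNP distances equal brute-force Hamming counts and are a metric", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AAAA", d = "CGAT")
  d <- snp_distance(aln)
  expect_equal(d["a", "b"], 1, ignore_attr = TRUE)
  expect_equal(d["a", "c"], 0, ignore_attr = TRUE)
  for (i in names(aln)) for (j in names(aln)) {
    expect_equal(d[i, j], hamming_oracle(aln[[i]], aln[[j]]),
                 ignore_attr = TRUE)
  }
  expect_error(snp_distance(c(a = "A-G", b = "AAG")), "gaps")
  withr::with_seed(29, {
    for (rep in 1:5) {
      aln <- setNames(vapply(rep(40, 5), random_dna, character(1)),
                      paste0("s", 1:5))
      d <- snp_distance(aln)
      expect_true(isSymmetric(d))
      expect_true(all(diag(d) == 0))
      # triangle inequality
      for (i in 1:5) for (j in 1:5) for (k in 1:5) {
        expect_lte(d[i, j], d[i, k] + d[k, j])
      }
    }
  })
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  # generating tree: ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  dm <- matrix(c(0, 5, 7, 8,
                 5, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- distance_tree(dm)
  # additivity: path lengths on the tree reproduce the input distances
  paths <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(paths, dm, tolerance = 1e-10)
  # correct topology: AB|CD split present
  splits <- ape::prop.part(tr)
  expect_true(any(vapply(splits, function(p) {
    setequal(tr$tip.label[p], c("A", "B")) ||
      setequal(tr$tip.label[p], c("C", "D"))
  }, logical(1))))
})

test_that("2-taxon and ultrametric 3-taxon cases behave as forced", {
  dm2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  tr2 <- distance_tree(dm2)
  expect_equal(sort(tr2$edge.length), c(3, 3))
  dm3 <- matrix(c(0, 2, 8,
                  2, 0, 8,
                  8, 8, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                  c("a", "b", "c")))
  tr3 <- distance_tree(dm3)
  paths <- ape::cophenetic.phylo(tr3)
  expect_lt(paths["a", "b"], paths["a", "c"])  # closest pair are siblings
  dmna <- dm3; dmna[1, 2] <- dmna[2, 1] <- NaN
  expect_error(distance_tree(dmna), "NaN")
})

test_that("bootstrap finds a planted bipartition with full support", {
  withr::with_seed(31, {
    left <- c("L1", "L2", "L3"); right <- c("R1", "R2", "R3")
    # 100 diagnostic columns separating the two clades + 40 noise-free shared
    diag_cols <- c(rep("A", 3), rep("C", 3))
    m <- matrix(rep(diag_cols, 100), 6, 100)
    shared <- matrix(rep(sample(c("A", "C", "G", "T"), 40, TRUE), each = 6),
                     6, 40)
    # a few taxon-specific sites so within-clade distances are nonzero
    priv <- diag(6)
    privm <- matrix("T", 6, 6); privm[priv == 1] <- "G"
    aln <- setNames(apply(cbind(m, shared, privm), 1, paste, collapse = ""),
                    c(left, right))
    bt <- bootstrap_tree(aln, n_replicates = 50, seed = 9)
    split_sets <- ape::prop.part(bt$phylo)
    labs <- bt$phylo$tip.label
    idx <- which(vapply(split_sets, function(p) {
      setequal(labs[p], left) || setequal(labs[p], right)
    }, logical(1)))
    expect_length(idx, 1)
    node_support <- as.numeric(bt$phylo$node.label)
    expect_equal(node_support[idx], 100)
    # determinism
    bt2 <- bootstrap_tree(aln, n_replicates = 50, seed = 9)
    expect_identical(bt$phylo$node.label, bt2$phylo$node.label)
  })
})

test_that("identical sequences give a star-like unsupported tree", {
  aln <- setNames(rep(strrep("ACGT", 20), 4), paste0("t", 1:4))
  bt <- bootstrap_tree(aln, n_replicates = 20, seed = 2)
  expect_true(all(bt$phylo$edge.length == 0))
})

test_that("rooting places the outgroup basally and preserves bipartitions", {
  dm <- matrix(c(0, 4, 6, 10,
                 4, 0, 6, 10,
                 6, 6, 0, 10,
                 10, 10, 10, 0), 4, 4,
               dimnames = list(c("a", "b", "c", "out"),
                               c("a", "b", "c", "out")))
  tr <- distance_tree(dm)
  rooted <- root_tree(tr, "out")
  expect_true(ape::is.rooted(rooted))
  # unrooting returns the original bipartition set
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr), 0,
               ignore_attr = TRUE)
  # leaf-to-leaf path lengths unchanged by rooting
  expect_equal(ape::cophenetic.phylo(rooted)[rownames(dm), rownames(dm)],
               ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)],
               tolerance = 1e-10)
  expect_error(root_tree(tr, "nope"), "unknown outgroup")
})

test_that("3-leaf rooting makes the outgroup sister to the rest", {
  dm3 <- matrix(c(0, 2, 6,
                  2, 0, 6,
                  6, 6, 0), 3, 3,
                dimnames = list(c("a", "b", "o"), c("a", "b", "o")))
  rooted <- root_tree(distance_tree(dm3), "o")
  # the two non-outgroup leaves form a clade
  parts <- ape::prop.part(rooted)
  expect_true(any(vapply(parts, function(p) {
    setequal(rooted$tip.label[p], c("a", "b"))
  }, logical(1))))
})

test_that("SNP counts scale linearly with substitution rate", {
  withr::with_seed(33, {
    base <- random_dna(8000)
    rates <- c(0.005, 0.01, 0.02, 0.04)
    res <- purrr::map_dfr(1:10, function(s) {
      tibble::tibble(rate = rates, snps = vapply(rates, function(r) {
        a <- mutate_sequence(base, r)
        b <- mutate_sequence(base, r)
        snp_distance(c(x = a, y = b))["x", "y"]
      }, numeric(1)))
    })
    fit <- lm(snps ~ rate, data = res)
    expect_gt(coef(fit)[2], 0)
    expect_gt(summary(fit)$r.squared, 0.9)
  })
})
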