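# Marker-based replicon assignment, reference-cluster presence calls,
# functional count matrices.

make_marker_case <- function() {
  withr::with_seed(41, {
    repA <- random_dna(900); repE <- random_dna(800); parA <- random_dna(700)
    chr_ref <- random_dna(40000)
    pl_ref <- random_dna(8000)
    mega <- paste0(random_dna(3000), repA, random_dna(2000), repE,
                   random_dna(1500), parA, random_dna(3000))
    list(markers = c(repA = repA, repE = repE, parA = parA),
         references = list(chromosome = c(chr = chr_ref),
                           small_plasmid = c(pl = pl_ref)),
         mega = mega, chr_ref = chr_ref, pl_ref = pl_ref)
  })
}

test_that("contigs carrying repA-type markers are called megaplasmid", {
  cs <- make_marker_case()
  # chromosome-like contig: 90% chromosome reference + filler
  chr_contig <- withr::with_seed(42, paste0(substr(cs$chr_ref, 1, 27000),
                                            random_dna(3000)))
  res <- assign_replicons(
    c(ctg_mp = cs$mega, ctg_chr = chr_contig),
    markers = cs$markers, references = cs$references)
  expect_equal(res$class[res$contig == "ctg_mp"], "repA_megaplasmid")
  expect_match(res$marker_hits[res$contig == "ctg_mp"], "parA,repA,repE")
  expect_equal(res$class[res$contig == "ctg_chr"], "chromosome")
  expect_gt(res$best_coverage[res$contig == "ctg_chr"], 0.85)
})

test_that("diverged markers below the identity threshold do not trigger the marker rule", {
  cs <- make_marker_case()
  # ~79% identity marker copy, as for a distant outgroup hit
  far_repA <- mutate_sequence(cs$markers[["repA"]], 0.21, seed = 43)
  contig <- withr::with_seed(44,
    paste0(substr(cs$chr_ref, 1, 20000), far_repA, random_dna(1000)))
  res <- assign_replicons(c(ctg = contig), markers = cs$markers,
                          references = cs$references)
  expect_equal(res$class, "chromosome")   # homology wins, not the marker
  expect_equal(res$marker_hits, "")
})

test_that("contigs under the homology floor stay unassigned and order does not matter", {
  cs <- make_marker_case()
  stray <- withr::with_seed(45, random_dna(5000))
  contigs <- c(ctg_mp = cs$mega, stray = stray)
  res1 <- assign_replicons(contigs, markers = cs$markers,
                           references = cs$references)
  res2 <- assign_replicons(rev(contigs), markers = cs$markers,
                           references = cs$references)
  expect_equal(res1$class[res1$contig == "stray"], "unassigned")
  expect_equal(dplyr::arrange(res1, contig), dplyr::arrange(res2, contig))
})

test_that("cluster presence uses an inclusive minimum-gene threshold", {
  cluster <- sprintf("eps%02d", 1:21)
  mk_labels <- function(n) {
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)),
                   label = cluster[seq_len(n)])
  }
  expect_true(call_cluster_presence(mk_labels(21), cluster)$cluster_present)
  expect_false(call_cluster_presence(mk_labels(17), cluster)$cluster_present)
  call18 <- call_cluster_presence(mk_labels(18), cluster)
  expect_true(call18$cluster_present)
  expect_equal(call18$total_present, 18)
  expect_equal(sum(call18$per_gene$present), 18)
  expect_error(call_cluster_presence(mk_labels(5), cluster, min_genes = 30),
               "exceeds")
})

test_that("cluster presence is monotone in matched genes", {
  cluster <- sprintf("eps%02d", 1:21)
  labs <- tibble::tibble(gene_id = sprintf("g%02d", 1:17),
                         label = cluster[1:17])
  before <- call_cluster_presence(labs, cluster)
  after <- call_cluster_presence(
    dplyr::bind_rows(labs, tibble::tibble(gene_id = "g18", label = cluster[18])),
    cluster)
  expect_false(before$cluster_present && !after$cluster_present)
  expect_gte(after$total_present, before$total_present)
})

test_that("observed gene order follows genomic coordinates", {
  cluster <- c("epsA", "epsB", "epsC")
  labs <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         label = c("epsC", "epsA", "epsB"))
  pos <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        replicon_id = "chr", start = c(100, 500, 900))
  call <- call_cluster_presence(labs, cluster, min_genes = 2,
                                gene_positions = pos)
  expect_equal(call$observed_order, c("epsC", "epsA", "epsB"))
})

test_that("feature counts and proportions recount the labels exactly", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    strain = "S1",
    replicon_class = c(rep("chromosome", 3), rep("repA_megaplasmid", 2)),
    label = c("GH13", "GH13", "GH32", "GT2", "GT4")
  )
  fc <- feature_count_matrix(genes)
  chr <- fc[fc$replicon_class == "chromosome", ]
  expect_equal(chr$n[chr$label == "GH13"], 2)
  expect_equal(chr$n[chr$label == "GH32"], 1)
  expect_false("small_plasmid" %in% fc$replicon_class)  # no plasmid row
  sums <- tapply(fc$proportion, paste(fc$strain, fc$replicon_class), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("multi-label genes are counted once under their best label", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    strain = "S1",
    replicon_class = "chromosome",
    label = c("GH13", "GH32", "GH13"),
    bit_score = c(80, 120, 60)
  )
  expect_message(fc <- feature_count_matrix(genes), "multi-label")
  expect_equal(sum(fc$n), 2)
  expect_equal(fc$n[fc$label == "GH32"], 1)   # higher bit score wins
})

test_that("count matrices recount the simulated truth table", {
  sim <- toy_sim()
  # plant labels: each gene labelled by its family's kind
  truth <- dplyr::left_join(
    sim$truth$membership,
    dplyr::select(sim$truth$prevalence, family_id, kind),
    by = "family_id")
  genes <- dplyr::transmute(truth, gene_id, strain, replicon_class,
                            label = kind)
  fc <- feature_count_matrix(genes)
  # oracle: plain table() on the truth
  orc <- as.data.frame(table(truth$strain, truth$replicon_class, truth$kind),
                       stringsAsFactors = FALSE)
  names(orc) <- c("strain", "replicon_class", "label", "freq")
  orc <- orc[orc$freq > 0, ]
  joined <- dplyr::inner_join(fc, orc,
                              by = c("strain", "replicon_class", "label"))
  expect_equal(nrow(joined), nrow(fc))
  expect_equal(joined$n, joined$freq)
})
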