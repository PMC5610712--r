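# Panel serialisation: genome FASTA + protein FASTA + GFF3 per strain,
# one truth TSV for the whole run.

#' Write a genome panel to disk
#'
#' Emits, per strain, a genome FASTA (`<strain>.fna`, 60-column wrap), a
#' protein FASTA (`<strain>.faa`) and a GFF3 gene-model file
#' (`<strain>.gff3`); if `truth` is supplied, a single `truth.tsv`
#' (gene_id, strain, replicon_id, replicon_class, family_id) is written
#' alongside. [read_panel()] round-trips the output.
#'
#' @param panel A `genome_panel`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `panel_truth` to serialise with the panel.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, truth = NULL) {
  stopifnot(inherits(panel, "genome_panel"))
  assert_that(nrow(panel$replicons) > 0, "panel is empty")
  strains <- unique(panel$replicons$strain)
  assert_that(!anyDuplicated(tolower(strains)),
              "strain identifiers collide (case-insensitive)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  for (s in strains) {
    reps <- panel$replicons[panel$replicons$strain == s, ]
    headers <- if ("class" %in% names(reps)) {
      sprintf("%s class=%s", reps$replicon_id, reps$class)
    } else {
      reps$replicon_id
    }
    dna <- Biostrings::DNAStringSet(setNames(reps$sequence, headers))
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(s, ".fna")),
                                width = 60L)
    genes <- panel$genes[panel$genes$strain == s, ]
    aa <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(s, ".faa")),
                                width = 60L)
    write_gff3(genes, reps, file.path(dir, paste0(s, ".gff3")))
  }
  if (!is.null(truth)) {
    readr::write_tsv(truth$membership, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

write_gff3 <- function(genes, reps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(reps))) {
    writeLines(sprintf("##sequence-region %s 1 %d", reps$replicon_id[[i]],
                       nchar(reps$sequence[[i]])), con)
  }
  if (nrow(genes) > 0) {
    lines <- sprintf("%s\tpanforge\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$replicon_id, genes$start, genes$end,
                     genes$strand, genes$gene_id)
    writeLines(lines, con)
  }
}

#' Read a genome panel from disk
#'
#' Reconstructs a `genome_panel` (and, when present, its `panel_truth`)
#' from a directory written by [write_panel()].
#'
#' @param dir Directory containing `<strain>.fna`, `<strain>.faa`,
#'   `<strain>.gff3` and optionally `truth.tsv`.
#' @return A list with `panel` and (possibly `NULL`) `truth`.
#' @export
read_panel <- function(dir) {
  fna <- sort(list.files(dir, pattern = "\\.fna$", full.names = TRUE))
  assert_that(length(fna) > 0, sprintf("no genome FASTA files under %s", dir))
  strains <- sub("\\.fna$", "", basename(fna))

  rep_rows <- list()
  gene_rows <- list()
  for (i in seq_along(strains)) {
    s <- strains[[i]]
    dna <- Biostrings::readDNAStringSet(fna[[i]])
    headers <- names(dna)
    ids <- sub("\\s.*$", "", headers)
    cls <- ifelse(grepl("class=", headers),
                  sub("^.*class=(\\S+).*$", "\\1", headers), NA_character_)
    names(dna) <- ids
    reps <- tibble::tibble(replicon_id = ids, strain = s, class = cls,
                           sequence = unname(as.character(dna)))
    gff <- ape::read.gff(file.path(dir, paste0(s, ".gff3")))
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0(s, ".faa")))
    ids <- sub("^ID=([^;]+).*$", "\\1", gff$attributes)
    seqs <- as.character(dna)[as.character(gff$seqid)]
    nt <- substring(seqs, gff$start, gff$end)
    neg <- gff$strand == "-"
    if (any(neg)) nt[neg] <- revcomp(nt[neg])
    gene_rows[[s]] <- tibble::tibble(
      gene_id = ids, strain = s, replicon_id = as.character(gff$seqid),
      start = gff$start, end = gff$end, strand = as.character(gff$strand),
      nt = unname(nt), protein = unname(as.character(aa)[ids])
    )
    rep_rows[[s]] <- reps
  }
  replicons <- dplyr::bind_rows(rep_rows)
  genes <- dplyr::bind_rows(gene_rows)

  truth <- NULL
  tpath <- file.path(dir, "truth.tsv")
  if (file.exists(tpath)) {
    membership <- readr::read_tsv(tpath, show_col_types = FALSE)
    truth <- structure(
      list(membership = membership,
           prevalence = membership |>
             dplyr::count(.data$family_id, name = "prevalence")),
      class = "panel_truth"
    )
    genes <- genes |>
      dplyr::left_join(truth$membership |>
                         dplyr::select("gene_id", "replicon_class"),
                       by = "gene_id") |>
      dplyr::relocate("replicon_class", .after = "replicon_id")
  }
  panel <- structure(list(replicons = replicons, genes = genes),
                     class = "genome_panel")
  list(panel = panel, truth = truth)
}
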