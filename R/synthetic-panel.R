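#' Replicon classes recognised by the panel generator
#'
#' Class labels follow the multi-replicon architecture typical of
#' megaplasmid-bearing lactobacilli: one chromosome, an optional repA-type
#' circular megaplasmid, optional further (e.g. linear) megaplasmids, and
#' small plasmids.
#'
#' @export
replicon_classes <- function() {
  c("chromosome", "repA_megaplasmid", "other_megaplasmid", "small_plasmid")
}

stop_codons  <- c("TAA", "TAG", "TGA")
sense_codons <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Configure a synthetic genome panel
#'
#' Defines the pan-genome structure of a simulated strain panel: a shared
#' core gene set, prevalence-structured accessory families, strain-unique
#' genes, a per-strain replicon plan, and a uniform per-site substitution
#' rate that controls nucleotide divergence between strains' copies of a
#' family.
#'
#' @param n_genomes Number of strains (>= 2).
#' @param n_core Number of core gene families (present in every strain).
#' @param accessory_spec Accessory family structure: a data frame (or tibble)
#'   with columns `prevalence` and `n_families`, or a list of
#'   `c(prevalence, n_families)` pairs. Each prevalence must lie in
#'   `[2, n_genomes - 1]`.
#' @param n_unique_per_genome Number of strain-unique (prevalence-1) families
#'   carried by each strain.
#' @param gene_length Mean gene length in codons (start and stop included).
#'   Individual family lengths are drawn around this mean.
#' @param replicon_plan Named integer vector over [replicon_classes()] giving
#'   the per-strain replicon counts, or a data frame with a `strain` column
#'   plus one column per class for heterogeneous plans. Every strain must
#'   have exactly one chromosome.
#' @param allocation Named list mapping family kind (`core`, `accessory`,
#'   `unique`) to a probability vector over [replicon_classes()]; each family
#'   is allotted one replicon class from its kind's distribution. The default
#'   places most core genes on the chromosome and biases accessory and
#'   unique genes towards the megaplasmid and small plasmids.
#' @param substitution_rate Per-site substitution probability in `[0, 0.3]`
#'   applied independently to each strain's copy of a family.
#' @param spacer_length Length of the random intergenic spacer (nt).
#' @param seed Integer seed; identical seeds give byte-identical panels.
#'
#' @return A `panel_config` list, validated.
#' @seealso [simulate_panel()]
#' @export
panel_config <- function(n_genomes,
                         n_core,
                         accessory_spec = list(),
                         n_unique_per_genome = 0,
                         gene_length = 250,
                         replicon_plan = c(chromosome = 1, repA_megaplasmid = 1,
                                           other_megaplasmid = 0, small_plasmid = 1),
                         allocation = default_allocation(),
                         substitution_rate = 0,
                         spacer_length = 100,
                         seed = 1L) {
  assert_that(n_genomes >= 2, "n_genomes must be >= 2")
  assert_that(n_core >= 0, "n_core must be non-negative")
  assert_that(substitution_rate >= 0 && substitution_rate <= 0.3,
              "substitution_rate must lie in [0, 0.3]")
  assert_that(gene_length >= 20, "gene_length must be >= 20 codons")

  acc <- normalise_accessory_spec(accessory_spec)
  if (nrow(acc) > 0) {
    bad <- acc$prevalence < 2 | acc$prevalence > n_genomes - 1
    assert_that(!any(bad),
                "every accessory prevalence must lie in [2, n_genomes - 1]")
  }

  plan <- normalise_replicon_plan(replicon_plan, n_genomes)
  assert_that(all(plan$chromosome == 1L),
              "each strain must have exactly one chromosome")

  alloc <- normalise_allocation(allocation)

  structure(
    list(n_genomes = as.integer(n_genomes),
         n_core = as.integer(n_core),
         accessory_spec = acc,
         n_unique_per_genome = as.integer(n_unique_per_genome),
         gene_length = gene_length,
         replicon_plan = plan,
         allocation = alloc,
         substitution_rate = substitution_rate,
         spacer_length = as.integer(spacer_length),
         seed = as.integer(seed)),
    class = "panel_config"
  )
}

#' @rdname panel_config
#' @export
default_allocation <- function() {
  list(
    core      = c(chromosome = 0.90, repA_megaplasmid = 0.10,
                  other_megaplasmid = 0, small_plasmid = 0),
    accessory = c(chromosome = 0.35, repA_megaplasmid = 0.45,
                  other_megaplasmid = 0, small_plasmid = 0.20),
    unique    = c(chromosome = 0.30, repA_megaplasmid = 0.40,
                  other_megaplasmid = 0, small_plasmid = 0.30)
  )
}

normalise_accessory_spec <- function(spec) {
  if (is.data.frame(spec)) {
    assert_that(all(c("prevalence", "n_families") %in% names(spec)),
                "accessory_spec needs columns prevalence, n_families")
    tibble::as_tibble(spec[, c("prevalence", "n_families")])
  } else if (is.list(spec) && length(spec) > 0) {
    tibble::tibble(
      prevalence = vapply(spec, function(x) as.integer(x[[1]]), integer(1)),
      n_families = vapply(spec, function(x) as.integer(x[[2]]), integer(1))
    )
  } else {
    tibble::tibble(prevalence = integer(), n_families = integer())
  }
}

normalise_replicon_plan <- function(plan, n_genomes) {
  classes <- replicon_classes()
  if (is.data.frame(plan)) {
    assert_that("strain" %in% names(plan), "per-strain plan needs a strain column")
    for (cl in classes) if (!cl %in% names(plan)) plan[[cl]] <- 0L
    assert_that(nrow(plan) == n_genomes,
                "per-strain plan must have one row per genome")
    out <- tibble::as_tibble(plan[, c("strain", classes)])
  } else {
    counts <- setNames(rep(0L, length(classes)), classes)
    counts[names(plan)] <- as.integer(plan)
    out <- tibble::tibble(strain = strain_ids(n_genomes))
    for (cl in classes) out[[cl]] <- counts[[cl]]
  }
  out
}

normalise_allocation <- function(alloc) {
  classes <- replicon_classes()
  for (kind in c("core", "accessory", "unique")) {
    assert_that(kind %in% names(alloc),
                sprintf("allocation must define '%s'", kind))
    p <- setNames(rep(0, length(classes)), classes)
    p[names(alloc[[kind]])] <- alloc[[kind]]
    assert_that(sum(p) > 0, sprintf("allocation['%s'] sums to zero", kind))
    alloc[[kind]] <- p / sum(p)
  }
  alloc
}

strain_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Point substitutions on a nucleotide sequence
#'
#' Applies independent per-site substitutions at probability `rate`; a
#' substituted site always changes to one of the three other bases, so the
#' expected mismatch fraction against the input equals `rate`.
#'
#' @param seq A single nucleotide sequence (character scalar, A/C/G/T).
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return The mutated sequence, same length as the input.
#' @examples
#' mutate_sequence("ACGTACGT", 0, seed = 1)
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  assert_that(is.character(seq) && length(seq) == 1 && nzchar(seq),
              "seq must be a non-empty nucleotide string")
  assert_that(rate >= 0 && rate <= 1, "rate must lie in [0, 1]")
  if (rate == 0) return(seq)
  with_seed(seed, {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(bases)) < rate)
    if (length(hit) > 0) {
      alphabet <- c("A", "C", "G", "T")
      repl <- vapply(bases[hit], function(b) {
        sample(setdiff(alphabet, b), 1L)
      }, character(1), USE.NAMES = FALSE)
      bases[hit] <- repl
    }
    paste(bases, collapse = "")
  })
}

# Mutate a coding sequence while keeping it a clean ORF: internal codons
# that become stops are reverted to the ancestral codon and the terminal
# stop codon is restored, so all copies of a family translate to
# equal-length proteins.
mutate_cds <- function(nt, rate) {
  if (rate == 0) return(nt)
  mut <- mutate_sequence(nt, rate)
  n_codon <- nchar(mut) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(mut, starts, starts + 2L)
  anc    <- substring(nt, starts, starts + 2L)
  internal_stop <- seq_len(n_codon - 1L)[codons[-n_codon] %in% stop_codons]
  codons[internal_stop] <- anc[internal_stop]
  codons[n_codon] <- anc[n_codon]
  paste(codons, collapse = "")
}

random_cds <- function(n_codons) {
  body <- sample(sense_codons, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome panel with known pan-genome structure
#'
#' Generates `n_genomes` strains carrying the configured core, accessory and
#' strain-unique gene families. Each family descends star-wise from one
#' ancestral coding sequence: every strain's copy is mutated independently at
#' `substitution_rate`, so the expected pairwise identity between two copies
#' is approximately `(1 - rate)^2` per site. Genes are allotted to replicon
#' classes by the allocation rule and concatenated (with random spacers) into
#' replicon sequences.
#'
#' @param config A [panel_config()].
#' @return A list with components `panel` (class `genome_panel`: tibbles
#'   `replicons` and `genes`) and `truth` (class `panel_truth`: tibbles
#'   `membership` and `prevalence`), the ground truth for every gene.
#' @examples
#' sim <- simulate_panel(panel_config(n_genomes = 3, n_core = 5, seed = 42))
#' sim$truth$prevalence
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  strains <- config$replicon_plan$strain
  classes <- replicon_classes()

  # --- family table: id, kind, prevalence, members -------------------------
  fams <- list()
  if (config$n_core > 0) {
    fams$core <- tibble::tibble(
      family_id = sprintf("core%04d", seq_len(config$n_core)),
      kind = "core",
      members = replicate(config$n_core, strains, simplify = FALSE)
    )
  }
  if (nrow(config$accessory_spec) > 0) {
    acc <- config$accessory_spec
    idx <- 0L
    rows <- purrr::pmap(acc, function(prevalence, n_families) {
      tibble::tibble(
        family_id = sprintf("acc_p%02d_%04d", prevalence, seq_len(n_families)),
        kind = "accessory",
        members = replicate(n_families, sort(sample(strains, prevalence)),
                            simplify = FALSE)
      )
    })
    fams$accessory <- dplyr::bind_rows(rows)
  }
  if (config$n_unique_per_genome > 0) {
    fams$unique <- dplyr::bind_rows(lapply(strains, function(s) {
      tibble::tibble(
        family_id = sprintf("uniq_%s_%03d", s, seq_len(config$n_unique_per_genome)),
        kind = "unique",
        members = replicate(config$n_unique_per_genome, s, simplify = FALSE)
      )
    }))
  }
  fam <- dplyr::bind_rows(fams)
  assert_that(nrow(fam) > 0, "panel would contain no gene families")

  # family lengths (codons), replicon class, ancestral sequence
  len_codons <- pmax(25L, round(rnorm(nrow(fam), config$gene_length,
                                      config$gene_length / 5)))
  fam$length_codons <- as.integer(len_codons)
  fam$class <- vapply(fam$kind, function(k) {
    p <- config$allocation[[k]]
    sample(classes, 1L, prob = p)
  }, character(1))
  fam$ancestral <- vapply(fam$length_codons, random_cds, character(1))
  # one ancestral intergenic spacer per family and a fixed strand: strains
  # are colinear (no rearrangements), so intergenic sequence is homologous
  # across strains and whole-genome fragment alignment behaves like real
  # conspecific genomes
  fam$spacer <- replicate(nrow(fam), random_spacer(config$spacer_length))
  fam$strand <- sample(c("+", "-"), nrow(fam), replace = TRUE)

  # feasibility: every carrying strain must own a replicon of the class
  plan <- config$replicon_plan
  for (i in seq_len(nrow(fam))) {
    cl <- fam$class[[i]]
    have <- plan[[cl]][match(fam$members[[i]], plan$strain)]
    if (any(have == 0L)) {
      abort(sprintf(
        "configuration error: family %s allotted to class '%s' but strain %s has no such replicon",
        fam$family_id[[i]], cl, fam$members[[i]][which(have == 0L)[1]]))
    }
  }

  # --- per-strain gene copies ---------------------------------------------
  membership <- fam |>
    dplyr::select("family_id", "kind", "class", "ancestral", "spacer",
                  "strand") |>
    dplyr::mutate(members = fam$members) |>
    tidyr::unnest_longer("members") |>
    dplyr::rename(strain = "members")

  membership$nt <- vapply(seq_len(nrow(membership)), function(i) {
    mutate_cds(membership$ancestral[[i]], config$substitution_rate)
  }, character(1))
  membership$spacer_nt <- vapply(seq_len(nrow(membership)), function(i) {
    mutate_sequence(membership$spacer[[i]], config$substitution_rate)
  }, character(1))

  # --- replicon assembly ---------------------------------------------------
  replicon_rows <- list()
  gene_rows <- list()
  for (s in strains) {
    srow <- plan[plan$strain == s, ]
    # replicon ids for this strain
    reps <- dplyr::bind_rows(lapply(classes, function(cl) {
      k <- srow[[cl]]
      if (k == 0L) return(NULL)
      tag <- c(chromosome = "chr", repA_megaplasmid = "mpA",
               other_megaplasmid = "mpO", small_plasmid = "pl")[[cl]]
      tibble::tibble(replicon_id = sprintf("%s_%s%d", s, tag, seq_len(k)),
                     strain = s, class = cl)
    }))

    # colinear layout: genes sorted by family id within each class, then
    # distributed round-robin over that class's replicons, so shared
    # families occupy the same relative positions in every strain
    sg <- membership[membership$strain == s, ]
    sg <- sg[order(sg$family_id), , drop = FALSE]
    sg$replicon_id <- NA_character_
    for (cl in unique(sg$class)) {
      ids <- reps$replicon_id[reps$class == cl]
      sel <- which(sg$class == cl)
      sg$replicon_id[sel] <- ids[((seq_along(sel) - 1L) %% length(ids)) + 1L]
    }

    # each gene is preceded by its family's (strain-mutated) spacer
    for (r in reps$replicon_id) {
      rg <- sg[sg$replicon_id == r, , drop = FALSE]
      pieces <- character(0)
      pos <- 0L
      if (nrow(rg) > 0) {
        rg$start <- NA_integer_
        rg$end <- NA_integer_
        for (j in seq_len(nrow(rg))) {
          pieces <- c(pieces, rg$spacer_nt[[j]])
          pos <- pos + nchar(rg$spacer_nt[[j]])
          g <- rg$nt[[j]]
          placed <- if (rg$strand[[j]] == "-") revcomp(g) else g
          pieces <- c(pieces, placed)
          rg$start[[j]] <- pos + 1L
          pos <- pos + nchar(g)
          rg$end[[j]] <- pos
        }
      } else {
        pieces <- random_spacer(config$spacer_length)
      }
      replicon_rows[[r]] <- tibble::tibble(
        replicon_id = r, strain = s,
        class = reps$class[reps$replicon_id == r],
        sequence = paste(pieces, collapse = "")
      )
      if (nrow(rg) > 0) gene_rows[[r]] <- rg
    }
  }

  replicons <- dplyr::bind_rows(replicon_rows)
  genes <- dplyr::bind_rows(gene_rows)

  # locus-tag style ids in replicon order
  genes <- genes |>
    dplyr::arrange(.data$strain, .data$replicon_id, .data$start) |>
    dplyr::group_by(.data$strain) |>
    dplyr::mutate(gene_id = sprintf("%s_%05d", .data$strain, dplyr::row_number())) |>
    dplyr::ungroup()
  genes$protein <- translate_cds(genes$nt)

  panel <- structure(
    list(replicons = replicons,
         genes = genes |>
           dplyr::select("gene_id", "strain", "replicon_id",
                         replicon_class = "class", "start", "end", "strand",
                         "nt", "protein")),
    class = "genome_panel"
  )
  truth <- structure(
    list(membership = genes |>
           dplyr::select("gene_id", "strain", "replicon_id",
                         replicon_class = "class", "family_id"),
         prevalence = membership |>
           dplyr::count(.data$family_id, name = "prevalence") |>
           dplyr::left_join(fam |> dplyr::select("family_id", "kind", "class"),
                            by = "family_id")),
    class = "panel_truth"
  )
  list(panel = panel, truth = truth)
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("<genome_panel> %d strains, %d replicons, %d genes\n",
              length(unique(x$replicons$strain)), nrow(x$replicons),
              nrow(x$genes)))
  invisible(x)
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf("<panel_truth> %d genes in %d families\n",
              nrow(x$membership), nrow(x$prevalence)))
  invisible(x)
}
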