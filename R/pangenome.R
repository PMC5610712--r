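# Core/pan/new-gene rarefaction, Heaps-law openness, leave-one-out core,
# and per-replicon gene-count summaries.

as_pa <- function(matrix) {
  assert_that(is.matrix(matrix) && !is.null(rownames(matrix)) &&
                !is.null(colnames(matrix)),
              "expected a presence/absence matrix with strain rownames")
  assert_that(all(matrix %in% c(0L, 1L)), "matrix entries must be 0/1")
  matrix
}

#' Core genome of a strain subset
#'
#' Families (and singleton columns) present in every strain of the subset.
#'
#' @param matrix A `pa_matrix` (or any binary strain-by-family matrix).
#' @param strains Strain subset; defaults to all rows.
#' @return Character vector of column ids present in every chosen strain.
#' @export
core_genome <- function(matrix, strains = rownames(matrix)) {
  matrix <- as_pa(matrix)
  assert_that(length(strains) > 0, "strain subset is empty")
  unknown <- setdiff(strains, rownames(matrix))
  assert_that(length(unknown) == 0,
              sprintf("unknown strain: %s", unknown[1]))
  sub <- matrix[strains, , drop = FALSE]
  colnames(sub)[colSums(sub) == length(strains)]
}

#' Permutation rarefaction of core, pan and new gene counts
#'
#' Starting from one genome and adding genomes one at a time in uniformly
#' random orders, records at each panel size k the number of families
#' present in all k genomes (core), present in at least one (pan), and
#' newly contributed by the k-th genome (new). Medians across permutations
#' summarise each curve; the per-permutation counts are kept so the
#' variation can be plotted.
#'
#' @param matrix Binary strain-by-family matrix (families plus singleton
#'   columns).
#' @param n_permutations Number of random genome orders (default 1000).
#' @param seed Integer seed making the permutation set reproducible.
#' @param orders Optional list of strain-id orderings that overrides random
#'   permutation (e.g. the exhaustive set of orders for a small panel).
#' @return A `rarefaction` object with tibbles `counts` (permutation, k,
#'   core, pan, new) and `medians` (k, core, pan, new).
#' @export
rarefaction <- function(matrix, n_permutations = 1000, seed = NULL,
                        orders = NULL) {
  matrix <- as_pa(matrix)
  n <- nrow(matrix)
  assert_that(n >= 2, "rarefaction needs at least 2 strains")
  if (is.null(orders)) {
    assert_that(n_permutations >= 1, "n_permutations must be >= 1")
    orders <- with_seed(seed, replicate(n_permutations,
                                        sample(rownames(matrix)),
                                        simplify = FALSE))
  }
  counts <- purrr::imap(orders, function(ord, p) {
    sub <- matrix[ord, , drop = FALSE]
    cum <- apply(sub, 2, cumsum)
    k <- seq_len(n)
    pan <- rowSums(cum > 0)
    core <- rowSums(cum == k)
    tibble::tibble(permutation = p, k = k, core = core, pan = pan,
                   new = c(pan[1], diff(pan)))
  }) |>
    dplyr::bind_rows()
  medians <- counts |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(core = median(.data$core), pan = median(.data$pan),
                     new = median(.data$new), .groups = "drop")
  structure(list(counts = counts, medians = medians,
                 n_permutations = length(orders), seed = seed),
            class = "rarefaction")
}

#' @export
print.rarefaction <- function(x, ...) {
  n <- max(x$medians$k)
  cat(sprintf(
    "<rarefaction> %d genomes, %d permutations; median core(N) = %g, pan(N) = %g\n",
    n, x$n_permutations, x$medians$core[n], x$medians$pan[n]))
  invisible(x)
}

#' @method tidy rarefaction
#' @export
tidy.rarefaction <- function(x, ...) {
  tidyr::pivot_longer(x$medians, c("core", "pan", "new"),
                      names_to = "curve", values_to = "median")
}

#' Fit the Heaps-law openness exponent to the new-gene curve
#'
#' Ordinary least squares of `log10(new)` on `log10(k)` over `fit_range`;
#' the openness exponent is `alpha = -slope` and the pan-genome is called
#' open when `alpha < 1` (new genes keep accruing as genomes are added).
#' k = 1 is excluded by default: the first genome's full gene complement is
#' not a discovery increment.
#'
#' @param new_medians A `rarefaction` object, or a tibble/data.frame with
#'   columns `k` and `new` (median new genes at each k).
#' @param fit_range Length-2 integer range of k values to fit (default
#'   `c(2, N)`).
#' @return A `heaps_fit` object with `alpha`, `kappa`, `slope`,
#'   `fit_range` and the openness call; see [tidy.heaps_fit()] and
#'   [glance.heaps_fit()].
#' @export
fit_heaps <- function(new_medians, fit_range = NULL) {
  if (inherits(new_medians, "rarefaction")) new_medians <- new_medians$medians
  assert_that(all(c("k", "new") %in% names(new_medians)),
              "expected columns k and new")
  if (is.null(fit_range)) fit_range <- c(2L, max(new_medians$k))
  pts <- new_medians[new_medians$k >= fit_range[1] &
                       new_medians$k <= fit_range[2], c("k", "new")]
  assert_that(nrow(pts) >= 3, "need at least 3 points in fit_range")
  if (any(pts$new <= 0)) {
    abort(paste("non-positive new-gene median inside fit_range;",
                "narrow fit_range to exclude exhausted k values"))
  }
  fit <- lm(log10(new) ~ log10(k), data = pts)
  slope <- unname(coef(fit)[2])
  alpha <- -slope
  structure(list(alpha = alpha,
                 kappa = 10^unname(coef(fit)[1]),
                 slope = slope,
                 # strict alpha < 1, up to numerical noise at the boundary
                 open = alpha < 1 - 1e-9,
                 fit_range = fit_range,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = nrow(pts),
                 data = tibble::as_tibble(pts),
                 model = fit),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("<heaps_fit> alpha = %.3f (kappa = %.1f), k in [%d, %d]: %s pan-genome\n",
              x$alpha, x$kappa, x$fit_range[1], x$fit_range[2],
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Tidy and summarise a Heaps-law fit
#'
#' @param x A `heaps_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted term; `glance()`: a one-row tibble
#'   with `alpha`, `kappa`, `slope`, `open`, `r_squared`, `n_points`.
#' @method tidy heaps_fit
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble::tibble(term = c("log10_kappa", "slope"),
                 estimate = c(log10(x$kappa), x$slope))
}

#' @rdname tidy.heaps_fit
#' @method glance heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, kappa = x$kappa, slope = x$slope,
                 open = x$open, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' Leave-one-out core-genome sizes
#'
#' Recomputes the core-genome size after excluding each strain in turn;
#' a strain whose exclusion inflates the core is missing families that are
#' otherwise universal (e.g. a strain that lost its megaplasmid).
#'
#' @param matrix Binary strain-by-family matrix.
#' @return Tibble with columns `excluded_strain`, `core_size`.
#' @export
leave_one_out_core <- function(matrix) {
  matrix <- as_pa(matrix)
  assert_that(nrow(matrix) >= 3, "leave-one-out needs at least 3 strains")
  tibble::tibble(
    excluded_strain = rownames(matrix),
    core_size = vapply(rownames(matrix), function(s) {
      length(core_genome(matrix, setdiff(rownames(matrix), s)))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Per-replicon-class gene-count summary
#'
#' Summarises per-strain gene totals within each replicon class by the
#' median and first/third quartiles (linear-interpolation quantiles, so
#' fractional values such as 47.5 arise naturally). Strains lacking a
#' replicon class contribute nothing to that class's distribution.
#'
#' @param genes Tibble with columns `strain` and `replicon_class` (one row
#'   per gene), e.g. `panel$genes` or annotated gene models.
#' @return Tibble with `replicon_class`, `n_strains`, `q1`, `median`, `q3`.
#' @export
replicon_gene_summary <- function(genes) {
  assert_that(all(c("strain", "replicon_class") %in% names(genes)),
              "genes needs strain and replicon_class columns")
  assert_that(!any(is.na(genes$replicon_class)),
              "every gene must carry a replicon class")
  genes |>
    dplyr::count(.data$strain, .data$replicon_class) |>
    dplyr::group_by(.data$replicon_class) |>
    dplyr::summarise(
      n_strains = dplyr::n(),
      q1 = unname(quantile(.data$n, 0.25, type = 7)),
      median = unname(median(.data$n)),
      q3 = unname(quantile(.data$n, 0.75, type = 7)),
      .groups = "drop"
    )
}
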