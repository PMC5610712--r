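# Independent oracles used to check package computations. These are
# deliberately naive implementations (explicit loops, no shared code with
# the package internals).

# Affine-gap Smith-Waterman (Gotoh) with traceback. Gap of length L costs
# open + L * ext. Returns raw score plus identity/length/coverage of the
# best local alignment.
sw_oracle <- function(q, s, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consume subject)
  F_ <- matrix(-Inf, n + 1, m + 1) # gap in subject (consume query)
  ptr <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up(F), 3 left(E)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      diag <- H[i - 1, j - 1] + sub[qc[i - 1], sc[j - 1]]
      H[i, j] <- max(0, diag, E[i, j], F_[i, j])
      ptr[i, j] <- if (H[i, j] == 0) 0L else if (H[i, j] == diag) 1L else
        if (H[i, j] == F_[i, j]) 2L else 3L
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best == 0) {
    return(list(score = 0, matches = 0L, alen = 0L, q_span = 0L))
  }
  # greedy traceback through H (sufficient for the statistics at the
  # thresholds the tests use)
  i <- bi; j <- bj; matches <- 0L; alen <- 0L; q_used <- 0L
  while (i > 1 && j > 1 && H[i, j] > 0) {
    move <- ptr[i, j]
    if (move == 1L) {
      matches <- matches + (qc[i - 1] == sc[j - 1])
      alen <- alen + 1L; q_used <- q_used + 1L
      i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      alen <- alen + 1L; q_used <- q_used + 1L; i <- i - 1L
    } else if (move == 3L) {
      alen <- alen + 1L; j <- j - 1L
    } else break
  }
  list(score = best, matches = matches, alen = alen, q_span = q_used)
}

oracle_bit <- function(raw) (0.267 * raw - log(0.041)) / log(2)

# random protein / dna helpers
random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance by explicit per-character loop.
hamming_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  d <- 0L
  for (k in seq_along(av)) if (toupper(av[k]) != toupper(bv[k])) d <- d + 1L
  d
}

# Exhaustive rarefaction over an explicit list of strain orders using set
# operations on column-name sets.
rarefaction_oracle <- function(mat, orders) {
  fam_sets <- lapply(rownames(mat), function(s) colnames(mat)[mat[s, ] == 1])
  names(fam_sets) <- rownames(mat)
  out <- list()
  for (p in seq_along(orders)) {
    ord <- orders[[p]]
    pan_set <- character(0); core_set <- NULL
    for (k in seq_along(ord)) {
      fs <- fam_sets[[ord[k]]]
      new_k <- length(setdiff(fs, pan_set))
      pan_set <- union(pan_set, fs)
      core_set <- if (is.null(core_set)) fs else intersect(core_set, fs)
      out[[length(out) + 1]] <- data.frame(
        permutation = p, k = k, core = length(core_set),
        pan = length(pan_set), new = new_k)
    }
  }
  do.call(rbind, out)
}

# Naive Markov clustering (independent of the package's implementation):
# explicit elementwise loops over the full node set.
mcl_oracle <- function(nodes, edges, inflation, iters = 200) {
  nodes <- sort(nodes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- edges$w[r]
    A[edges$to[r], edges$from[r]] <- edges$w[r]
  }
  for (i in seq_len(n)) A[i, i] <- max(A[, i])
  normalise <- function(M) {
    for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
    M
  }
  M <- normalise(A)
  for (t in seq_len(iters)) {
    M <- normalise(normalise(M %*% M)^inflation)
    M[M < 1e-14] <- 0
    M <- normalise(M)
  }
  # clusters: rows of attractors
  att <- which(diag(M) > 1e-6)
  groups <- list()
  for (a in att) {
    memb <- nodes[M[a, ] > 1e-6]
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (length(intersect(groups[[g]], memb)) > 0) {
        groups[[g]] <- union(groups[[g]], memb); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- memb
  }
  lapply(groups, sort)
}

# Brute-force complete-linkage agglomeration on the rows of a matrix:
# returns the sequence of merge heights.
complete_linkage_oracle <- function(m) {
  clusters <- as.list(rownames(m))
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  heights
}

# canonical partition signature: sorted "member|member" strings
partition_signature <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                     character(1))))
}
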