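# Shared fixtures, all generated in code under fixed seeds.

DNA <- c("A", "C", "G", "T")

fixture_motif <- function(seed = 42, len = 60, n = 12, divergence = 0.08) {
  withr::with_seed(seed, {
    cons <- paste(sample(DNA, len, replace = TRUE), collapse = "")
    aln <- vapply(seq_len(n), function(i) {
      tnpbtools:::mutate_seq(cons, divergence, DNA)
    }, character(1))
    names(aln) <- sprintf("seed%02d", seq_len(n))
    ss <- paste(c(rep("<", 10), rep(".", len - 20), rep(">", 10)),
                collapse = "")
    list(consensus = cons, alignment = aln, structure = ss)
  })
}

# Small profile DBs for role annotation: each profile from mutated copies
# of a random consensus.
fixture_profile_db <- function(ids, seed, len = 80, n_members = 8,
                               divergence = 0.1) {
  withr::with_seed(seed, {
    db <- lapply(ids, function(id) {
      cons <- tnpbtools:::rand_protein(1, len)
      members <- vapply(seq_len(n_members), function(i) {
        tnpbtools:::mutate_seq(cons, divergence, tnpbtools:::AA_ALPHABET)
      }, character(1))
      profile_from_seqs(id, members)
    })
    names(db) <- ids
    db
  })
}

# A locus hosting a transcript with the canonical segment layout:
# 37-nt 5' flanking, 73-nt RNA motif, 64-nt 3' flanking, 10-nt tail.
fixture_rerna_locus <- function(seed = 7, pad5 = 120, pad3 = 80) {
  withr::with_seed(seed, {
    tstart <- pad5
    list(
      locus = paste(sample(DNA, pad5 + 184 + pad3, replace = TRUE),
                    collapse = ""),
      transcript = c(tstart, tstart + 184L),
      motif_start = tstart + 37L,
      motif_end = tstart + 37L + 73L,
      tail_start = tstart + 37L + 73L + 64L,
      orf_end = tstart - 13L
    )
  })
}

# Independent adjusted Rand index (contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Reference MCL, independently coded with explicit elementwise loops, for
# cross-checking the package implementation on small graphs.
reference_mcl <- function(A, inflation = 2, prune = 1e-5, tol = 1e-6,
                          max_iter = 100) {
  n <- nrow(A)
  for (i in seq_len(n)) {
    if (A[i, i] == 0) {
      mx <- 0
      for (j in seq_len(n)) if (A[i, j] > mx) mx <- A[i, j]
      A[i, i] <- if (mx > 0) mx else 1
    }
  }
  normalise <- function(M) {
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s > 0) M[, j] <- M[, j] / s
    }
    M
  }
  M <- normalise(A)
  for (it in seq_len(max_iter)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      E[i, j] <- sum(M[i, ] * M[, j])
    }
    E <- E^inflation
    E[E < prune] <- 0
    E <- normalise(E)
    if (max(abs(E - M)) < tol) {
      M <- E
      break
    }
    M <- E
  }
  # clusters: merge attractor supports that overlap
  eps <- 1e-6
  attr_rows <- which(diag(M) > eps)
  supports <- lapply(attr_rows, function(a) which(M[a, ] > eps))
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  for (k in seq_along(supports)) {
    hit <- unique(stats::na.omit(labels[supports[[k]]]))
    if (length(hit) == 0) {
      next_label <- next_label + 1L
      labels[supports[[k]]] <- next_label
    } else {
      keepl <- min(hit)
      labels[supports[[k]]] <- keepl
      labels[labels %in% hit] <- keepl
    }
  }
  for (i in which(is.na(labels))) {
    next_label <- next_label + 1L
    labels[i] <- next_label
  }
  labels
}

# Brute-force defense island enumeration: test every (i, j) gene run
# against the definition directly.
brute_force_islands <- function(roles) {
  n <- length(roles)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      run <- roles[i:j]
      if (any(run == "housekeeping")) next
      if (!any(run == "defense")) next
      left_ok <- i == 1 || roles[i - 1] == "housekeeping"
      right_ok <- j == n || roles[j + 1] == "housekeeping"
      if (left_ok && right_ok) out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}
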