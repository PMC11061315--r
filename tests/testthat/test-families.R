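# Independent top-down local-alignment scorer (Gotoh recursion, memoised)
# used as an oracle on tiny instances.
sw_oracle <- function(a, b, go = 10, ge = 1) {
  B <- tnpbtools:::blosum62()
  A <- strsplit(a, "")[[1]]; C <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(C)
  H <- matrix(NA_real_, n + 1, m + 1)
  E <- matrix(NA_real_, n + 1, m + 1)  # gap in b
  F_ <- matrix(NA_real_, n + 1, m + 1) # gap in a
  H[1, ] <- 0; H[, 1] <- 0
  E[1, ] <- -Inf; E[, 1] <- -Inf
  F_[1, ] <- -Inf; F_[, 1] <- -Inf
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - go - ge, E[i - 1, j] - ge)
      F_[i, j] <- max(H[i, j - 1] - go - ge, F_[i, j - 1] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + B[A[i - 1], C[j - 1]],
                     E[i, j], F_[i, j])
    }
  }
  max(H)
}

partition_of <- function(clusters) {
  split(clusters$protein_id, clusters$cluster_id) |>
    lapply(sort) |>
    unname() |>
    (\(x) x[order(vapply(x, `[`, "", 1))])()
}

test_that("pairwise alignment statistics behave as defined", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  self <- align_pair(s, s)
  expect_equal(self$identity, 1)
  expect_equal(self$coverage, 1)
  expect_equal(self$similarity, 1)

  # DP score equals an independently coded Gotoh recursion on toy pairs
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- tnpbtools:::rand_protein(1, 8)
      b <- tnpbtools:::rand_protein(1, 8)
      got <- align_pair(a, b)$score
      expect_equal(got, sw_oracle(a, b))
    }
  })

  # unrelated random 200-aa pairs rarely reach coverage 0.6
  withr::with_seed(32, {
    covs <- vapply(1:20, function(i) {
      align_pair(tnpbtools:::rand_protein(1, 200),
                 tnpbtools:::rand_protein(1, 200))$coverage
    }, numeric(1))
    expect_true(all(covs < 0.6))
  })

  expect_error(align_pair("", "AA"), "non-empty")
})

test_that("greedy clustering recovers planted families", {
  f0 <- generate_families(family_spec(n_families = 3,
                                      members_per_family = 4,
                                      divergence = 0, seed = 51))
  prots0 <- dplyr::rename(f0$proteins[, c("protein_id", "seq")])
  cl0 <- greedy_cluster(prots0)
  truth0 <- f0$proteins$family[match(cl0$protein_id,
                                     f0$proteins$protein_id)]
  expect_equal(adjusted_rand(cl0$cluster_id, truth0), 1)

  f <- generate_families(family_spec(n_families = 4,
                                     members_per_family = 5,
                                     divergence = 0.2, seed = 52))
  cl <- greedy_cluster(f$proteins[, c("protein_id", "seq")])
  truth <- f$proteins$family[match(cl$protein_id, f$proteins$protein_id)]
  expect_gte(adjusted_rand(cl$cluster_id, truth), 0.9)

  # a singleton outlier stays a singleton
  outlier <- withr::with_seed(53, tnpbtools:::rand_protein(1, 150))
  cl2 <- greedy_cluster(dplyr::bind_rows(
    f0$proteins[, c("protein_id", "seq")],
    tibble::tibble(protein_id = "lone", seq = outlier)))
  lone_cl <- cl2$cluster_id[cl2$protein_id == "lone"]
  expect_equal(sum(cl2$cluster_id == lone_cl), 1)
})

test_that("cluster profiles match manual counts", {
  one <- tibble::tibble(protein_id = "p1", seq = "MKTAYIAK")
  prof1 <- build_cluster_profile(one)
  expect_equal(prof1$consensus, "MKTAYIAK")

  members <- tibble::tibble(protein_id = sprintf("p%d", 1:5),
                            seq = c("MKTAY", "MKTAY", "MKTAW", "MKTAY",
                                    "AKTAY"))
  prof <- build_cluster_profile(members)
  # column 1: 4 M + 1 A, Laplace pseudocount 1 over the 20-letter alphabet
  expect_equal(prof$pfm["M", 1], (4 + 1) / (5 + 20), ignore_attr = TRUE)
  expect_equal(prof$pfm["A", 1], (1 + 1) / (5 + 20), ignore_attr = TRUE)
  expect_equal(prof$pfm["W", 5], (1 + 1) / (5 + 20), ignore_attr = TRUE)
  expect_true(all(abs(colSums(prof$pfm) - 1) < 1e-9))
})

test_that("the similarity graph is symmetric with near-unit self-affinity", {
  f <- generate_families(family_spec(n_families = 3,
                                     members_per_family = 4,
                                     divergence = 0.15, seed = 61))
  prots <- f$proteins[, c("protein_id", "seq")]
  cl <- greedy_cluster(prots)
  g <- similarity_graph(prots, cl, seed = 62)
  # symmetric by construction: adjacency equals its transpose
  A <- matrix(0, nrow(prots), nrow(prots),
              dimnames = list(prots$protein_id, prots$protein_id))
  for (k in seq_len(nrow(g$edges))) {
    A[g$edges$from[k], g$edges$to[k]] <- g$edges$weight[k]
    A[g$edges$to[k], g$edges$from[k]] <- g$edges$weight[k]
  }
  expect_equal(max(abs(A - t(A))), 0)
  expect_true(all(g$edges$weight >= 0 & g$edges$weight <= 1))
  # within-family edges sit near 1
  fam <- f$proteins$family[match(g$edges$from, f$proteins$protein_id)] ==
    f$proteins$family[match(g$edges$to, f$proteins$protein_id)]
  expect_gte(min(g$edges$weight[fam]), 0.8)
})

test_that("MCL separates disconnected cliques and handles trivial graphs", {
  A <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1
  diag(A) <- 0
  res <- mcl(A)
  expect_true(res$converged)
  p <- partition_of(res$clusters)
  expect_equal(p, list(sort(letters[1:4]), sort(letters[5:8])))

  B <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  B["a", "b"] <- B["b", "a"] <- 1
  expect_equal(length(partition_of(mcl(B)$clusters)), 1)
})

test_that("MCL matches an independently coded reference on random graphs", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      A <- matrix(0, n, n)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (runif(1) < 0.4) A[i, j] <- A[j, i] <- runif(1)
      }
      dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
      got <- mcl(A)
      labels_ref <- reference_mcl(A)
      got_labels <- got$clusters$cluster_id[
        match(paste0("n", 1:n), got$clusters$protein_id)]
      canon <- function(l) unname(lapply(
        split(seq_along(l), l), identity)[order(
          vapply(split(seq_along(l), l), min, 1))])
      expect_equal(canon(got_labels), canon(labels_ref))
    }
  })
})

test_that("MCL iterations keep columns stochastic", {
  # re-run the normalization chain manually to assert the invariant
  withr::with_seed(72, {
    n <- 10
    A <- matrix(runif(n * n) * (matrix(runif(n * n), n) < 0.3), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- apply(A, 1, max)
    cs <- colSums(A); cs[cs == 0] <- 1
    M <- sweep(A, 2, cs, "/")
    for (it in 1:10) {
      M <- M %*% M
      M <- M^2
      M[M < 1e-5] <- 0
      cs <- colSums(M); cs[cs == 0] <- 1
      M <- sweep(M, 2, cs, "/")
      expect_true(all(abs(colSums(M) - 1) < 1e-9))
    }
  })
})

test_that("two-step clustering recovers families at divergence 0.3", {
  f <- generate_families(family_spec(n_families = 4,
                                     members_per_family = 5,
                                     consensus_length = 150,
                                     divergence = 0.3, seed = 81))
  res <- two_step_cluster(f$proteins[, c("protein_id", "seq")], seed = 82)
  truth <- f$proteins$family[match(res$clusters$protein_id,
                                   f$proteins$protein_id)]
  expect_gte(adjusted_rand(res$clusters$cluster_id, truth), 0.9)
  # every protein lands in exactly one final cluster
  expect_setequal(res$clusters$protein_id, f$proteins$protein_id)
  expect_equal(anyDuplicated(res$clusters$protein_id), 0)
})

test_that("dedupe keeps one representative per redundancy group", {
  base <- withr::with_seed(91, tnpbtools:::rand_protein(1, 100))
  near <- withr::with_seed(92, tnpbtools:::mutate_seq(
    base, 0.05, tnpbtools:::AA_ALPHABET))
  prots <- tibble::tibble(protein_id = c("a", "b", "c"),
                          seq = c(base, base, near))
  kept <- dedupe(prots)
  expect_equal(nrow(kept), 1)
  # verify the planted pair really is >= 0.9 identical
  expect_gte(align_pair(base, near)$identity, 0.9)

  distinct <- generate_families(family_spec(n_families = 4,
                                            members_per_family = 1,
                                            divergence = 0, seed = 93))
  kept2 <- dedupe(distinct$proteins[, c("protein_id", "seq")])
  expect_equal(nrow(kept2), 4)
})

test_that("taxonomy assignment follows the agreement and cross-check rules", {
  lin <- function(sp, gen = "G1") sprintf(
    "d__Bacteria;p__P1;c__C1;o__O1;f__F1;g__%s;s__%s", gen, sp)
  ph <- tibble::tibble(
    contig = "c1", protein_id = sprintf("p%d", 1:10),
    lineage = lin(rep("S1", 10)), identity = 0.8, coverage = 0.9)
  ch <- tibble::tibble(contig = "c1", lineage = lin("S1"))
  res <- assign_taxonomy(ph, ch)
  expect_equal(res$status, "assigned")
  expect_equal(res$assigned_rank, "species")
  expect_equal(res$label, "S1")

  # 6/10 at species S1 but 8/10 at genus G1: genus wins
  ph2 <- tibble::tibble(
    contig = "c1", protein_id = sprintf("p%d", 1:10),
    lineage = c(rep(lin("S1"), 6), rep(lin("S2"), 2),
                rep(lin("S3", gen = "G2"), 2)),
    identity = 0.8, coverage = 0.9)
  res2 <- assign_taxonomy(ph2, tibble::tibble(contig = "c1",
                                              lineage = lin("S1")))
  expect_equal(res2$assigned_rank, "genus")
  expect_equal(res2$label, "G1")

  # protein consensus disagrees with the nucleotide method: undetermined
  res3 <- assign_taxonomy(ph, tibble::tibble(
    contig = "c1", lineage = lin("S9", gen = "G9")))
  expect_equal(res3$status, "undetermined")

  # low-identity hits are excluded; zero annotated proteins: undetermined
  ph4 <- dplyr::mutate(ph, identity = 0.2)
  expect_equal(assign_taxonomy(ph4, ch)$status, "undetermined")
})

test_that("co-occurrence fractions mirror planted adjacency", {
  hits <- tibble::tibble(hit_id = sprintf("h%03d", 1:100), motif = "rna1")
  # 64 of 100 hits have a family member in their window
  windows <- tibble::tibble(
    hit_id = rep(sprintf("h%03d", 1:100), each = 2),
    gene_id = c(rbind(sprintf("gA%03d", 1:100), sprintf("gB%03d", 1:100))),
    side = "upstream", rank = 1L, distance = 10L)
  clusters <- tibble::tibble(
    cluster_id = "fam_001",
    protein_id = sprintf("gA%03d", 1:64))
  tab <- cooccurrence(hits, windows, clusters)
  expect_equal(tab$fraction, 0.64)
  expect_equal(tab$n_adjacent, 64L)
  expect_equal(tab$n_hits, 100L)

  # no family members anywhere: no co-occurrence rows above zero
  none <- cooccurrence(hits, windows,
                       tibble::tibble(cluster_id = character(),
                                      protein_id = character()))
  expect_equal(nrow(none), 0)
})

test_that("representative selection caps members per species", {
  mk <- function(n, sp) tibble::tibble(
    cluster_id = "fam_001", protein_id = sprintf("%s_p%02d", sp, 1:n))
  prots <- function(cl) tibble::tibble(
    protein_id = cl$protein_id,
    seq = strrep("A", 100 + seq_len(nrow(cl))))
  tax <- function(cl, sp) tibble::tibble(protein_id = cl$protein_id,
                                         species = sp)
  ten <- mk(10, "s1")
  expect_equal(nrow(select_representatives(ten, tax(ten, "s1"),
                                           prots(ten))), 6)
  three <- mk(3, "s1")
  expect_equal(nrow(select_representatives(three, tax(three, "s1"),
                                           prots(three))), 3)
  two_sp <- dplyr::bind_rows(mk(8, "s1"), mk(8, "s2"))
  sel <- select_representatives(
    two_sp, dplyr::bind_rows(tax(mk(8, "s1"), "s1"),
                             tax(mk(8, "s2"), "s2")),
    prots(two_sp))
  expect_equal(as.integer(table(sel$species)), c(6L, 6L))
})
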