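test_that("the engine enforces TAM and seed-mismatch rules", {
  eng <- cleavage_engine()
  sub <- tam_substrate(eng, seed = 1)
  perfect <- cleave_in_silico(sub, eng, seed = 2)
  expect_true(perfect$cleaved)
  expect_equal(perfect$efficiency, 1)

  # all 15 single TAM mutants abolish cleavage
  tam <- strsplit(eng$tam_consensus, "")[[1]]
  n_dead <- 0L
  for (p in 1:5) for (b in setdiff(DNA, tam[p])) {
    mut <- tam
    mut[p] <- b
    eff <- cleavage_efficiency(eng, paste(mut, collapse = ""), eng$guide)
    if (eff == 0) n_dead <- n_dead + 1L
  }
  expect_equal(n_dead, 15L)

  # single seed-region mismatch (position 5) abolishes cleavage
  g5 <- strsplit(eng$guide, "")[[1]]
  g5[5] <- setdiff(DNA, g5[5])[1]
  expect_equal(cleavage_efficiency(eng, eng$tam_consensus, eng$guide,
                                   guide = paste(g5, collapse = "")), 0)
  # distal mismatch (position 18) halves efficiency
  g18 <- strsplit(eng$guide, "")[[1]]
  g18[18] <- setdiff(DNA, g18[18])[1]
  expect_equal(cleavage_efficiency(eng, eng$tam_consensus, eng$guide,
                                   guide = paste(g18, collapse = "")), 0.5)

  # fragment conservation on each strand
  res <- cleave_in_silico(sub, eng, seed = 3)
  for (s in c("TS", "NTS")) {
    lens <- res$fragments$length[res$fragments$strand == s]
    expect_equal(sum(lens), nchar(sub$seq))
  }
  expect_error(cleave_in_silico(list(seq = "ACGT"), eng), "annotation")
})

test_that("TAM extraction recovers truth 7-mers and counts rejections", {
  eng <- cleavage_engine()
  sub <- tam_substrate(eng, seed = 4)
  params <- read_sim_params(depth = 30000, error_rate = 0.001, seed = 5)
  sim <- simulate_tam_library_reads(eng, sub, params)
  obs <- extract_tam_observations(sim$reads, sub, params$adapter)
  truth_mers <- sim$truth$seven_mer[sim$truth$cleaved]
  # recall >= 0.99 at error rate 0.001
  expect_gte(length(obs$tams) / length(truth_mers), 0.99)
  expect_true(all(obs$tams %in% truth_mers))

  # a read without the adapter is rejected with reason no_adapter
  bad <- tibble::tibble(id = "x", seq = strrep("T", 60))
  obs2 <- extract_tam_observations(bad, sub, params$adapter)
  expect_equal(obs2$rejected$reason, "no_adapter")
  expect_equal(length(obs2$tams), 0)
})

test_that("TAM enrichment calls the consensus with correct IC limits", {
  # degenerate: one observation repeated has 2 bits everywhere
  e1 <- suppressWarnings(tam_enrichment(rep("GGAGGAG", 50)))
  expect_equal(unname(e1$ic), rep(2, 7))
  # uniform observations carry no information
  withr::with_seed(6, {
    unif <- vapply(1:4000, function(i)
      paste(sample(DNA, 7, TRUE), collapse = ""), character(1))
  })
  e2 <- tam_enrichment(unif)
  expect_true(all(e2$ic < 0.1))
  expect_equal(e2$consensus, "NNNNNNN")
  expect_error(tam_enrichment(character(0)), "no TAM")
  # frequencies are column-stochastic
  expect_true(all(abs(colSums(e2$freq) - 1) < 1e-9))
})

test_that("cut-site mapping recovers the generating distribution", {
  eng <- cleavage_engine(ts_site_dist = c(`22` = 1.0))
  sub <- tam_substrate(eng, seed = 7)
  ro <- simulate_runoff_reads(eng, sub, n = 300, seed = 8)
  cp <- map_cut_sites(ro$reads, sub)
  ts <- dplyr::filter(cp$profile, strand == "TS")
  expect_equal(ts$position, 22L)
  expect_equal(ts$fraction, 1)

  eng2 <- cleavage_engine()
  ro2 <- simulate_runoff_reads(eng2, sub, n = 10000, seed = 9)
  cp2 <- map_cut_sites(ro2$reads, sub)
  expect_equal(cp2$ts_mode, 22L)
  expect_equal(cp2$nts_mode, 16L)
  expect_gte(cp2$nts_mode_fraction, 0.8)
  expect_gte(cp2$ts_mode_fraction, 0.6)
  expect_equal(cp2$overhang, 6L)
  # every per-position fraction within the multinomial band
  for (s in c("TS", "NTS")) {
    d <- if (s == "TS") eng2$ts_site_dist else eng2$nts_site_dist
    sub_p <- dplyr::filter(cp2$profile, strand == s)
    for (p in names(d)) {
      got <- sub_p$fraction[sub_p$position == as.integer(p)]
      expect_lt(abs(got - d[[p]]), 0.02)
    }
  }
  # per-strand fractions sum to one
  sums <- dplyr::summarise(dplyr::group_by(cp2$profile, strand),
                           s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("transcript anatomy reproduces the canonical segment lengths", {
  loc <- fixture_rerna_locus()
  reads <- simulate_small_rna_reads(loc$locus, loc$transcript,
                                    read_sim_params(read_length = 30,
                                                    seed = 10),
                                    mode = "tiling", step = 1)
  an <- small_rna_anatomy(reads, loc$locus, loc$motif_start, loc$motif_end,
                          loc$tail_start, orf_end = loc$orf_end)
  expect_equal(an$total_length, 184L)
  expect_equal(an$segments$length, c(37L, 73L, 64L, 10L))
  expect_equal(an$orf_offset, 13L)
  expect_false(an$truncated)

  # random reads with low error recover boundaries within 1 nt
  rnd <- simulate_small_rna_reads(loc$locus, loc$transcript,
                                  read_sim_params(depth = 500,
                                                  read_length = 30,
                                                  error_rate = 0.001,
                                                  seed = 11))
  an2 <- small_rna_anatomy(rnd, loc$locus, loc$motif_start, loc$motif_end,
                           loc$tail_start)
  expect_lte(abs(an2$transcript_start - loc$transcript[1]), 1)
  expect_lte(abs(an2$transcript_end - loc$transcript[2]), 1)

  # transcript flush with the locus edge is flagged truncated
  edge_reads <- simulate_small_rna_reads(loc$locus, c(0, 120),
                                         read_sim_params(read_length = 30,
                                                         seed = 12),
                                         mode = "tiling")
  an3 <- small_rna_anatomy(edge_reads, loc$locus, 40, 90, 110)
  expect_true(an3$truncated)

  expect_error(small_rna_anatomy(tibble::tibble(id = "r", seq = "GGGGGGGG"),
                                 strrep("A", 100), 10, 50, 80),
               "zero coverage")
})

test_that("indel quantification recovers planted rates and respects the window", {
  eng <- cleavage_engine()
  sub <- tam_substrate(eng, seed = 13)
  w <- c(sub$target_start - 5L, sub$target_end + 5L)

  sim0 <- simulate_amplicon_reads(sub$seq, 0, w,
                                  read_sim_params(depth = 200, seed = 14))
  expect_equal(quantify_indels(sim0$reads, sub$seq, w)$fraction, 0)

  sim <- simulate_amplicon_reads(sub$seq, 0.425, w,
                                 read_sim_params(depth = 1000,
                                                 error_rate = 0.001,
                                                 seed = 15))
  rep <- quantify_indels(sim$reads, sub$seq, w)
  expect_lte(abs(rep$fraction - 0.425), 0.005)

  # an indel planted outside the window is not counted
  far_w <- c(10L, 25L)
  sim_far <- simulate_amplicon_reads(sub$seq, 0.5, far_w,
                                     read_sim_params(depth = 100,
                                                     error_rate = 0,
                                                     seed = 16))
  rep_far <- quantify_indels(sim_far$reads, sub$seq, w)
  expect_equal(rep_far$fraction, 0)
})

test_that("the mismatch heatmap normalizes to WT and zeroes the seed block", {
  eng <- cleavage_engine()
  panel <- simulate_mismatch_panel(eng, base_rate = 0.425, depth = 150,
                                   error_rate = 0.001, seed = 17)
  hm <- mismatch_heatmap(panel, eng$guide)
  # WT cells are exactly 1
  gbase <- strsplit(eng$guide, "")[[1]]
  expect_true(all(hm$normalized[cbind(match(gbase, DNA), 1:20)] == 1))
  # seed positions 1-13: every substitution abolishes editing
  seed_cells <- hm$table$normalized[hm$table$position <= 13 &
                                      !hm$table$is_wt]
  expect_true(all(seed_cells == 0))
  # distal positions scale with the 0.5-per-mismatch factor
  distal <- hm$table$normalized[hm$table$position >= 14 & !hm$table$is_wt]
  expect_lt(max(abs(distal - 0.5)), 0.2)
  expect_equal(mean(distal), 0.5, tolerance = 0.1)

  # WT fraction zero is an explicit error
  bad <- dplyr::mutate(panel,
                       fraction = ifelse(is.na(position), 0, fraction))
  expect_error(mismatch_heatmap(bad, eng$guide), "normalization undefined")
})

test_that("off-target enumeration applies the exact-TAM and mismatch rules", {
  eng <- cleavage_engine()
  withr::with_seed(18, {
    bg <- paste(sample(DNA, 3000, TRUE), collapse = "")
    g2 <- strsplit(eng$guide, "")[[1]]
    g2[c(4, 11)] <- vapply(g2[c(4, 11)],
                           function(b) setdiff(DNA, b)[1], "")
    on_site <- paste0(eng$tam_consensus, eng$guide)
    off_site <- paste0(eng$tam_consensus, paste(g2, collapse = ""))
    mut_tam <- paste0("TGGAG", eng$guide)
    genome <- tibble::tibble(
      contig = "chr_test",
      seq = paste0(substr(bg, 1, 1000), on_site, substr(bg, 1001, 2000),
                   off_site, substr(bg, 2001, 2500), mut_tam,
                   substr(bg, 2501, 3000)))
  })
  cand <- find_offtarget_candidates(genome, eng$tam_consensus, eng$guide)
  expect_equal(cand$mismatches[1], 0)
  expect_equal(cand$start[1], 1005)
  expect_true(any(cand$mismatches == 2))
  # the mutated-TAM site must not be reported at its location
  expect_false(any(cand$start == 2530 + 5 & cand$strand == "+" &
                     cand$mismatches == 0 & cand$start != 1005))
  # planted on reverse strand is found too
  genome_rc <- tibble::tibble(contig = "rc", seq = revcomp(genome$seq))
  cand_rc <- find_offtarget_candidates(genome_rc, eng$tam_consensus,
                                       eng$guide)
  expect_true(any(cand_rc$strand == "-" & cand_rc$mismatches == 0))
})

test_that("reRNA construct assembly concatenates scaffold and guide", {
  withr::with_seed(19, {
    scaffold <- paste(sample(c("A", "C", "G", "U"), 187, TRUE),
                      collapse = "")
  })
  cons <- assemble_rerna(scaffold, cleavage_engine()$guide)
  expect_equal(cons$length, 207L)
  expect_equal(cons$scaffold_length, 187L)
  expect_equal(cons$guide_length, 20L)
  expect_false(grepl("T", cons$seq))
})
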