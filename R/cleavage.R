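hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

guide_mismatch_positions <- function(target, guide) {
  which(strsplit(target, "")[[1]] != strsplit(guide, "")[[1]])
}

#' Cleavage efficiency under the engine's mismatch rules
#'
#' Cleavage requires an exact TAM and zero guide-target mismatches inside
#' the seed region (positions 1-13 by default, counted from the
#' TAM-proximal edge); each mismatch outside the seed multiplies the
#' efficiency by the distal mismatch factor.
#'
#' @param engine A [cleavage_engine()].
#' @param tam Observed TAM (5 nt).
#' @param target Observed 20-nt target (non-target-strand sequence).
#' @param guide Guide to compare against; defaults to the engine's guide.
#' @return Efficiency in `[0, 1]`.
#' @export
cleavage_efficiency <- function(engine, tam, target, guide = NULL) {
  guide <- chartr("U", "T", toupper(guide %||% engine$guide))
  if (tam != engine$tam_consensus) return(0)
  mm <- guide_mismatch_positions(toupper(target), guide)
  seed_mm <- mm[mm >= engine$seed_region[1] & mm <= engine$seed_region[2]]
  if (length(seed_mm)) return(0)
  engine$distal_mismatch_factor^length(mm)
}

#' Cleave a substrate in silico
#'
#' Applies the engine's TAM and mismatch rules to an annotated substrate;
#' when cleavage occurs, per-strand cut positions are drawn from the site
#' distributions and product fragment coordinates computed. Fragment
#' lengths on each strand always sum to the substrate length.
#'
#' @param substrate Layout from [tam_substrate()] (or any list with `seq`,
#'   `tam_start`, `tam_end`, `target_start`, `target_end`).
#' @param engine A [cleavage_engine()].
#' @param seed Integer seed for the stochastic efficiency draw and cut
#'   positions.
#' @param guide Optional guide override (variant-guide experiments).
#' @return List `cleaved`, `efficiency`, `ts_cut`, `nts_cut` (nt from the
#'   TAM/target junction) and `fragments` (tibble `strand`, `fragment`,
#'   `start`, `end`, `length`; 0-based top-strand coordinates).
#' @export
cleave_in_silico <- function(substrate, engine, seed = 1L, guide = NULL) {
  need <- c("seq", "tam_start", "tam_end", "target_start", "target_end")
  if (!all(need %in% names(substrate))) {
    abort("substrate must carry TAM and target annotation")
  }
  withr::local_seed(seed)
  tam <- substr(substrate$seq, substrate$tam_start + 1L, substrate$tam_end)
  target <- substr(substrate$seq, substrate$target_start + 1L,
                   substrate$target_end)
  eff <- cleavage_efficiency(engine, tam, target, guide)
  cleaved <- runif(1) < eff
  if (!cleaved) {
    return(list(cleaved = FALSE, efficiency = eff, ts_cut = NA_integer_,
                nts_cut = NA_integer_, fragments = NULL))
  }
  L <- nchar(substrate$seq)
  ts <- draw_positions(engine$ts_site_dist, 1)
  nts <- draw_positions(engine$nts_site_dist, 1)
  cut_top <- substrate$target_start + nts
  cut_bot <- substrate$target_start + ts
  fragments <- tibble(
    strand = c("NTS", "NTS", "TS", "TS"),
    fragment = c("tam_proximal", "tam_distal", "tam_proximal", "tam_distal"),
    start = c(0L, cut_top, 0L, cut_bot),
    end = c(cut_top, L, cut_bot, L)
  ) |> mutate(length = .data$end - .data$start)
  list(cleaved = TRUE, efficiency = eff, ts_cut = ts, nts_cut = nts,
       fragments = fragments)
}

#' Extract TAM observations from cleaved-end reads
#'
#' A read is kept when its 5' adapter matches within tolerance and a 12-nt
#' backbone anchor immediately 5' of the randomized window matches exactly
#' after re-orienting the read; the 7-mer is then excised by coordinates.
#' Rejected reads are counted by reason.
#'
#' @param reads Tibble `id`, `seq` (from [simulate_tam_library_reads()] or
#'   [read_fastq()]).
#' @param substrate Backbone layout from [tam_substrate()].
#' @param adapter Adapter sequence.
#' @param max_adapter_mismatch Allowed adapter mismatches.
#' @param background Optional character vector of input-library 7-mers
#'   used as the enrichment background.
#' @return A `tam_observation_set`: `tams` (7-mers), `rejected` (tibble
#'   `reason`, `n`), `background`.
#' @export
extract_tam_observations <- function(reads, substrate, adapter,
                                     max_adapter_mismatch = 1,
                                     background = NULL) {
  anchor_start <- substrate$window_start - 12L
  if (anchor_start < 0) abort("backbone too short for a 12-nt anchor")
  # two 12-nt anchors flank the randomized window; an exact match to
  # either localises the window (a sequencing error in one anchor then
  # cannot discard the read)
  anchor_l <- substr(substrate$seq, anchor_start + 1L, anchor_start + 12L)
  anchor_r <- substr(substrate$seq, substrate$window_end + 1L,
                     substrate$window_end + 12L)
  for (a in c(anchor_l, anchor_r)) {
    if (length(gregexpr(a, substrate$seq, fixed = TRUE)[[1]]) != 1L) {
      abort("backbone anchor is not unique in the backbone")
    }
  }
  alen <- nchar(adapter)
  tams <- character(0)
  reasons <- character(0)
  for (i in seq_len(nrow(reads))) {
    r <- reads$seq[i]
    if (nchar(r) < alen + 19L ||
        hamming(substr(r, 1, alen), adapter) > max_adapter_mismatch) {
      reasons <- c(reasons, "no_adapter")
      next
    }
    frag <- revcomp(substr(r, alen + 1L, nchar(r)))
    pos <- regexpr(anchor_l, frag, fixed = TRUE)
    if (pos < 0) {
      pos_r <- regexpr(anchor_r, frag, fixed = TRUE)
      pos <- if (pos_r > 0) pos_r - 19L else -1L
    }
    if (pos < 0) {
      reasons <- c(reasons, "no_anchor")
      next
    }
    if (pos + 12L < 1L) {
      reasons <- c(reasons, "bad_window")
      next
    }
    mer <- substr(frag, pos + 12L, pos + 18L)
    if (nchar(mer) != 7L || grepl("[^ACGT]", mer)) {
      reasons <- c(reasons, "bad_window")
      next
    }
    tams <- c(tams, mer)
  }
  rejected <- if (length(reasons)) {
    as_tibble(table(reason = reasons)) |> dplyr::rename(n = "n")
  } else tibble(reason = character(), n = integer())
  new_tnpb_result(list(tams = tams, rejected = rejected,
                       background = background), "tam_observation_set")
}

base_freq_matrix <- function(mers, len = 7L) {
  mat <- do.call(rbind, strsplit(mers, ""))
  f <- vapply(seq_len(len), function(j) {
    as.numeric(table(factor(mat[, j], levels = DNA_BASES)))
  }, numeric(4))
  rownames(f) <- DNA_BASES
  sweep(f, 2, colSums(f), "/")
}

#' Per-position TAM enrichment and consensus call
#'
#' Computes the 7-position nucleotide frequency matrix of cleaved-product
#' 7-mers, per-position information content (2 - Shannon entropy, bits),
#' log2 enrichment over the background (uniform unless an input library
#' was supplied), and a consensus string with `N` at positions below 1 bit
#' of information.
#'
#' @param obs A `tam_observation_set` or character vector of 7-mers.
#' @param pseudo Pseudo-frequency added in the enrichment ratio.
#' @return A `tam_enrichment`: `freq` (4 x 7), `ic` (bits), `enrichment`
#'   (4 x 7 log2 ratios), `consensus`, `confidence` (per-position max
#'   frequency), `n`.
#' @export
tam_enrichment <- function(obs, pseudo = 1e-3) {
  mers <- if (inherits(obs, "tam_observation_set")) obs$tams else obs
  if (!length(mers)) abort("no TAM observations")
  if (length(mers) < 100) {
    warn(sprintf("only %d TAM observations; logo will be noisy",
                 length(mers)))
  }
  f <- base_freq_matrix(mers)
  ent <- apply(f, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- 2 - ent
  bg <- if (inherits(obs, "tam_observation_set") && !is.null(obs$background)) {
    base_freq_matrix(obs$background)
  } else matrix(0.25, 4, 7, dimnames = list(DNA_BASES, NULL))
  enr <- log2((f + pseudo) / (bg + pseudo))
  cons <- vapply(seq_len(7), function(j) {
    if (ic[j] >= 1) DNA_BASES[which.max(f[, j])] else "N"
  }, character(1))
  new_tnpb_result(list(
    freq = f, ic = ic, enrichment = enr,
    consensus = paste(cons, collapse = ""),
    confidence = apply(f, 2, max), n = length(mers)
  ), "tam_enrichment")
}

#' Map cut sites from run-off reads
#'
#' Each read is a (possibly noisy) prefix of its strand; the terminal base
#' is mapped to a position relative to the TAM/target junction (position 1
#' = the target base adjacent to the TAM). Reads below the identity floor
#' against their implied placement are discarded and counted. The overhang
#' is the target-strand mode minus the non-target-strand mode; a positive
#' value is a 5'-overhang at the TAM-distal end.
#'
#' @param reads Tibble `id`, `strand` (`TS`/`NTS`), `seq`.
#' @param substrate Layout from [tam_substrate()].
#' @param min_identity Identity floor for keeping a read.
#' @return A `cut_site_profile`: `profile` (tibble `strand`, `position`,
#'   `count`, `fraction`), `ts_mode`, `nts_mode`, `ts_mode_fraction`,
#'   `nts_mode_fraction`, `overhang`, `n_discarded`.
#' @export
map_cut_sites <- function(reads, substrate, min_identity = 0.9) {
  ref <- substrate$seq
  L <- nchar(ref)
  t0 <- substrate$target_start
  pos <- integer(0); strands <- character(0); discarded <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads$seq[i]
    len <- nchar(r)
    if (reads$strand[i] == "NTS") {
      expected <- substr(ref, 1L, len)
      p <- len - t0
    } else {
      expected <- revcomp(substr(ref, L - len + 1L, L))
      p <- L - t0 - len
    }
    if (len > L || hamming(r, expected) / len > 1 - min_identity) {
      discarded <- discarded + 1L
      next
    }
    pos <- c(pos, p); strands <- c(strands, reads$strand[i])
  }
  if (!length(pos)) abort("no mappable run-off reads")
  profile <- tibble(strand = strands, position = pos) |>
    group_by(.data$strand, .data$position) |>
    summarise(count = n(), .groups = "drop_last") |>
    mutate(fraction = .data$count / sum(.data$count)) |>
    ungroup()
  mode_of <- function(s) {
    sub <- filter(profile, .data$strand == s)
    if (!nrow(sub)) return(c(NA_integer_, NA_real_))
    k <- which.max(sub$fraction)
    c(sub$position[k], sub$fraction[k])
  }
  ts <- mode_of("TS"); nts <- mode_of("NTS")
  new_tnpb_result(list(
    profile = profile,
    ts_mode = as.integer(ts[1]), nts_mode = as.integer(nts[1]),
    ts_mode_fraction = ts[2], nts_mode_fraction = nts[2],
    overhang = as.integer(ts[1] - nts[1]),
    n_discarded = discarded
  ), "cut_site_profile")
}

#' Transcript anatomy from small-RNA coverage
#'
#' Places reads on the locus (exact match, with a near-exact fallback up
#' to `max_mismatch`), computes per-base coverage, calls the transcript as
#' the maximal region with coverage at or above `coverage_threshold` of
#' the maximum, and partitions it into 5' flanking, RNA-motif, 3' flanking
#' and 3' non-conserved tail segments at the provided landmarks.
#'
#' @param reads Tibble `id`, `seq`.
#' @param locus Locus sequence.
#' @param motif_start,motif_end Motif (e.g. RAGATH-18) bounds on the
#'   locus, 0-based half-open.
#' @param tail_start Start of the non-conserved 3' tail.
#' @param orf_end Optional 3' end of the upstream ORF; when given, the
#'   transcript-start offset from the ORF is reported.
#' @param coverage_threshold Fraction of maximum coverage defining the
#'   transcript.
#' @param max_mismatch Mismatch allowance for the fallback placement.
#' @return A `rerna_anatomy`: `transcript_start`, `transcript_end`,
#'   `total_length`, `segments` (tibble `name`, `start`, `end`, `length`),
#'   `truncated`, `orf_offset`, `coverage` (tibble `position`, `depth`),
#'   `n_unplaced`.
#' @export
small_rna_anatomy <- function(reads, locus, motif_start, motif_end,
                              tail_start, orf_end = NULL,
                              coverage_threshold = 0.1, max_mismatch = 2) {
  L <- nchar(locus)
  cov <- integer(L)
  unplaced <- 0L
  starts <- ends <- integer(0)
  locus_dna <- Biostrings::DNAString(locus)
  for (r in reads$seq) {
    s <- regexpr(r, locus, fixed = TRUE)
    if (s < 0 && max_mismatch > 0) {
      m <- Biostrings::matchPattern(r, locus_dna,
                                    max.mismatch = max_mismatch)
      s <- if (length(m)) Biostrings::start(m)[1] else -1L
    }
    if (s < 0) {
      unplaced <- unplaced + 1L
      next
    }
    idx <- s:(s + nchar(r) - 1L)
    cov[idx] <- cov[idx] + 1L
    starts <- c(starts, s); ends <- c(ends, s + nchar(r))
  }
  if (all(cov == 0)) abort("zero coverage on the locus")
  # core region by the coverage threshold, then bounds extended to the
  # outermost reads overlapping the core (keeps the trapezoid's ramps)
  hi <- which(cov >= coverage_threshold * max(cov))
  core_start <- min(hi); core_end <- max(hi)
  touching <- starts <= core_end & ends >= core_start
  tstart <- min(starts[touching]) - 1L  # back to 0-based
  tend <- max(ends[touching]) - 1L
  cuts <- sort(unique(pmin(pmax(
    c(tstart, motif_start, motif_end, tail_start, tend), tstart), tend)))
  seg_names <- character(0); seg_start <- integer(0); seg_end <- integer(0)
  labels <- c("five_prime_flanking", "rna_motif", "three_prime_flanking",
              "non_conserved_tail")
  bounds <- c(tstart, motif_start, motif_end, tail_start, tend)
  for (k in seq_len(4)) {
    s <- max(bounds[k], tstart); e <- min(bounds[k + 1], tend)
    if (e > s) {
      seg_names <- c(seg_names, labels[k])
      seg_start <- c(seg_start, s); seg_end <- c(seg_end, e)
    }
  }
  segments <- tibble(name = seg_names, start = seg_start, end = seg_end,
                     length = seg_end - seg_start)
  new_tnpb_result(list(
    transcript_start = tstart, transcript_end = tend,
    total_length = tend - tstart,
    segments = segments,
    truncated = tstart == 0L || tend == L,
    orf_offset = if (!is.null(orf_end)) tstart - orf_end else NA_integer_,
    coverage = tibble(position = seq_len(L) - 1L, depth = cov),
    n_unplaced = unplaced
  ), "rerna_anatomy")
}

#' Quantify indels in amplicon reads
#'
#' Each read is globally aligned to the reference with affine gaps (match
#' +2, mismatch -3, gap open 8, extend 1); a read counts as edited when at
#' least one gap column overlaps the target window. Reads below the
#' identity floor are discarded and counted. Substitutions never count as
#' edits.
#'
#' @param reads Tibble `id`, `seq`.
#' @param reference Amplicon reference sequence.
#' @param window Integer `c(start, end)`, 0-based half-open; conventionally
#'   the guide span padded by 5 nt.
#' @param min_identity Identity floor.
#' @param amplicon_id Label carried into the report.
#' @return An `indel_report`: `amplicon_id`, `total`, `aligned`, `edited`,
#'   `fraction`, `n_discarded`, `histogram` (tibble `position`, `count`).
#' @export
quantify_indels <- function(reads, reference, window, min_identity = 0.8,
                            amplicon_id = "amplicon") {
  if (any(nchar(reads$seq) > 2L * nchar(reference))) {
    abort("reference much shorter than reads")
  }
  w <- as.integer(window)
  # reads identical to the reference need no alignment
  exact <- reads$seq == reference
  todo <- which(!exact)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  ap <- as_ <- vector("list", nrow(reads))
  if (length(todo)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads$seq[todo]),
      Biostrings::DNAString(reference),
      substitutionMatrix = submat, gapOpening = 8, gapExtension = 1,
      type = "global")
    ap[todo] <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")
    as_[todo] <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")
  }
  edited <- logical(nrow(reads))
  discarded <- 0L
  hist_pos <- integer(0)
  for (i in todo) {
    p <- ap[[i]]; s <- as_[[i]]
    both <- p != "-" & s != "-"
    ident <- sum(p[both] == s[both]) / length(p)
    if (ident < min_identity) {
      edited[i] <- NA
      discarded <- discarded + 1L
      next
    }
    # 0-based reference coordinates: a deletion column sits on the deleted
    # base; an insertion sits on the boundary before the next reference
    # base and overlaps the window inclusively at both edges
    refpos <- cumsum(s != "-")
    gapcols <- which(!both)
    if (length(gapcols)) {
      is_ins <- s[gapcols] == "-"
      gp <- ifelse(is_ins, refpos[gapcols], refpos[gapcols] - 1L)
      inwin <- ifelse(is_ins, gp >= w[1] & gp <= w[2],
                      gp >= w[1] & gp < w[2])
      edited[i] <- any(inwin)
      hist_pos <- c(hist_pos, gp[inwin])
    }
  }
  aligned <- sum(!is.na(edited))
  n_edit <- sum(edited, na.rm = TRUE)
  histogram <- if (length(hist_pos)) {
    tibble(position = as.integer(names(table(hist_pos))),
           count = as.integer(table(hist_pos)))
  } else tibble(position = integer(), count = integer())
  new_tnpb_result(list(
    amplicon_id = amplicon_id, total = nrow(reads), aligned = aligned,
    edited = n_edit,
    fraction = if (aligned > 0) n_edit / aligned else NA_real_,
    n_discarded = discarded, histogram = histogram
  ), "indel_report")
}

#' Guide single-mismatch heatmap
#'
#' Normalises per-variant indel fractions by the wild-type guide's
#' fraction and lays them out as a 4 x 20 matrix (substituted base x guide
#' position). Cells at the original guide base hold the wild-type
#' normalised value 1.
#'
#' @param reports Tibble with columns `position` (1-20, `NA` for the WT
#'   row), `base` (substituted base, `NA` for WT) and `fraction`.
#' @param guide The original 20-nt guide.
#' @return A `mismatch_heatmap`: `normalized` (4 x 20 matrix),
#'   `wt_fraction`, `guide`, `table` (long tibble).
#' @export
mismatch_heatmap <- function(reports, guide) {
  guide <- chartr("U", "T", toupper(guide))
  wt <- reports$fraction[is.na(reports$position)]
  if (length(wt) != 1 || is.na(wt)) abort("exactly one WT row is required")
  if (wt == 0) abort("WT fraction is zero: normalization undefined")
  gbase <- strsplit(guide, "")[[1]]
  m <- matrix(NA_real_, 4, 20, dimnames = list(DNA_BASES, 1:20))
  m[cbind(match(gbase, DNA_BASES), 1:20)] <- 1
  var <- filter(reports, !is.na(.data$position))
  for (i in seq_len(nrow(var))) {
    m[var$base[i], var$position[i]] <- var$fraction[i] / wt
  }
  tbl <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    stats::setNames(c("base", "position", "normalized")) |>
    mutate(position = as.integer(.data$position),
           is_wt = .data$base == gbase[.data$position])
  new_tnpb_result(list(normalized = m, wt_fraction = wt, guide = guide,
                       table = tbl), "mismatch_heatmap")
}

#' Simulate a single-mismatch guide panel
#'
#' Generates amplicon reads for the wild-type guide plus all 60 single
#' substitutions, with the planted indel rate equal to the base editing
#' rate scaled by the engine's cleavage efficiency for each variant, and
#' quantifies each. A convenience wrapper composing the synthetic
#' generator and [quantify_indels()].
#'
#' @param engine A [cleavage_engine()].
#' @param base_rate Editing rate of the perfectly matched guide.
#' @param depth Reads per variant.
#' @param error_rate Per-base substitution error.
#' @param seed Integer seed.
#' @return Tibble `position`, `base`, `fraction` ready for
#'   [mismatch_heatmap()].
#' @export
simulate_mismatch_panel <- function(engine, base_rate = 0.425, depth = 400,
                                    error_rate = 0.001, seed = 1L) {
  sub <- tam_substrate(engine, seed = seed)
  window <- c(sub$target_start - 5L, sub$target_end + 5L)
  gbase <- strsplit(engine$guide, "")[[1]]
  variants <- tibble(position = NA_integer_, base = NA_character_)
  for (pos in 1:20) {
    for (b in setdiff(DNA_BASES, gbase[pos])) {
      variants <- bind_rows(variants, tibble(position = pos, base = b))
    }
  }
  fractions <- numeric(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    g <- gbase
    if (!is.na(variants$position[i])) g[variants$position[i]] <- variants$base[i]
    eff <- cleavage_efficiency(engine, engine$tam_consensus,
                               paste(gbase, collapse = ""),
                               guide = paste(g, collapse = ""))
    sim <- simulate_amplicon_reads(
      sub$seq, indel_rate = base_rate * eff, indel_window = window,
      params = read_sim_params(depth = depth, error_rate = error_rate,
                               seed = seed + i))
    rep <- quantify_indels(sim$reads, sub$seq, window)
    fractions[i] <- rep$fraction
  }
  mutate(variants, fraction = fractions)
}

#' Assemble a guide-programmed reRNA construct
#'
#' Concatenates the reRNA scaffold (5' flanking + RNA motif + 3' flanking)
#' with a variable 3' guide segment, the layout used to retarget the
#' nuclease: scaffold first, guide at the 3' end.
#'
#' @param scaffold Scaffold RNA sequence.
#' @param guide Guide segment (DNA input is transcribed T to U).
#' @return List `seq`, `length`, `scaffold_length`, `guide_length`.
#' @export
assemble_rerna <- function(scaffold, guide) {
  scaffold <- chartr("T", "U", toupper(scaffold))
  guide <- chartr("T", "U", toupper(guide))
  seq <- paste0(scaffold, guide)
  list(seq = seq, length = nchar(seq),
       scaffold_length = nchar(scaffold), guide_length = nchar(guide))
}

#' Enumerate candidate off-target sites
#'
#' Scans both strands of a genome for an exact TAM immediately followed by
#' a 20-nt window with at most `max_mismatches` against the guide (no
#' bulges). Sites are sorted by mismatch count, then coordinate.
#'
#' @param genome Tibble `contig`, `seq`.
#' @param tam TAM consensus (exact match required).
#' @param guide 20-nt guide.
#' @param max_mismatches Mismatch cap (default 3).
#' @return Tibble `contig`, `strand`, `start`, `end` (0-based half-open
#'   target window on the forward strand), `mismatches`, `site_seq`.
#' @export
find_offtarget_candidates <- function(genome, tam, guide,
                                      max_mismatches = 3) {
  guide <- chartr("U", "T", toupper(guide))
  gl <- nchar(guide)
  gchar <- strsplit(guide, "")[[1]]
  rows <- list()
  scan_strand <- function(seq, contig, strand) {
    L <- nchar(seq)
    hits <- gregexpr(tam, seq, fixed = TRUE)[[1]]
    if (hits[1] < 0) return()
    for (q in hits) {
      s <- q + nchar(tam)  # 1-based target start
      if (s + gl - 1L > L) next
      site <- substr(seq, s, s + gl - 1L)
      mm <- sum(strsplit(site, "")[[1]] != gchar)
      if (mm > max_mismatches) next
      if (strand == "+") {
        start0 <- s - 1L
      } else {
        start0 <- L - (s + gl - 1L)
      }
      rows[[length(rows) + 1]] <<- tibble(
        contig = contig, strand = strand, start = start0,
        end = start0 + gl, mismatches = mm, site_seq = site)
    }
  }
  for (i in seq_len(nrow(genome))) {
    scan_strand(genome$seq[i], genome$contig[i], "+")
    scan_strand(revcomp(genome$seq[i]), genome$contig[i], "-")
  }
  if (!length(rows)) {
    return(tibble(contig = character(), strand = character(),
                  start = integer(), end = integer(),
                  mismatches = integer(), site_seq = character()))
  }
  bind_rows(rows) |> arrange(.data$mismatches, .data$contig, .data$start)
}
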