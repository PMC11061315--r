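#' Build a TAM-assay substrate around an engine's guide
#'
#' Lays out a top strand (the non-target strand) as
#' `5'-backbone - 7-nt window - 20-nt target - backbone-3'`, where the
#' TAM-proximal 5 nt of the window carry the engine's TAM consensus and the
#' target equals the guide read as DNA. Coordinates are 0-based half-open.
#'
#' @param engine A [cleavage_engine()].
#' @param upstream,downstream Backbone lengths flanking the window/target.
#' @param seed Integer seed for the random backbone.
#' @return List with `seq`, `window_start`, `window_end`, `tam_start`,
#'   `tam_end`, `target_start`, `target_end`.
#' @export
tam_substrate <- function(engine, upstream = 60L, downstream = 120L,
                          seed = 1L) {
  stopifnot(inherits(engine, "cleavage_engine"))
  if (upstream < 12L) abort("upstream backbone must be >= 12 nt (anchor)")
  withr::local_seed(seed)
  window <- paste0(paste(sample(DNA_BASES, 2, replace = TRUE), collapse = ""),
                   engine$tam_consensus)
  seq <- paste0(rand_dna(1, upstream), window, engine$guide,
                rand_dna(1, downstream))
  list(seq = seq,
       window_start = upstream, window_end = upstream + 7L,
       tam_start = upstream + 2L, tam_end = upstream + 7L,
       target_start = upstream + 7L, target_end = upstream + 27L)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, mutate_seq, character(1), rate = error_rate,
         alphabet = DNA_BASES, USE.NAMES = FALSE)
}

draw_positions <- function(dist, n) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

#' Simulate a randomized-TAM cleavage library
#'
#' Emulates the biochemical TAM-discovery assay: a plasmid library carries
#' a 7-nt randomized window immediately 5' of a 20-nt target; molecules
#' whose 5 TAM-proximal window bases match the engine's TAM consensus are
#' cleaved, their ends adapter-ligated, and reads spanning the window are
#' emitted. Uncleaved molecules emit no cleaved-end reads.
#'
#' @param engine A [cleavage_engine()].
#' @param substrate Substrate layout from [tam_substrate()].
#' @param params A [read_sim_params()]; `depth` is the number of library
#'   molecules.
#' @return List with `reads` (tibble `id`, `seq`, `qual`, `molecule`) and
#'   `truth` (tibble `molecule`, `seven_mer`, `cleaved`).
#' @export
simulate_tam_library_reads <- function(engine, substrate, params) {
  stopifnot(inherits(engine, "cleavage_engine"),
            inherits(params, "read_sim_params"))
  if (substrate$window_end - substrate$window_start < 7L) {
    abort("randomized window shorter than 7 nt")
  }
  withr::local_seed(params$seed)
  n <- params$depth
  mers <- vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, 7, replace = TRUE), collapse = ""), character(1))
  cleaved <- substr(mers, 3, 7) == engine$tam_consensus
  truth <- tibble(molecule = sprintf("mol_%06d", seq_len(n)),
                  seven_mer = mers, cleaved = cleaved)

  idx <- which(cleaved)
  reads <- tibble(id = character(), seq = character(), qual = character(),
                  molecule = character())
  if (length(idx)) {
    cuts <- substrate$target_start + draw_positions(engine$nts_site_dist,
                                                    length(idx))
    anchor_start <- substrate$window_start - 12L
    frag <- vapply(seq_along(idx), function(k) {
      mol <- substrate$seq
      substr(mol, substrate$window_start + 1L, substrate$window_end) <- mers[idx[k]]
      substr(mol, anchor_start + 1L, cuts[k])
    }, character(1))
    rseq <- paste0(params$adapter, revcomp(frag))
    rseq <- substr(rseq, 1L, params$read_length)
    rseq <- apply_errors(rseq, params$error_rate)
    reads <- tibble(id = sprintf("tamread_%06d", seq_along(idx)),
                    seq = rseq, qual = strrep("I", nchar(rseq)),
                    molecule = truth$molecule[idx])
  }
  list(reads = reads, truth = truth)
}

#' Simulate run-off reads of cleavage products
#'
#' Cut positions are drawn i.i.d. from the engine's per-strand site
#' distributions. A non-target-strand read is the top-strand prefix ending
#' at the cut; a target-strand read is the bottom-strand prefix (reverse
#' complement of the top-strand suffix) ending at its cut. `n` reads are
#' emitted per strand.
#'
#' @param engine A [cleavage_engine()].
#' @param substrate Layout from [tam_substrate()]; its TAM must equal the
#'   engine consensus and its target must match the guide.
#' @param n Reads per strand.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution probability.
#' @return List with `reads` (tibble `id`, `strand`, `seq`, `qual`) and
#'   `truth` (tibble `id`, `strand`, `position`).
#' @export
simulate_runoff_reads <- function(engine, substrate, n = 1000, seed = 1L,
                                  error_rate = 0) {
  stopifnot(inherits(engine, "cleavage_engine"))
  seq <- substrate$seq
  if (substr(seq, substrate$tam_start + 1L, substrate$tam_end) !=
      engine$tam_consensus) {
    abort("substrate TAM does not match the engine consensus")
  }
  if (substr(seq, substrate$target_start + 1L, substrate$target_end) !=
      engine$guide) {
    abort("substrate target does not match the engine guide")
  }
  withr::local_seed(seed)
  L <- nchar(seq)
  ts_pos <- draw_positions(engine$ts_site_dist, n)
  nts_pos <- draw_positions(engine$nts_site_dist, n)
  nts_seq <- substr(rep(seq, n), 1L, substrate$target_start + nts_pos)
  ts_seq <- revcomp(substr(rep(seq, n),
                           substrate$target_start + ts_pos + 1L, L))
  reads <- tibble(
    id = c(sprintf("nts_%06d", seq_len(n)), sprintf("ts_%06d", seq_len(n))),
    strand = rep(c("NTS", "TS"), each = n),
    seq = apply_errors(c(nts_seq, ts_seq), error_rate)
  )
  reads$qual <- strrep("I", nchar(reads$seq))
  truth <- tibble(id = reads$id, strand = reads$strand,
                  position = c(nts_pos, ts_pos))
  list(reads = reads, truth = truth)
}

#' Simulate small-RNA reads over a transcript
#'
#' In tiling mode every `step`-spaced window of the transcript is emitted
#' exactly once; in random mode `depth` read start positions are drawn
#' uniformly. Reads never extend outside the transcript bounds.
#'
#' @param locus Locus sequence (character scalar).
#' @param transcript_bounds Integer `c(start, end)`, 0-based half-open on
#'   the locus.
#' @param params A [read_sim_params()].
#' @param mode `"random"` or `"tiling"`.
#' @param step Tiling step in nt.
#' @return Tibble `id`, `seq`, `qual`, `truth_start` (0-based).
#' @export
simulate_small_rna_reads <- function(locus, transcript_bounds, params,
                                     mode = c("random", "tiling"), step = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "read_sim_params"))
  tb <- as.integer(transcript_bounds)
  if (tb[1] < 0 || tb[2] > nchar(locus)) abort("transcript outside locus")
  rl <- params$read_length
  if (tb[2] - tb[1] < rl) abort("transcript shorter than read_length")
  withr::local_seed(params$seed)
  starts <- if (mode == "tiling") {
    seq.int(tb[1], tb[2] - rl, by = step)
  } else {
    tb[1] + sample.int(tb[2] - rl - tb[1] + 1L, params$depth,
                       replace = TRUE) - 1L
  }
  seqs <- substr(rep(locus, length(starts)), starts + 1L, starts + rl)
  seqs <- apply_errors(seqs, params$error_rate)
  tibble(id = sprintf("srna_%06d", seq_along(starts)), seq = seqs,
         qual = strrep("I", rl), truth_start = starts)
}

#' Simulate amplicon reads with planted indels
#'
#' Exactly `round(indel_rate * depth)` reads carry one indel of 1-10 nt at
#' a uniform position inside the window; all other reads match the
#' reference up to the substitution error rate. Sequencing errors are
#' substitutions only, so the edited-read truth is unambiguous.
#'
#' @param reference Amplicon reference sequence.
#' @param indel_rate Fraction of edited reads.
#' @param indel_window Integer `c(start, end)`, 0-based half-open.
#' @param params A [read_sim_params()].
#' @return List with `reads` (tibble `id`, `seq`, `qual`) and `truth`
#'   (tibble `id`, `edited`, `indel_type`, `indel_size`, `indel_pos`).
#' @export
simulate_amplicon_reads <- function(reference, indel_rate, indel_window,
                                    params) {
  stopifnot(inherits(params, "read_sim_params"))
  w <- as.integer(indel_window)
  if (w[1] < 0 || w[2] > nchar(reference)) abort("window outside reference")
  if (w[2] - w[1] < 10L) abort("window too small for maximum 10-nt indel")
  withr::local_seed(params$seed)
  n <- params$depth
  n_edit <- round(indel_rate * n)
  edited <- seq_len(n) <= n_edit
  type <- ifelse(edited, sample(c("del", "ins"), n, replace = TRUE), NA)
  size <- ifelse(edited, sample.int(10L, n, replace = TRUE), NA_integer_)
  seqs <- rep(reference, n)
  pos <- rep(NA_integer_, n)
  for (i in which(edited)) {
    if (type[i] == "del") {
      pos[i] <- w[1] + sample.int(w[2] - w[1] - size[i] + 1L, 1) - 1L
      seqs[i] <- paste0(substr(reference, 1L, pos[i]),
                        substr(reference, pos[i] + size[i] + 1L,
                               nchar(reference)))
    } else {
      pos[i] <- w[1] + sample.int(w[2] - w[1] + 1L, 1) - 1L
      seqs[i] <- paste0(substr(reference, 1L, pos[i]),
                        paste(sample(DNA_BASES, size[i], replace = TRUE),
                              collapse = ""),
                        substr(reference, pos[i] + 1L, nchar(reference)))
    }
  }
  seqs <- apply_errors(seqs, params$error_rate)
  list(
    reads = tibble(id = sprintf("amp_%06d", seq_len(n)), seq = seqs,
                   qual = strrep("I", nchar(seqs))),
    truth = tibble(id = sprintf("amp_%06d", seq_len(n)), edited = edited,
                   indel_type = type, indel_size = size, indel_pos = pos)
  )
}
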