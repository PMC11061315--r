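#' Specification objects for the synthetic-data generators
#'
#' Each generator consumes a validated spec object; a spec plus its seed
#' fully determines the output (byte-identical on re-run). `genome_spec()`
#' describes contigs of protein-coding genes with a defense / housekeeping /
#' other role mosaic, optional planted defense islands and planted
#' intergenic RNA motifs. `family_spec()` describes protein families derived
#' from a consensus by point substitution. `cleavage_engine()` parameterises
#' the in-silico nuclease; `read_sim_params()` parameterises read emission.
#'
#' @param n_contigs,genes_per_contig Counts.
#' @param role_mix Named proportions over `defense`, `housekeeping`,
#'   `other`; must sum to 1.
#' @param islands List of planted islands, each
#'   `list(contig =, at_gene =, n_genes =)` (1-based gene indices).
#' @param motif_plants List of planted motifs, each
#'   `list(contig =, igr_index =, strand =, seq =)`; `igr_index` i is the
#'   intergenic region following gene i (0 = before the first gene).
#' @param gene_length_range,igr_length_range Length ranges in nt.
#' @param defense_consensus,housekeeping_consensus Optional character
#'   vectors of consensus proteins; when given, genes of that role carry
#'   proteins mutated from a sampled consensus (divergence 0.05) so that
#'   profile-based role annotation has signal to find.
#' @param seed Integer seed.
#' @return A validated spec object (a classed list).
#' @export
genome_spec <- function(n_contigs = 1, genes_per_contig = 20,
                        role_mix = c(defense = 0.15, housekeeping = 0.35,
                                     other = 0.5),
                        islands = list(), motif_plants = list(),
                        gene_length_range = c(300, 900),
                        igr_length_range = c(20, 200),
                        defense_consensus = NULL,
                        housekeeping_consensus = NULL,
                        seed = 1L) {
  role_mix <- role_mix[c("defense", "housekeeping", "other")]
  if (anyNA(role_mix) || abs(sum(role_mix) - 1) > 1e-9) {
    abort("role_mix must cover defense/housekeeping/other and sum to 1")
  }
  if (any(c(gene_length_range, igr_length_range) <= 0)) {
    abort("length ranges must be positive")
  }
  for (isl in islands) {
    if (isl$at_gene < 1 || isl$at_gene + isl$n_genes - 1 > genes_per_contig) {
      abort("infeasible spec: planted island does not fit on its contig")
    }
    if (isl$contig > n_contigs) abort("island on nonexistent contig")
  }
  for (mp in motif_plants) {
    if (mp$contig > n_contigs || mp$igr_index < 0 ||
        mp$igr_index > genes_per_contig) {
      abort("infeasible spec: planted motif IGR index out of range")
    }
  }
  new_tnpb_result(list(
    n_contigs = n_contigs, genes_per_contig = genes_per_contig,
    role_mix = role_mix, islands = islands, motif_plants = motif_plants,
    gene_length_range = gene_length_range,
    igr_length_range = igr_length_range,
    defense_consensus = defense_consensus,
    housekeeping_consensus = housekeeping_consensus,
    seed = as.integer(seed)
  ), "genome_spec")
}

#' @rdname genome_spec
#' @param n_families,members_per_family Counts.
#' @param consensus_length Consensus protein length (aa).
#' @param divergence Per-site substitution rate in `[0, 1)` applied
#'   independently to each member.
#' @param species_labels Optional named character vector mapping member id
#'   to a 7-rank lineage string; defaults to one species per family.
#' @export
family_spec <- function(n_families = 3, members_per_family = 5,
                        consensus_length = 200, divergence = 0.1,
                        species_labels = NULL, seed = 1L) {
  if (divergence < 0 || divergence >= 1) abort("divergence must be in [0, 1)")
  if (n_families < 1 || members_per_family < 1 || consensus_length < 1) {
    abort("counts must be positive")
  }
  new_tnpb_result(list(
    n_families = n_families, members_per_family = members_per_family,
    consensus_length = consensus_length, divergence = divergence,
    species_labels = species_labels, seed = as.integer(seed)
  ), "family_spec")
}

#' @rdname genome_spec
#' @param tam_consensus TAM consensus (5 nt, immediately 5' of the target
#'   on the non-target strand).
#' @param guide 20-nt guide sequence (DNA alphabet; T is read as U).
#' @param seed_region Inclusive guide position range intolerant to
#'   mismatches (positions counted 1..20 from the TAM-proximal edge).
#' @param distal_mismatch_factor Per-mismatch efficiency multiplier applied
#'   for mismatches outside the seed region.
#' @param ts_site_dist,nts_site_dist Named numeric vectors mapping cut
#'   position (nt from the TAM/target junction, position 1 adjacent to the
#'   TAM) to probability; each must sum to 1. Defaults place the
#'   target-strand mode at 22 and the non-target-strand mode at 16,
#'   yielding a 6-nt 5'-overhang at the TAM-distal end.
#' @export
cleavage_engine <- function(tam_consensus = "AGGAG",
                            guide = "GTCACCTCCAATGACTAGGG",
                            seed_region = c(1L, 13L),
                            distal_mismatch_factor = 0.5,
                            ts_site_dist = c(`21` = 0.20, `22` = 0.65,
                                             `23` = 0.15),
                            nts_site_dist = c(`15` = 0.075, `16` = 0.85,
                                              `17` = 0.075)) {
  if (nchar(tam_consensus) != 5) abort("tam_consensus must be 5 nt")
  if (nchar(guide) != 20) abort("guide length must be 20")
  if (distal_mismatch_factor <= 0 || distal_mismatch_factor > 1) {
    abort("distal_mismatch_factor must be in (0, 1]")
  }
  check_prob_dist(ts_site_dist, "ts_site_dist")
  check_prob_dist(nts_site_dist, "nts_site_dist")
  new_tnpb_result(list(
    tam_consensus = toupper(tam_consensus),
    guide = chartr("U", "T", toupper(guide)),
    seed_region = as.integer(seed_region),
    distal_mismatch_factor = distal_mismatch_factor,
    ts_site_dist = ts_site_dist, nts_site_dist = nts_site_dist
  ), "cleavage_engine")
}

#' @rdname genome_spec
#' @param depth Number of reads (or molecules).
#' @param error_rate Per-base substitution probability in `[0, 0.1]`;
#'   sequencing errors are substitutions only, so indel truth stays
#'   unambiguous.
#' @param read_length Read length in nt.
#' @param adapter Adapter sequence prefixed to cleaved-end reads.
#' @export
read_sim_params <- function(depth = 1000, error_rate = 0.001,
                            read_length = 150,
                            adapter = "ACACGACGCTCTTCCGATCT", seed = 1L) {
  if (error_rate < 0 || error_rate > 0.1) abort("error_rate must be in [0, 0.1]")
  if (depth <= 0) abort("depth must be positive")
  new_tnpb_result(list(
    depth = as.integer(depth), error_rate = error_rate,
    read_length = as.integer(read_length), adapter = toupper(adapter),
    seed = as.integer(seed)
  ), "read_sim_params")
}
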