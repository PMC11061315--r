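#' Run the end-to-end discovery pipeline
#'
#' Chains the discovery stages on one genome set: role annotation (or
#' ground-truth roles), defense-island calling, IGR extraction, motif
#' calibration and scanning, neighborhood windows, two-step protein
#' clustering of the windowed proteins, and RNA-protein co-occurrence.
#' Every stage output and a run manifest are returned.
#'
#' @param genome Tibble `contig`, `seq`.
#' @param genes Gene tibble (`contig`, `gene_id`, `start`, `end`,
#'   `strand`, `protein`, optional `role`).
#' @param motif_model A [build_motif_model()].
#' @param defense_db,housekeeping_db Profile databases for
#'   [annotate_roles()]; when `NULL`, the `role` column of `genes` is used
#'   directly (truth-role mode).
#' @param igr_min_len,neighborhood_k,cluster_identity,cluster_coverage,mcl_inflation
#'   Stage thresholds (defaults 15, 5, 0.3, 0.6, 2.0).
#' @param scan_fpr Per-window false positive rate for motif calling.
#' @param seed Integer seed covering calibration and clustering.
#' @return List of class `discovery_run`: `roles`, `islands`, `igrs`,
#'   `null`, `hits`, `windows`, `clustering`, `cooccurrence`, `manifest`.
#' @export
run_discovery <- function(genome, genes, motif_model,
                          defense_db = NULL, housekeeping_db = NULL,
                          igr_min_len = 15, neighborhood_k = 5,
                          cluster_identity = 0.3, cluster_coverage = 0.6,
                          mcl_inflation = 2.0, scan_fpr = 1e-3,
                          seed = 1L) {
  if (nrow(genome) == 0) abort("empty genome set")
  roles <- if (!is.null(defense_db)) {
    stage <- "annotate_roles"
    left_join(select(genes, -dplyr::any_of("role")),
              annotate_roles(genes, defense_db, housekeeping_db,
                             seed = seed),
              by = "gene_id")
  } else {
    if (!"role" %in% names(genes)) {
      abort("run_discovery without profile DBs needs a role column")
    }
    genes
  }
  islands <- call_islands(roles)
  igrs <- extract_igrs(roles, genome, min_len = igr_min_len,
                       islands = islands)
  null <- calibrate_null(motif_model, seed = seed, fpr = scan_fpr)
  hits <- scan_motif(igrs, motif_model, null = null)
  if (nrow(hits)) {
    hits_on_contig <- mutate(hits, start = .data$contig_start,
                             end = .data$contig_end,
                             motif = motif_model$name)
  } else {
    hits_on_contig <- mutate(hits, motif = character(0))
  }
  windows <- neighborhood(hits_on_contig, roles, k = neighborhood_k)
  prots <- roles |>
    filter(.data$gene_id %in% windows$gene_id) |>
    distinct(.data$gene_id, .data$protein) |>
    dplyr::rename(protein_id = "gene_id", seq = "protein")
  clustering <- if (nrow(prots) >= 2) {
    two_step_cluster(prots, min_identity = cluster_identity,
                     min_coverage = cluster_coverage,
                     inflation = mcl_inflation, seed = seed)
  } else NULL
  cooc <- if (!is.null(clustering) && nrow(hits_on_contig)) {
    cooccurrence(hits_on_contig, windows, clustering$clusters)
  } else {
    tibble(motif = character(), cluster_id = character(),
           n_adjacent = integer(), n_hits = integer(),
           fraction = numeric())
  }
  manifest <- run_manifest(
    step = "run_discovery",
    params = list(igr_min_len = igr_min_len,
                  neighborhood_k = neighborhood_k,
                  cluster_identity = cluster_identity,
                  cluster_coverage = cluster_coverage,
                  mcl_inflation = mcl_inflation, scan_fpr = scan_fpr,
                  motif = motif_model$name,
                  truth_roles = is.null(defense_db)),
    seed = seed)
  new_tnpb_result(list(
    roles = roles, islands = islands, igrs = igrs, null = null,
    hits = hits_on_contig, windows = windows, clustering = clustering,
    cooccurrence = cooc, manifest = manifest
  ), "discovery_run")
}
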