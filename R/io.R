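#' Read and write FASTA files as tibbles
#'
#' Sequences travel through the package as tibbles with an id column and a
#' plain-character `seq` column; [Biostrings::readDNAStringSet()] and
#' friends do the parsing. Round-trips are lossless for ids and sequences.
#'
#' @param path File path.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta()`: a tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- switch(type,
    DNA = Biostrings::readDNAStringSet(path),
    AA = Biostrings::readAAStringSet(path)
  )
  tibble(id = names(ss), seq = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @param x Tibble with columns `id`, `seq`.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- switch(type,
    DNA = Biostrings::DNAStringSet(setNames(x$seq, x$id)),
    AA = Biostrings::AAStringSet(setNames(x$seq, x$id))
  )
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write FASTQ files as tibbles
#'
#' Qualities are carried as plain Phred+33 strings; generated reads use a
#' constant high-quality symbol since no quality-aware logic exists in the
#' package.
#'
#' @param path File path.
#' @return `read_fastq()`: a tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(id = names(ss), seq = unname(as.character(ss)),
         qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' @rdname read_fastq
#' @param x Tibble with columns `id`, `seq` and optionally `qual`.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("qual" %in% names(x)) x$qual else strrep("I", nchar(x$seq))
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read and write gene tables as GFF3
#'
#' Internally all coordinates are 0-based half-open; GFF3 is 1-based
#' inclusive, so `start` gains 1 on write and loses 1 on read. The gene
#' `role` and `protein` columns ride along as GFF3 attributes.
#'
#' @param path File path.
#' @return `read_gff_genes()`: a tibble with columns `contig`, `gene_id`,
#'   `start`, `end` (0-based half-open), `strand`, plus any attributes.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble(contig = character(), gene_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    abort(sprintf("malformed GFF3 record at line %d: expected 9 fields",
                  which(!startsWith(lines, "#") & nzchar(lines))[bad[1]]))
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  attr_field <- strsplit(f(9), ";", fixed = TRUE)
  get_attr <- function(key) {
    vapply(attr_field, function(a) {
      hit <- grep(paste0("^", key, "="), a, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }, character(1))
  }
  out <- tibble(
    contig = f(1),
    gene_id = get_attr("ID"),
    start = as.integer(f(4)) - 1L,
    end = as.integer(f(5)),
    strand = f(7)
  )
  for (key in c("role", "protein")) {
    val <- get_attr(key)
    if (!all(is.na(val))) out[[key]] <- val
  }
  out
}

#' @rdname read_gff_genes
#' @param x Gene tibble (`contig`, `gene_id`, `start`, `end`, `strand`,
#'   optional `role`, `protein`).
#' @param source Value for the GFF3 source column.
#' @export
write_gff_genes <- function(x, path, source = "tnpbtools") {
  attrs <- paste0("ID=", x$gene_id)
  for (key in c("role", "protein")) {
    if (key %in% names(x)) attrs <- paste0(attrs, ";", key, "=", x[[key]])
  }
  lines <- paste(x$contig, source, "gene", x$start + 1L, x$end, ".",
                 x$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read and write interval tables as BED
#'
#' BED is 0-based half-open, matching the package's internal convention,
#' so coordinates pass through unchanged.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `contig`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  nm <- c("contig", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(ncol(x))]
  as_tibble(x)
}

#' @rdname read_bed
#' @param x Tibble with at least `contig`, `start`, `end`; optional `name`,
#'   `score`, `strand`.
#' @export
write_bed <- function(x, path) {
  pick <- function(col, default) {
    if (col %in% names(x)) x[[col]] else default
  }
  out <- tibble(
    contig = x$contig, start = x$start, end = x$end,
    name = pick("name", "."),
    score = pick("score", 0),
    strand = pick("strand", ".")
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a Stockholm-lite RNA seed alignment
#'
#' Parses the minimal Stockholm dialect the motif builder consumes: aligned
#' sequences plus a `#=GC SS_cons` consensus-structure line. Multi-block
#' (interleaved) files are concatenated per id.
#'
#' @param path File path.
#' @return List with `alignment` (named character vector of aligned rows)
#'   and `ss_cons` (consensus structure string).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  ss <- character()
  for (ln in lines) {
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (!startsWith(ln, "#") && !startsWith(ln, "//") && nzchar(trimws(ln))) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2) abort(sprintf("malformed Stockholm line: %s", ln))
      seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
    }
  }
  if (length(seqs) == 0) abort("no sequences in Stockholm file")
  list(alignment = unlist(seqs), ss_cons = paste(ss, collapse = ""))
}

#' @rdname read_stockholm
#' @param alignment Named character vector of equal-length aligned rows.
#' @param ss_cons Consensus structure string (same length).
#' @export
write_stockholm <- function(alignment, ss_cons, path) {
  pad <- max(nchar(names(alignment)), nchar("#=GC SS_cons"))
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf("%-*s %s", pad, names(alignment), alignment),
    sprintf("%-*s %s", pad, "#=GC SS_cons", ss_cons),
    "//"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run manifest
#'
#' Records what a pipeline run saw and produced: package version, the full
#' parameter set, seeds, md5 checksums of any file inputs, and timestamps.
#' Re-running with the same manifest parameters reproduces byte-identical
#' analytical outputs (timestamps aside).
#'
#' @param step Name of the pipeline step.
#' @param params Named list of parameters (must be JSON-serialisable).
#' @param seed Integer seed(s) used.
#' @param input_files Character vector of input file paths to checksum.
#' @param output_files Character vector of produced files.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(step, params = list(), seed = NULL,
                         input_files = character(), output_files = character()) {
  new_tnpb_result(list(
    tool = "tnpbtools",
    version = as.character(utils::packageVersion("tnpbtools")),
    step = step,
    params = params,
    seed = seed,
    rng = "R Mersenne-Twister via set.seed per generator call",
    input_checksums = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    outputs = output_files,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), "run_manifest")
}

#' @rdname run_manifest
#' @param x A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
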