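# Reading, writing and de-duplicating genome collections.
#
# On disk a collection is three files: a metadata TSV, a GFF3 with CDS
# features (1-based inclusive coordinates, `ID` attribute naming the protein)
# and a protein FASTA whose ids match the CDS ids.

#' Read a genome collection from metadata TSV, GFF3 and protein FASTA
#'
#' Cross-references are enforced: every FASTA record must match a CDS `ID`,
#' every CDS must have a sequence, and every GFF3 seqid must appear in the
#' metadata. Missing or empty `host`/`morphology` values default to
#' `"unknown"`. Amino acids outside the 20-letter alphabet are mapped to `X`.
#'
#' @param metadata_path TSV with columns `genome_id`, `taxid`,
#'   `genome_length`, `na_class`, `host`, `morphology`.
#' @param gff_path GFF3 file; only `CDS` features are used.
#' @param fasta_path protein FASTA; ids (first whitespace token) must match
#'   CDS `ID` attributes.
#' @return A validated [new_collection()] `Collection`.
#' @export
read_collection <- function(metadata_path, gff_path, fasta_path) {
  for (f in c(metadata_path, gff_path, fasta_path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  meta <- read_tsv(metadata_path)
  miss <- setdiff(METADATA_COLUMNS, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta$taxid <- as.integer(meta$taxid)
  meta$genome_length <- as.integer(meta$genome_length)
  for (col in c("host", "morphology")) {
    v <- as.character(meta[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    meta[[col]] <- v
  }
  meta$protein_count <- NULL

  check_gff3_coordinates(gff_path)
  gr <- rtracklayer::import(gff_path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  prot <- data.frame(
    protein_id = as.character(gr$ID),
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (nrow(prot) && any(is.na(prot$protein_id))) {
    stop("GFF3 CDS feature without ID attribute")
  }
  orphan_g <- setdiff(prot$genome_id, meta$genome_id)
  if (length(orphan_g)) {
    stop("GFF3 seqid not present in metadata: ", paste(orphan_g, collapse = ", "))
  }

  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  orphan_f <- setdiff(ids, prot$protein_id)
  if (length(orphan_f)) {
    stop("FASTA record with no matching CDS: ", paste(orphan_f, collapse = ", "))
  }
  missing_seq <- setdiff(prot$protein_id, ids)
  if (length(missing_seq)) {
    stop("CDS with no FASTA sequence: ", paste(missing_seq, collapse = ", "))
  }
  prot$sequence <- unname(seqs[match(prot$protein_id, ids)])
  new_collection(meta, prot)
}

# Pre-validate GFF3 coordinate columns so malformed rows are reported with
# their line number (range containers reject them with a less useful message).
check_gff3_coordinates <- function(gff_path) {
  lines <- readLines(gff_path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop("malformed GFF3 record at line ", i)
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) stop("non-numeric GFF3 coordinates at line ", i)
    if (e < s) stop("GFF3 coordinates with end < start at line ", i)
  }
  invisible(TRUE)
}

#' Write a collection to a directory
#'
#' Emits `metadata.tsv`, `genomes.gff3` (with `##gff-version 3` pragma,
#' 1-based inclusive coordinates, CDS features carrying `ID`) and
#' `proteins.faa`. `read_collection()` on the emitted files reproduces the
#' collection field for field.
#'
#' @param collection a `Collection`.
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_collection <- function(collection, out_dir) {
  validate_collection(collection)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(metadata = file.path(out_dir, "metadata.tsv"),
             gff = file.path(out_dir, "genomes.gff3"),
             fasta = file.path(out_dir, "proteins.faa"))

  meta <- collection$genomes[, c(METADATA_COLUMNS, "protein_count")]
  write_tsv(meta, paths[["metadata"]])

  p <- collection$proteins
  if (nrow(p)) {
    gr <- GenomicRanges::GRanges(
      seqnames = p$genome_id,
      ranges = IRanges::IRanges(start = p$start, end = p$end),
      strand = p$strand
    )
    gr$source <- "viranet"
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- p$protein_id
    rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  } else {
    writeLines("##gff-version 3", paths[["gff"]])
  }

  aa <- Biostrings::AAStringSet(setNames(p$sequence, p$protein_id))
  Biostrings::writeXStringSet(aa, paths[["fasta"]], width = 70L)
  invisible(paths)
}

#' De-duplicate a collection by NCBI taxid
#'
#' Keeps exactly one genome per distinct taxid: the one with the largest
#' proteome (CDS count). Ties are broken by larger `genome_length`, then by
#' lexicographically smallest `genome_id`, so the result is deterministic.
#' Proteins of dropped genomes are removed.
#'
#' @param collection a `Collection`.
#' @return A `Collection` with one genome per taxid; the character vector of
#'   dropped `genome_id`s is attached as attribute `"dropped_genomes"` (also
#'   retrievable with [dropped_genomes()]).
#' @export
deduplicate_by_taxid <- function(collection) {
  validate_collection(collection)
  g <- collection$genomes
  if (!nrow(g)) {
    out <- collection
    attr(out, "dropped_genomes") <- character()
    return(out)
  }
  ord <- order(g$taxid, -g$protein_count, -g$genome_length, g$genome_id)
  g_ord <- g[ord, , drop = FALSE]
  keep <- g_ord$genome_id[!duplicated(g_ord$taxid)]
  dropped <- setdiff(g$genome_id, keep)
  genomes <- g[g$genome_id %in% keep, , drop = FALSE]
  proteins <- collection$proteins[collection$proteins$genome_id %in% keep, , drop = FALSE]
  out <- new_collection(genomes[, c(METADATA_COLUMNS)], proteins)
  attr(out, "dropped_genomes") <- dropped
  out
}

#' Genomes dropped by the last de-duplication
#' @param collection a `Collection` returned by [deduplicate_by_taxid()].
#' @return Character vector of dropped genome ids (possibly empty).
#' @export
dropped_genomes <- function(collection) {
  attr(collection, "dropped_genomes") %||% character()
}
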