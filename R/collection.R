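# The in-memory data model: a Collection holds one genome metadata table and
# one protein table, the shared substrate of every downstream stage.

NA_CLASSES  <- c("dsDNA", "ssDNA", "dsRNA", "ssRNA_pos", "ssRNA_neg", "retro")
HOSTS       <- c("bacteria", "archaea", "eukaryote", "unknown")
MORPHOLOGIES <- c("myovirus", "siphovirus", "podovirus", "other", "unknown")

METADATA_COLUMNS <- c("genome_id", "taxid", "genome_length", "na_class",
                      "host", "morphology")

#' Construct a genome collection
#'
#' Bundles a genome metadata table and a protein table into a validated
#' `Collection`. Proteins are sorted by start coordinate within each genome
#' and `protein_count` is recomputed from the protein table.
#'
#' @param genomes data.frame with columns `genome_id`, `taxid`,
#'   `genome_length` (bp), `na_class`, `host`, `morphology`.
#' @param proteins data.frame with columns `protein_id`, `genome_id`,
#'   `start`, `end` (1-based inclusive bp), `strand` (`+`/`-`), `sequence`
#'   (amino acids; letters outside the 20-letter alphabet are mapped to `X`).
#' @return An object of class `Collection`: a list with elements `genomes`
#'   and `proteins`.
#' @export
new_collection <- function(genomes, proteins = NULL) {
  genomes <- as.data.frame(genomes, stringsAsFactors = FALSE)
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = character(), genome_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), sequence = character(),
                           stringsAsFactors = FALSE)
  }
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (nrow(proteins)) {
    proteins$sequence <- clean_aa(proteins$sequence)
    proteins <- proteins[order(match(proteins$genome_id, genomes$genome_id),
                               proteins$start), , drop = FALSE]
    rownames(proteins) <- NULL
  }
  counts <- table(factor(proteins$genome_id, levels = genomes$genome_id))
  genomes$protein_count <- as.integer(counts[genomes$genome_id])
  rownames(genomes) <- NULL
  obj <- structure(list(genomes = genomes, proteins = proteins),
                   class = "Collection")
  validate_collection(obj)
  obj
}

clean_aa <- function(x) {
  gsub(sprintf("[^%sX]", paste(AA20, collapse = "")), "X", toupper(x))
}

#' Validate a Collection's invariants
#'
#' Checks id uniqueness, positive genome lengths, coordinate sanity
#' (`end >= start`), non-empty sequences, cross-references between proteins
#' and genomes, and per-genome sorting by start.
#'
#' @param x a `Collection`.
#' @return `x`, invisibly; stops with an informative error on violation.
#' @export
validate_collection <- function(x) {
  stopifnot(inherits(x, "Collection"))
  g <- x$genomes; p <- x$proteins
  miss <- setdiff(METADATA_COLUMNS, names(g))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(g$genome_id)) stop("duplicate genome_id in collection")
  if (any(g$genome_length <= 0)) stop("genome_length must be positive")
  bad <- !g$na_class %in% NA_CLASSES
  if (any(bad)) stop("unknown na_class: ", paste(unique(g$na_class[bad]), collapse = ", "))
  if (nrow(p)) {
    if (anyDuplicated(p$protein_id)) stop("duplicate protein_id in collection")
    if (any(p$end < p$start)) {
      stop("protein coordinates with end < start: ",
           paste(head(p$protein_id[p$end < p$start], 3L), collapse = ", "))
    }
    if (any(nchar(p$sequence) < 1L)) stop("empty protein sequence")
    orphan <- setdiff(p$genome_id, g$genome_id)
    if (length(orphan)) {
      stop("proteins reference unknown genome_id: ", paste(orphan, collapse = ", "))
    }
    for (gid in unique(p$genome_id)) {
      s <- p$start[p$genome_id == gid]
      if (is.unsorted(s)) stop("proteins of genome ", gid, " not sorted by start")
    }
  }
  invisible(x)
}

#' @export
print.Collection <- function(x, ...) {
  cat(sprintf("Collection: %d genomes, %d proteins\n",
              nrow(x$genomes), nrow(x$proteins)))
  if (nrow(x$genomes)) {
    cat("  na_class:", paste(sprintf("%s=%d", names(table(x$genomes$na_class)),
                                     table(x$genomes$na_class)), collapse = " "), "\n")
  }
  invisible(x)
}
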