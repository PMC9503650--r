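# Domain architectures, gene neighborhoods and conserved-context mining.
#
# A neighborhood is the run of genes around an anchor, walked outward up to a
# window and truncated at the first inter-gene gap exceeding the cutoff
# (100 nt by default, an operon proxy). Gaps are next.start - prev.end - 1 on
# 1-based inclusive coordinates; a negative gap (overlapping genes) counts as
# 0 and passes the filter. Neighborhoods are canonicalized so the anchor is
# always on the + strand.

#' Resolve domain architectures from a hit table
#'
#' Per protein, hits are retained greedily by descending score; a hit is
#' dropped if it overlaps an already-retained hit by more than `overlap_frac`
#' of the shorter span. Survivors are reported in order of `ali_start`.
#'
#' @param hits data.frame with `protein_id`, `family_id`, `ali_start`,
#'   `ali_end`, `score`.
#' @param overlap_frac maximum tolerated overlap as a fraction of the shorter
#'   span (default 0.5).
#' @return A data.frame with `protein_id`, `n_domains`, `architecture`
#'   (families joined with `+`). The retained hits are attached as attribute
#'   `"retained_hits"`.
#' @export
detect_architectures <- function(hits, overlap_frac = 0.5) {
  if (!nrow(hits)) {
    out <- data.frame(protein_id = character(), n_domains = integer(),
                      architecture = character(), stringsAsFactors = FALSE)
    attr(out, "retained_hits") <- hits
    return(out)
  }
  kept <- lapply(split(hits, hits$protein_id), function(h) {
    h <- h[order(-h$score, h$ali_start, h$family_id), , drop = FALSE]
    retained <- h[0, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      cand <- h[i, ]
      ok <- TRUE
      for (j in seq_len(nrow(retained))) {
        ov <- min(cand$ali_end, retained$ali_end[j]) -
          max(cand$ali_start, retained$ali_start[j]) + 1L
        shorter <- min(cand$ali_end - cand$ali_start,
                       retained$ali_end[j] - retained$ali_start[j]) + 1L
        if (ov > overlap_frac * shorter) { ok <- FALSE; break }
      }
      if (ok) retained <- rbind(retained, cand)
    }
    retained[order(retained$ali_start), , drop = FALSE]
  })
  retained_hits <- do.call(rbind, kept)
  rownames(retained_hits) <- NULL
  arch <- vapply(kept, function(h) paste(h$family_id, collapse = "+"), character(1))
  out <- data.frame(protein_id = names(kept),
                    n_domains = vapply(kept, nrow, integer(1)),
                    architecture = unname(arch), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_hits") <- retained_hits
  out
}

#' Extract gene neighborhoods around anchor proteins
#'
#' Walks outward from each anchor up to `window` genes on each side, stopping
#' a side when the next inter-gene gap exceeds `gap_cutoff`. Strands are
#' recorded relative to the anchor; if the anchor is on the minus strand, the
#' member order and relative strands are flipped so the canonical anchor
#' strand is always `+` (the flip is an involution).
#'
#' @param collection a `Collection`.
#' @param anchors character vector of anchor protein ids.
#' @param window maximum genes per side (default 5).
#' @param gap_cutoff inter-gene distance cutoff in nt (default 100).
#' @return A data.frame with one row per neighborhood member: `anchor`
#'   (anchor protein id), `genome_id`, `protein_id`, `offset` (canonical
#'   signed gene offset, 0 = anchor), `rel_strand` (`+` if same strand as the
#'   anchor), `gap_prev` (nt gap to the previous member in canonical order;
#'   `NA` for the first member).
#' @export
extract_neighborhoods <- function(collection, anchors, window = 5L,
                                  gap_cutoff = 100L) {
  p <- collection$proteins
  missing <- setdiff(anchors, p$protein_id)
  if (length(missing)) {
    stop("anchor not in collection: ", paste(head(missing, 3L), collapse = ", "))
  }
  out <- vector("list", length(anchors))
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    row <- which(p$protein_id == a)
    gid <- p$genome_id[row]
    gp <- p[p$genome_id == gid, , drop = FALSE]   # sorted by start
    ai <- which(gp$protein_id == a)
    gaps <- gp$start[-1] - gp$end[-nrow(gp)] - 1L  # gap[i] between gene i and i+1
    gaps <- pmax(gaps, 0L)
    lo <- ai
    while (lo > 1L && (ai - lo) < window && gaps[lo - 1L] <= gap_cutoff) lo <- lo - 1L
    hi <- ai
    while (hi < nrow(gp) && (hi - ai) < window && gaps[hi] <= gap_cutoff) hi <- hi + 1L
    idx <- lo:hi
    member_gaps <- c(NA_integer_, gaps[idx[-length(idx)]])
    offs <- idx - ai
    rel <- ifelse(gp$strand[idx] == gp$strand[ai], "+", "-")
    if (gp$strand[ai] == "-") {   # canonicalize: flip order and offsets
      ord <- rev(seq_along(idx))
      idx <- idx[ord]
      offs <- -offs[ord]
      rel <- rel[ord]
      member_gaps <- c(NA_integer_, rev(member_gaps[-1L]))
    }
    out[[k]] <- data.frame(
      anchor = a, genome_id = gid, protein_id = gp$protein_id[idx],
      offset = offs, rel_strand = rel, gap_prev = member_gaps,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mine conserved gene-neighborhood contexts
#'
#' For every (anchor family, partner family) pair co-occurring in a
#' neighborhood, accumulates the supporting genomes and emits pairs with
#' `support >= min_support` distinct genomes spanning
#' `distinct_taxa >= min_taxa` distinct taxids (the phyletic-pattern filter:
#' support must not come from one clonal cluster). Orientation is reported as
#' `same_strand` or `opposite` when at least `orientation_consensus` of the
#' supporting instances agree, otherwise `any`.
#'
#' @param neighborhoods output of [extract_neighborhoods()].
#' @param annotations data.frame with `protein_id`, `family` (one row per
#'   domain annotation).
#' @param genomes genome metadata data.frame with `genome_id`, `taxid`.
#' @param min_support minimum supporting genomes (default 3).
#' @param min_taxa minimum distinct taxids among supporting genomes
#'   (default 2).
#' @param orientation_consensus agreement fraction for calling an orientation
#'   (default 0.8).
#' @return A data.frame of class rows: `anchor_family`, `partner_family`,
#'   `orientation`, `support`, `distinct_taxa`, `genome_ids`
#'   (comma-separated).
#' @export
mine_contexts <- function(neighborhoods, annotations, genomes,
                          min_support = 3L, min_taxa = 2L,
                          orientation_consensus = 0.8) {
  empty <- data.frame(anchor_family = character(), partner_family = character(),
                      orientation = character(), support = integer(),
                      distinct_taxa = integer(), genome_ids = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(neighborhoods) || !nrow(annotations)) return(empty)
  ann <- split(annotations$family, annotations$protein_id)
  inst <- list()
  for (nb in split(neighborhoods, neighborhoods$anchor)) {
    a <- nb$anchor[1]
    af <- ann[[a]]
    if (is.null(af)) next
    others <- nb[nb$protein_id != a, , drop = FALSE]
    if (!nrow(others)) next
    for (i in seq_len(nrow(others))) {
      pf <- ann[[others$protein_id[i]]]
      if (is.null(pf)) next
      for (fa in unique(af)) for (fp in unique(pf)) {
        inst[[length(inst) + 1L]] <- data.frame(
          anchor_family = fa, partner_family = fp,
          genome_id = nb$genome_id[1],
          same_strand = others$rel_strand[i] == "+",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(inst)) return(empty)
  inst <- do.call(rbind, inst)
  inst$taxid <- genomes$taxid[match(inst$genome_id, genomes$genome_id)]
  key <- paste(inst$anchor_family, inst$partner_family, sep = "\r")
  rows <- lapply(split(inst, key), function(d) {
    sup_genomes <- sort(unique(d$genome_id))
    frac_same <- mean(d$same_strand)
    orientation <- if (frac_same >= orientation_consensus) "same_strand"
      else if (1 - frac_same >= orientation_consensus) "opposite"
      else "any"
    data.frame(anchor_family = d$anchor_family[1],
               partner_family = d$partner_family[1],
               orientation = orientation,
               support = length(sup_genomes),
               distinct_taxa = length(unique(d$taxid)),
               genome_ids = paste(sup_genomes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$support >= min_support & res$distinct_taxa >= min_taxa, ,
             drop = FALSE]
  res <- res[order(-res$support, res$anchor_family, res$partner_family), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Query loci where a target family lacks coupled partner families
#'
#' Returns every locus where a protein annotated with one of
#' `target_families` has no member of `excluded_partner_families` in its
#' filtered neighborhood (including fusions on the target protein itself).
#' Each reported locus lists what *is* in the neighborhood, for downstream
#' inspection of the accreted variable genes.
#'
#' @param collection a `Collection`.
#' @param annotations data.frame with `protein_id`, `family`.
#' @param target_families families whose loci are examined.
#' @param excluded_partner_families families whose presence disqualifies a
#'   locus.
#' @param window,gap_cutoff neighborhood parameters as in
#'   [extract_neighborhoods()].
#' @return A data.frame with `genome_id`, `protein_id`, `target_family`,
#'   `n_neighbors`, `neighbor_families` (comma-separated; empty string if
#'   none annotated).
#' @export
absence_query <- function(collection, annotations, target_families,
                          excluded_partner_families, window = 5L,
                          gap_cutoff = 100L) {
  empty <- data.frame(genome_id = character(), protein_id = character(),
                      target_family = character(), n_neighbors = integer(),
                      neighbor_families = character(), stringsAsFactors = FALSE)
  tgt <- annotations[annotations$family %in% target_families, , drop = FALSE]
  if (!nrow(tgt)) return(empty)
  nbs <- extract_neighborhoods(collection, unique(tgt$protein_id),
                               window = window, gap_cutoff = gap_cutoff)
  ann <- split(annotations$family, annotations$protein_id)
  rows <- list()
  for (i in seq_len(nrow(tgt))) {
    a <- tgt$protein_id[i]
    nb <- nbs[nbs$anchor == a, , drop = FALSE]
    fams_here <- unlist(ann[nb$protein_id], use.names = FALSE)
    self_fams <- ann[[a]]
    if (any(c(fams_here, self_fams) %in% excluded_partner_families)) next
    others <- nb$protein_id[nb$protein_id != a]
    nb_fams <- sort(unique(unlist(ann[others], use.names = FALSE)))
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = nb$genome_id[1], protein_id = a,
      target_family = tgt$family[i], n_neighbors = length(others),
      neighbor_families = paste(nb_fams, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
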