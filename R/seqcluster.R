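# Protein family clustering by pairwise alignment score density.
#
# Pairs are scored with Smith-Waterman local alignment (affine gaps, BLOSUM62
# by default), converted to bit scores with fixed Karlin-Altschul constants,
# and connected when the bit-score density (bits per aligned column) and
# alignment coverage pass thresholds. Families are the connected components
# (single linkage). Small clusters can then be merged into larger ones on
# independent evidence: reciprocal best hits, shared profile annotations, or
# shared conserved genome context.

#' Scoring and clustering parameters
#'
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap costs; a gap of length `k` costs
#'   `gap_open + k * gap_extend`.
#' @param lambda_,K bit-score conversion constants
#'   (`bit = (lambda_ * raw - ln K) / ln 2`); defaults are the published
#'   gapped-BLOSUM62 constants 0.267 and 0.041.
#' @param density_threshold minimum bit-score density (bits per aligned
#'   column) for an edge.
#' @param coverage_threshold minimum aligned fraction for an edge.
#' @param coverage_mode `"both"` (both sequences must reach coverage) or
#'   `"shorter"` (only the shorter one must).
#' @return A list of class `ScoringParams`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda_ = 0.267, K = 0.041,
                           density_threshold = 0.8, coverage_threshold = 0.6,
                           coverage_mode = c("both", "shorter")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(lambda_ > 0, K > 0, gap_open > 0, gap_extend > 0,
            density_threshold > 0,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda_ = lambda_, K = K,
                 density_threshold = density_threshold,
                 coverage_threshold = coverage_threshold,
                 coverage_mode = coverage_mode),
            class = "ScoringParams")
}

raw_to_bits <- function(raw, params) {
  (params$lambda_ * raw - log(params$K)) / log(2)
}

#' Score one sequence pair
#'
#' Smith-Waterman local alignment with affine gaps; the raw score is converted
#' to bits, and coverage of each sequence is the number of its residues inside
#' the alignment divided by its length.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param params a [scoring_params()].
#' @return A list of class `PairScore`: `raw_score`, `bit_score`,
#'   `aligned_cols` (alignment columns including gaps), `coverage_a`,
#'   `coverage_b`, `density` (bits per aligned column).
#' @export
pairwise_score <- function(seq_a, seq_b, params = scoring_params()) {
  stopifnot(nchar(seq_a) >= 1, nchar(seq_b) >= 1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  pair_score_from_alignment(aln, nchar(seq_a), nchar(seq_b), params)
}

pair_score_from_alignment <- function(aln, len_a, len_b, params) {
  raw <- Biostrings::score(aln)
  cols <- Biostrings::nchar(aln)  # alignment columns including gaps
  cov_a <- IRanges::width(Biostrings::pattern(aln)) / len_a
  cov_b <- IRanges::width(Biostrings::subject(aln)) / len_b
  bit <- raw_to_bits(raw, params)
  structure(list(raw_score = raw, bit_score = bit,
                 aligned_cols = as.integer(cols),
                 coverage_a = cov_a, coverage_b = cov_b,
                 density = bit / cols),
            class = "PairScore")
}

# All-vs-all pair table: one vectorized alignment call over all i < j pairs.
all_pair_scores <- function(seqs, params) {
  ids <- names(seqs)
  n <- length(seqs)
  if (n < 2) {
    return(data.frame(id_a = character(), id_b = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      aligned_cols = integer(), coverage_a = numeric(),
                      coverage_b = numeric(), density = numeric(),
                      stringsAsFactors = FALSE))
  }
  aa <- Biostrings::AAStringSet(seqs)
  idx <- utils::combn(n, 2L)
  aln <- Biostrings::pairwiseAlignment(
    aa[idx[1, ]], aa[idx[2, ]], type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(aln)
  cols <- as.integer(Biostrings::nchar(aln))
  bit <- raw_to_bits(raw, params)
  data.frame(
    id_a = ids[idx[1, ]], id_b = ids[idx[2, ]], raw_score = raw,
    bit_score = bit, aligned_cols = cols,
    coverage_a = IRanges::width(Biostrings::pattern(aln)) / nchar(seqs[idx[1, ]]),
    coverage_b = IRanges::width(Biostrings::subject(aln)) / nchar(seqs[idx[2, ]]),
    density = bit / cols, stringsAsFactors = FALSE, row.names = NULL
  )
}

passes_edge <- function(pairs, params) {
  cov_ok <- switch(params$coverage_mode,
    both = pmin(pairs$coverage_a, pairs$coverage_b) >= params$coverage_threshold,
    shorter = ifelse(pairs$len_a_shorter,
                     pairs$coverage_a, pairs$coverage_b) >= params$coverage_threshold
  )
  pairs$density >= params$density_threshold & cov_ok
}

#' Cluster proteins into families by single linkage
#'
#' Computes all-vs-all local alignments, draws an edge between two sequences
#' when the bit-score density and coverage criteria pass, and reports
#' connected components. Cluster ids are assigned in order of each cluster's
#' lexicographically smallest member, so the output is invariant under input
#' order.
#'
#' @param seqs named character vector of protein sequences.
#' @param params a [scoring_params()].
#' @return A data.frame with `cluster_id`, `protein_id`, `is_representative`
#'   (representative = longest member, ties broken by smallest id). The
#'   passing-pair edge list is attached as attribute `"edges"`.
#' @export
cluster_proteins <- function(seqs, params = scoring_params()) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  ids <- sort(names(seqs))
  seqs <- seqs[ids]
  pairs <- all_pair_scores(seqs, params)
  if (nrow(pairs)) {
    pairs$len_a_shorter <- nchar(seqs[pairs$id_a]) <= nchar(seqs[pairs$id_b])
    edges <- pairs[passes_edge(pairs, params), c("id_a", "id_b"), drop = FALSE]
  } else {
    edges <- data.frame(id_a = character(), id_b = character())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- members[order(vapply(members, min, character(1)))]
  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    m <- sort(members[[k]])
    lens <- nchar(seqs[m])
    rep_id <- m[order(-lens, m)][1]
    data.frame(cluster_id = sprintf("C%04d", k), protein_id = m,
               is_representative = m == rep_id, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  out
}

#' Merge clusters on independent lines of evidence
#'
#' Two clusters are merged when (a) their representatives are reciprocal best
#' hits with pairwise E-value at most `merge_E` (E is the Karlin-Altschul
#' search-space estimate `len_a * len_b * 2^-bit`), (b) at least `merge_frac`
#' of both clusters' members carry the same profile `family_id` in `hits`, or
#' (c) both clusters have the same non-empty conserved-context signature (the
#' set of partner families their annotated families associate with in
#' `contexts`). Merging is transitive; an audit log of merges and their
#' evidence class is attached as attribute `"merge_log"`.
#'
#' @param clusters output of [cluster_proteins()].
#' @param seqs the named sequences that were clustered.
#' @param hits optional hit table with `protein_id`, `family_id`.
#' @param contexts optional context table with `anchor_family`,
#'   `partner_family`.
#' @param params a [scoring_params()].
#' @param merge_E reciprocal-best-hit E-value ceiling (default 1e-3).
#' @param merge_frac member annotation agreement fraction (default 0.5).
#' @return A data.frame in the same shape as [cluster_proteins()].
#' @export
merge_clusters <- function(clusters, seqs, hits = NULL, contexts = NULL,
                           params = scoring_params(), merge_E = 1e-3,
                           merge_frac = 0.5) {
  cl_ids <- sort(unique(clusters$cluster_id))
  n <- length(cl_ids)
  log_rows <- list()
  if (n >= 2) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j, evidence) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        parent[max(ri, rj)] <<- min(ri, rj)
        log_rows[[length(log_rows) + 1L]] <<- data.frame(
          from_cluster = cl_ids[max(ri, rj)], into_cluster = cl_ids[min(ri, rj)],
          evidence = evidence, stringsAsFactors = FALSE
        )
      }
    }

    # (a) reciprocal best hits among representatives
    reps <- clusters$protein_id[clusters$is_representative]
    reps <- reps[match(cl_ids, clusters$cluster_id[clusters$is_representative])]
    if (n >= 2) {
      rep_seqs <- seqs[reps]
      pairs <- all_pair_scores(setNames(rep_seqs, cl_ids), params)
      pairs$evalue <- nchar(rep_seqs[match(pairs$id_a, cl_ids)]) *
        nchar(rep_seqs[match(pairs$id_b, cl_ids)]) * 2^(-pairs$bit_score)
      sym <- rbind(pairs[, c("id_a", "id_b", "bit_score", "evalue")],
                   setNames(pairs[, c("id_b", "id_a", "bit_score", "evalue")],
                            c("id_a", "id_b", "bit_score", "evalue")))
      best <- sym[order(sym$id_a, -sym$bit_score), ]
      best <- best[!duplicated(best$id_a), ]
      bb <- setNames(best$id_b, best$id_a)
      for (i in seq_len(nrow(best))) {
        a <- best$id_a[i]; b <- best$id_b[i]
        if (bb[[b]] == a && best$evalue[i] <= merge_E) {
          union_(match(a, cl_ids), match(b, cl_ids), "reciprocal_best_hit")
        }
      }
    }

    # (b) shared profile-annotation majority
    if (!is.null(hits) && nrow(hits)) {
      fam_frac <- function(cid, fam) {
        m <- clusters$protein_id[clusters$cluster_id == cid]
        mean(m %in% hits$protein_id[hits$family_id == fam])
      }
      fams <- unique(hits$family_id)
      for (fam in fams) {
        carriers <- cl_ids[vapply(cl_ids, fam_frac, numeric(1), fam = fam) >= merge_frac]
        if (length(carriers) >= 2) {
          for (k in 2:length(carriers)) {
            union_(match(carriers[1], cl_ids), match(carriers[k], cl_ids),
                   "shared_profile_annotation")
          }
        }
      }
    }

    # (c) identical conserved-context signature
    if (!is.null(contexts) && nrow(contexts) && !is.null(hits) && nrow(hits)) {
      signature <- vapply(cl_ids, function(cid) {
        m <- clusters$protein_id[clusters$cluster_id == cid]
        fams <- unique(hits$family_id[hits$protein_id %in% m])
        partners <- sort(unique(contexts$partner_family[contexts$anchor_family %in% fams]))
        paste(partners, collapse = "+")
      }, character(1))
      for (sig in unique(signature[nzchar(signature)])) {
        grp <- cl_ids[signature == sig]
        if (length(grp) >= 2) {
          for (k in 2:length(grp)) {
            union_(match(grp[1], cl_ids), match(grp[k], cl_ids),
                   "shared_context_signature")
          }
        }
      }
    }

    root <- vapply(seq_len(n), find, integer(1))
    clusters$cluster_id <- cl_ids[root[match(clusters$cluster_id, cl_ids)]]
  }

  # renumber and recompute representatives
  members <- split(clusters$protein_id, clusters$cluster_id)
  members <- members[order(vapply(members, min, character(1)))]
  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    m <- sort(members[[k]])
    lens <- nchar(seqs[m])
    rep_id <- m[order(-lens, m)][1]
    data.frame(cluster_id = sprintf("C%04d", k), protein_id = m,
               is_representative = m == rep_id, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "merge_log") <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(from_cluster = character(), into_cluster = character(),
               evidence = character(), stringsAsFactors = FALSE)
  out
}
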