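# Profile scanning with empirical E-values and iterative profile inclusion.
#
# Scoring is an ungapped sliding window: the hit score is the maximum over all
# offsets of the summed per-column log-odds, so hit spans always have the
# profile's length. Significance is empirical: decoy proteins drawn from the
# background composition are scanned with the same profile, and E(s) is the
# expected number of decoy best-scores >= s, scaled to the database size.

#' Scan one protein with a profile
#'
#' @param profile a `Profile`.
#' @param sequence amino-acid string (or integer codes).
#' @param protein_id optional id carried into the result.
#' @return A list with `score` (half-bits), `ali_start`, `ali_end` (1-based
#'   inclusive). Proteins shorter than the profile give `score = -Inf` and
#'   `NA` span.
#' @export
scan_protein <- function(profile, sequence, protein_id = NA_character_) {
  codes <- if (is.numeric(sequence)) as.integer(sequence) else encode_aa(sequence)
  res <- scan_best_cpp(lo21(profile), list(codes))
  if (!is.finite(res$score[1])) {
    return(list(protein_id = protein_id, score = -Inf,
                ali_start = NA_integer_, ali_end = NA_integer_))
  }
  list(protein_id = protein_id, score = res$score[1],
       ali_start = res$start[1],
       ali_end = res$start[1] + profile$length - 1L)
}

#' All window scores of a protein against a profile
#'
#' Exposed mainly for diagnostics; [scan_protein()] is the maximum of this
#' vector.
#'
#' @inheritParams scan_protein
#' @return Numeric vector of window scores (length `nchar - m + 1`; empty if
#'   the protein is shorter than the profile).
#' @export
window_scores <- function(profile, sequence) {
  codes <- if (is.numeric(sequence)) as.integer(sequence) else encode_aa(sequence)
  window_scores_cpp(lo21(profile), codes)
}

#' Calibrate an empirical null model for a profile
#'
#' Draws `n_decoys` i.i.d. background decoy proteins of length
#' `decoy_length`, scans each, and stores the sorted best scores. E-values are
#' `database_size * (k + 1) / (n_decoys + 1)` where `k` is the number of decoy
#' best-scores at or above the query score; the +1 smoothing keeps E > 0.
#'
#' @param profile a `Profile`.
#' @param database_size number of proteins in the searched database (the scale
#'   of the E-value).
#' @param n_decoys number of decoys (>= 100).
#' @param decoy_length decoy protein length (>= profile length).
#' @param seed RNG seed for the decoy draw.
#' @param background background frequencies; defaults to the profile's.
#' @return An object of class `NullModel`.
#' @export
calibrate_null <- function(profile, database_size, n_decoys = 2000L,
                           decoy_length = 250L, seed = 1L,
                           background = NULL) {
  stopifnot(n_decoys >= 100L)
  bg <- background %||% profile$background
  bg <- bg / sum(bg)
  if (decoy_length < profile$length) {
    stop("decoy_length must be at least the profile length")
  }
  scores <- with_seed(seed, decoy_max_scores_cpp(lo21(profile), as.integer(n_decoys),
                                                 as.integer(decoy_length), cumsum(bg)))
  structure(list(
    family_id = profile$family_id,
    decoy_scores = sort(scores),
    n_decoys = as.integer(n_decoys),
    database_size = as.integer(database_size),
    decoy_length = as.integer(decoy_length)
  ), class = "NullModel")
}

#' Empirical E-value of one or more scores
#'
#' @param null a `NullModel` from [calibrate_null()].
#' @param score numeric vector of scores in half-bits.
#' @return Numeric vector of E-values (expected decoy hits at that score or
#'   better in a database of `database_size` proteins).
#' @export
evalue <- function(null, score) {
  d <- null$decoy_scores
  n <- null$n_decoys
  k <- n - findInterval(score, d, left.open = TRUE)  # decoys >= score
  null$database_size * (k + 1) / (n + 1)
}

#' Iterative profile search over a protein collection
#'
#' Implements profile-inclusion iteration: scan all proteins with the seed
#' profile, include every hit with E-value at or below `inclusion_E`, add the
#' matched (ungapped) segments to the alignment with uniform weight, rebuild
#' the profile, recalibrate the null, and repeat until the included set stops
#' growing or `max_iter` is reached. The included set only ever grows, so the
#' procedure terminates. Each hit records the iteration at which it first
#' passed, with the score and E-value from that iteration.
#'
#' @param profile seed `Profile`.
#' @param proteins a `Collection`, a data.frame with `protein_id` and
#'   `sequence`, or a named character vector of sequences.
#' @param inclusion_E profile-inclusion E-value threshold (default 0.01).
#' @param max_iter maximum iterations (default 5).
#' @param n_decoys decoys per calibration; default scales with the database so
#'   that E-values at `inclusion_E` are resolvable:
#'   `max(1999, ceiling(1.2 * database_size / inclusion_E))`.
#' @param decoy_length decoy length; default the median protein length
#'   (at least the profile length).
#' @param seed RNG seed for decoy calibration (one substream per iteration).
#' @return A list with `hits` (data.frame: protein_id, family_id, ali_start,
#'   ali_end, score, e_value, iteration), `candidates` (borderline tier with
#'   `inclusion_E < E <= 10 * inclusion_E` at the final iteration), `n_iter`,
#'   `converged`, and the final `profile`.
#' @export
iterative_search <- function(profile, proteins, inclusion_E = 0.01,
                             max_iter = 5L, n_decoys = NULL,
                             decoy_length = NULL, seed = 1L) {
  pr <- as_protein_table(proteins)
  db <- nrow(pr)
  if (db == 0L) {
    return(list(hits = empty_hit_table(), candidates = empty_hit_table(),
                n_iter = 0L, converged = TRUE, profile = profile))
  }
  n_decoys <- n_decoys %||% max(1999L, as.integer(ceiling(1.2 * db / inclusion_E)))
  decoy_length <- decoy_length %||% max(profile$length,
                                        as.integer(round(median(nchar(pr$sequence)))))
  codes <- lapply(pr$sequence, encode_aa)

  cur <- profile
  included <- integer(0)
  segments <- character(0)
  rec <- list()
  converged <- FALSE
  iter <- 0L
  final_E <- NULL
  sc_last <- NULL
  lo_last <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    null <- calibrate_null(cur, database_size = db, n_decoys = n_decoys,
                           decoy_length = decoy_length,
                           seed = (seed %% 1000000L) * 10L + iter)
    sc <- scan_best_cpp(lo21(cur), codes)
    E <- evalue(null, sc$score)
    final_E <- E
    sc_last <- sc
    lo_last <- cur$length
    new_idx <- setdiff(which(E <= inclusion_E & is.finite(sc$score)), included)
    if (length(new_idx)) {
      rec[[iter]] <- data.frame(
        protein_id = pr$protein_id[new_idx],
        family_id = profile$family_id,
        ali_start = sc$start[new_idx],
        ali_end = sc$start[new_idx] + cur$length - 1L,
        score = sc$score[new_idx],
        e_value = E[new_idx],
        iteration = iter,
        stringsAsFactors = FALSE
      )
      included <- c(included, new_idx)
    } else {
      converged <- TRUE
      break
    }
    segments <- c(segments, substr(pr$sequence[new_idx], sc$start[new_idx],
                                   sc$start[new_idx] + cur$length - 1L))
    cur <- profile_from_rows(c(profile$match_rows, segments),
                             profile$pseudocount_weight, profile$background,
                             profile$family_id)
  }
  hits <- if (length(rec)) do.call(rbind, rec) else empty_hit_table()
  rownames(hits) <- NULL
  cand_idx <- setdiff(which(final_E > inclusion_E & final_E <= 10 * inclusion_E &
                              is.finite(sc_last$score)),
                      included)
  candidates <- if (length(cand_idx)) data.frame(
    protein_id = pr$protein_id[cand_idx],
    family_id = profile$family_id,
    ali_start = sc_last$start[cand_idx],
    ali_end = sc_last$start[cand_idx] + lo_last - 1L,
    score = sc_last$score[cand_idx],
    e_value = final_E[cand_idx],
    iteration = iter,
    stringsAsFactors = FALSE
  ) else empty_hit_table()
  list(hits = hits, candidates = candidates, n_iter = iter,
       converged = converged, profile = cur)
}

empty_hit_table <- function() {
  data.frame(protein_id = character(), family_id = character(),
             ali_start = integer(), ali_end = integer(), score = numeric(),
             e_value = numeric(), iteration = integer(),
             stringsAsFactors = FALSE)
}

as_protein_table <- function(proteins) {
  if (inherits(proteins, "Collection")) {
    return(proteins$proteins[, c("protein_id", "sequence")])
  }
  if (is.data.frame(proteins)) {
    stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
    return(proteins[, c("protein_id", "sequence")])
  }
  if (is.character(proteins)) {
    ids <- names(proteins) %||% as.character(seq_along(proteins))
    return(data.frame(protein_id = ids, sequence = unname(proteins),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret 'proteins'")
}

#' Scan a collection with several family profiles
#'
#' Runs [iterative_search()] per family and binds the hit tables. Borderline
#' candidates are collected separately.
#'
#' @param profiles named list of `Profile` objects.
#' @param collection a `Collection` (or anything [iterative_search()] accepts).
#' @param ... passed to [iterative_search()].
#' @param seed base RNG seed; each family uses a seed derived from its name.
#' @return List with `hits`, `candidates` (bound data.frames) and `reports`
#'   (per family: n_iter, converged).
#' @export
scan_collection <- function(profiles, collection, seed = 1L, ...) {
  hits <- list(); cands <- list(); reports <- list()
  for (fam in names(profiles)) {
    res <- iterative_search(profiles[[fam]], collection,
                            seed = (seed + string_seed(fam)) %% .Machine$integer.max,
                            ...)
    hits[[fam]] <- res$hits
    cands[[fam]] <- res$candidates
    reports[[fam]] <- data.frame(family_id = fam, n_iter = res$n_iter,
                                 converged = res$converged, n_hits = nrow(res$hits),
                                 stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, c(hits, list(empty_hit_table()))),
       candidates = do.call(rbind, c(cands, list(empty_hit_table()))),
       reports = do.call(rbind, reports))
}
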