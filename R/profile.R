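# Position-specific scoring profiles built from seed alignments.
#
# A profile stores per-column emission probabilities and log-odds scores in
# half-bits: log_odds[i, a] = 2 * log2(emission[i, a] / background[a]).

GAP_CHARS <- c("-", ".")

#' Read an aligned FASTA seed alignment
#'
#' @param path aligned FASTA (all records the same width; `-` or `.` as gap).
#' @return Named character vector of aligned rows.
#' @export
read_seed_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(rows))) > 1L) {
    stop("seed alignment rows have unequal widths: ", path)
  }
  rows
}

#' Write a seed alignment as aligned FASTA
#' @param rows named character vector of equal-width aligned rows.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seed_alignment <- function(rows, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(rows), path, width = 70L)
  invisible(path)
}

#' Build a scoring profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped (match-column rule). Per match
#' column, emissions are `(counts + pseudocount_weight * background) /
#' (n + pseudocount_weight)` where `n` is the number of residues observed in
#' that column (gaps and `X` contribute no counts); sequences are weighted
#' uniformly. Log-odds are reported in half-bits.
#'
#' @param seed_alignment named character vector of equal-width aligned rows
#'   (as from [read_seed_alignment()]), or an `AAStringSet`.
#' @param pseudocount_weight non-negative scalar weight on the background
#'   pseudocounts (default 1).
#' @param background residue background frequencies; default [aa_background()].
#' @param family_id family label carried into hits.
#' @return An object of class `Profile`.
#' @export
build_profile <- function(seed_alignment, pseudocount_weight = 1,
                          background = aa_background(), family_id = "family") {
  rows <- as_alignment_rows(seed_alignment)
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  gap_frac <- colMeans(matrix(mat %in% GAP_CHARS, nrow = nrow(mat)))
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("no match columns (all columns > 50% gaps)")
  mat <- mat[, keep, drop = FALSE]
  rows_match <- apply(mat, 1L, paste, collapse = "")
  profile_from_rows(rows_match, pseudocount_weight, background, family_id)
}

as_alignment_rows <- function(x) {
  if (methods::is(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x) || length(x) < 1L) stop("empty seed alignment")
  if (length(unique(nchar(x))) > 1L) stop("aligned rows have unequal widths")
  x
}

# Core builder over match columns only (no further column dropping): used by
# build_profile and by the iterative-search profile rebuild, where included
# hit segments are gap-free rows of the same width.
profile_from_rows <- function(rows, pseudocount_weight, background, family_id) {
  stopifnot(pseudocount_weight >= 0, length(background) == 20L)
  background <- background / sum(background)
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  m <- ncol(mat)
  counts <- matrix(0, nrow = m, ncol = 20L, dimnames = list(NULL, AA20))
  for (i in seq_len(m)) {
    tab <- table(factor(mat[, i], levels = AA20))
    counts[i, ] <- as.numeric(tab)
  }
  n_col <- rowSums(counts)
  denom <- n_col + pseudocount_weight
  emission <- (counts + pseudocount_weight * outer(rep(1, m), background)) / denom
  zero <- denom == 0
  if (any(zero)) emission[zero, ] <- matrix(background, sum(zero), 20L, byrow = TRUE)
  log_odds <- 2 * log2(emission / outer(rep(1, m), background))
  consensus <- paste(AA20[max.col(log_odds, ties.method = "first")], collapse = "")
  structure(list(
    family_id = family_id,
    length = m,
    log_odds = log_odds,
    emission_probs = emission,
    background = unname(background),
    pseudocount_weight = pseudocount_weight,
    consensus = consensus,
    match_rows = rows
  ), class = "Profile")
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("Profile '%s': %d columns, %d seed rows, pseudocount %.3g\n",
              x$family_id, x$length, length(x$match_rows), x$pseudocount_weight))
  invisible(x)
}

#' Profile consensus sequence
#' @param profile a `Profile`.
#' @return Single string: per-column maximum-scoring residue.
#' @export
profile_consensus <- function(profile) profile$consensus

# log-odds extended with the X column (0 = background score).
lo21 <- function(profile) cbind(profile$log_odds, 0)
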