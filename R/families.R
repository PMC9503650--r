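# Built-in synthetic domain families.
#
# The package ships no real seed alignments: each named family is a synthetic
# stand-in, generated deterministically from the family name, so that profile
# search, clustering and context mining can be exercised with known ground
# truth. Family names follow the field's domain nomenclature (Macro, NADAR,
# SLOG, Nudix, ART, ARG, NadV, NadM, Sirtuin, plus a Terminase anchor used as
# a virion-morphogenesis neighborhood marker), but the sequences themselves
# carry no biological information.

#' Names of the built-in synthetic families
#' @return Character vector of family ids.
#' @export
builtin_family_names <- function() {
  c("Macro", "NADAR", "SLOG", "Nudix", "ART", "ARG",
    "NadV", "NadM", "Sirtuin", "Terminase")
}

#' Deterministic synthetic consensus for a family
#'
#' The consensus is drawn from the background residue composition under a
#' seed derived from the family name, so repeated calls (and fresh sessions)
#' give the same sequence.
#'
#' @param family_id family name.
#' @param length consensus length in residues (default 60).
#' @return Amino-acid string.
#' @export
family_consensus <- function(family_id, length = 60L) {
  bg <- aa_background()
  with_seed(string_seed(family_id, base = 7L), {
    paste(sample(AA20, length, replace = TRUE, prob = bg), collapse = "")
  })
}

#' Mutate a sequence to a target identity
#'
#' Each position is replaced with probability `1 - identity`; replacements are
#' drawn from the background excluding the current residue, so the expected
#' identity to the input equals `identity`.
#'
#' @param sequence amino-acid string.
#' @param identity target expected fraction of conserved positions in `[0, 1]`.
#' @return Mutated amino-acid string (same length).
#' @export
mutate_sequence <- function(sequence, identity) {
  stopifnot(identity >= 0, identity <= 1)
  bg <- aa_background()
  chars <- strsplit(sequence, "")[[1]]
  hit <- runif(length(chars)) > identity
  if (any(hit)) {
    for (i in which(hit)) {
      ok <- AA20 != chars[i]
      chars[i] <- sample(AA20[ok], 1L, prob = bg[ok])
    }
  }
  paste(chars, collapse = "")
}

#' Synthetic seed alignment for a built-in family
#'
#' Returns the family consensus plus `n_seqs - 1` variants mutated to
#' `identity` (no gaps), deterministically per family name. These are the
#' seeds from which scanning profiles are built and from which the genome
#' generator emits planted domain segments.
#'
#' @param family_id family name.
#' @param n_seqs number of rows (default 5).
#' @param identity identity of variants to the consensus (default 0.85).
#' @param length consensus length (default 60).
#' @return Named character vector of aligned rows.
#' @export
family_seed_alignment <- function(family_id, n_seqs = 5L, identity = 0.85,
                                  length = 60L) {
  cons <- family_consensus(family_id, length)
  with_seed(string_seed(family_id, base = 13L), {
    rows <- c(cons, vapply(seq_len(n_seqs - 1L),
                           function(i) mutate_sequence(cons, identity),
                           character(1)))
    setNames(rows, paste0(family_id, "_seed", seq_len(n_seqs)))
  })
}

#' Build profiles for a set of built-in families
#'
#' @param families family names (default all built-ins).
#' @param pseudocount_weight passed to [build_profile()].
#' @param ... passed to [family_seed_alignment()].
#' @return Named list of `Profile` objects.
#' @export
builtin_profiles <- function(families = builtin_family_names(),
                             pseudocount_weight = 1, ...) {
  setNames(lapply(families, function(f) {
    build_profile(family_seed_alignment(f, ...), pseudocount_weight,
                  family_id = f)
  }), families)
}
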