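# Shared constants and small helpers.

# 20-letter amino-acid alphabet in BLOSUM row order; X is handled as code 21
# (scores as background, i.e. log-odds 0) wherever sequences are integer-coded.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Background amino-acid frequencies
#'
#' Standard database residue composition (Robinson-Robinson frequencies),
#' normalized to sum to one, in the package's fixed alphabet order. Used as
#' the null emission model for profiles, decoys and synthetic background
#' residues so that E-value calibration is stable across runs.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  bg <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
          Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
          L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
          S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  bg / sum(bg)
}

# Integer-encode an amino-acid string: 1..20 per AA20, anything else -> 21 (X).
encode_aa <- function(x) {
  codes <- match(strsplit(toupper(x), "")[[1]], AA20)
  codes[is.na(codes)] <- 21L
  as.integer(codes)
}

decode_aa <- function(codes) {
  paste(c(AA20, "X")[codes], collapse = "")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic small integer derived from a string (for per-family streams).
string_seed <- function(x, base = 0L) {
  v <- utf8ToInt(x)
  s <- base
  for (ch in v) s <- (s * 131L + ch) %% 1000003L
  as.integer(s)
}

# Write a data.frame as deterministic TSV (no quoting, no row names).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
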