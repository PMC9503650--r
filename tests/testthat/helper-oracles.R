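# Independent oracle implementations used to cross-check the package's fast
# paths, plus small fixture builders. Everything here is deliberately naive.

# exhaustive window enumeration for profile scanning (plain R, no C++ path)
oracle_scan <- function(profile, sequence) {
  codes <- viranet:::encode_aa(sequence)
  lo <- cbind(profile$log_odds, 0)  # X scores 0
  m <- profile$length
  nw <- length(codes) - m + 1L
  if (nw < 1L) return(list(score = -Inf, start = NA_integer_))
  scores <- vapply(seq_len(nw), function(o) {
    sum(lo[cbind(seq_len(m), codes[o:(o + m - 1L)])])
  }, numeric(1))
  list(score = max(scores), start = which.max(scores))
}

# brute-force single-linkage components via union-find over a passing-pair list
oracle_components <- function(ids, edges) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(match(edges$id_a[k], ids))
      rb <- find(match(edges$id_b[k], ids))
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_along(ids), find, numeric(1))
  split(ids, root)
}

# recursive (memoized on start cell) enumeration of local alignments with
# affine gaps, for tiny peptides; gap of length k costs open + k * ext
oracle_local_align <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  memo <- matrix(NA_real_, na, nb)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    s <- sub[A[i], B[j]]
    best <- s
    if (i < na && j < nb) {
      for (di in 0:(na - i - 1L)) for (dj in 0:(nb - j - 1L)) {
        gap <- 0
        if (di > 0) gap <- gap + open + ext * di
        if (dj > 0) gap <- gap + open + ext * dj
        best <- max(best, s - gap + rec(i + 1L + di, j + 1L + dj))
      }
    }
    memo[i, j] <<- best
    best
  }
  max(outer(seq_len(na), seq_len(nb), Vectorize(rec)))
}

# hypergeometric upper tail by direct summation of the pmf
oracle_hyper_upper <- function(both, n_a, n_b, N) {
  ks <- both:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(N - n_a, n_b - ks)) / choose(N, n_b)
}

# random background protein
random_protein <- function(n) {
  bg <- aa_background()
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# a protein with a planted domain segment at the given identity
planted_protein <- function(family, identity, flank = 100L, total = 300L) {
  p <- random_protein(total)
  seg <- mutate_sequence(family_consensus(family), identity)
  paste0(substr(p, 1, flank), seg,
         substr(p, flank + nchar(seg) + 1L, total))
}

# minimal single-genome collection from gene coordinates
coords_collection <- function(starts, ends, strands,
                              seqs = NULL, genome_length = NULL) {
  n <- length(starts)
  if (is.null(seqs)) {
    seqs <- vapply(seq_len(n), function(i) random_protein(50L), character(1))
  }
  g <- data.frame(genome_id = "G1", taxid = 1L,
                  genome_length = genome_length %||% (max(ends) + 100L),
                  na_class = "dsDNA", host = "bacteria",
                  morphology = "myovirus", stringsAsFactors = FALSE)
  p <- data.frame(protein_id = sprintf("p%d", seq_len(n)), genome_id = "G1",
                  start = as.integer(starts), end = as.integer(ends),
                  strand = strands, sequence = seqs, stringsAsFactors = FALSE)
  new_collection(g, p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# benchmark configuration for conserved-context mining: every family carried
# by a flat 10% of DNA genomes (no size/morphology/co-occurrence structure),
# so incidental same-operon adjacencies stay below the support floor while
# planted contexts reach support ~13
context_benchmark_config <- function(seed) {
  fp <- generator_config()$family_params
  fp$a_dna <- qlogis(0.10); fp$b_dna <- 0
  fp$a_rna <- NA_real_; fp$b_rna <- NA_real_
  fp$morph_shift <- 0; fp$cooccur <- FALSE
  generator_config(n_genomes = 300L, seed = seed, family_params = fp,
                   cooccur_rho = 0)
}

# planted context truth as unordered family pairs with genome support,
# taking the transitive closure of planted adjacencies per genome (chained
# contexts such as anchor-partner-partner make all involved pairs planted)
planted_pair_support <- function(context_truth, annotations) {
  truth_support <- list()
  for (g in unique(context_truth$genome_id)) {
    e <- context_truth[context_truth$genome_id == g, , drop = FALSE]
    ids <- unique(c(e$anchor_protein, e$partner_protein))
    parent <- setNames(seq_along(ids), ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(e))) {
      ra <- find(match(e$anchor_protein[k], ids))
      rb <- find(match(e$partner_protein[k], ids))
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    comp <- split(ids, vapply(seq_along(ids), find, numeric(1)))
    for (cmp in comp) {
      fams <- sort(unique(annotations$family[annotations$protein_id %in% cmp]))
      if (length(fams) >= 2) {
        for (pr in utils::combn(fams, 2, paste, collapse = " ")) {
          truth_support[[pr]] <- union(truth_support[[pr]], g)
        }
      }
    }
  }
  vapply(truth_support, length, integer(1))
}
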