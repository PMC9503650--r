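# Survey statistics: size-stratified prevalence, morphology enrichment,
# per-1000 carriage rates, pairwise co-occurrence with a fixed-margin
# hypergeometric null, and Euler-style exclusive set counts.

#' Genome size class configuration
#'
#' Default classes follow the survey conventions for tailed phages: small
#' genomes below 25 kb, medium 100-180 kb, jumbo at and above 180 kb. The gap
#' between 25 and 100 kb is deliberately left unclassed. `rna_rise` and
#' `dna_rise` record the prevalence-curve landmarks (sharp rises near 17.5 kb
#' for RNA and 60 kb for DNA viruses).
#'
#' @param classes data.frame with `class`, `min_bp` (inclusive), `max_bp`
#'   (exclusive, `Inf` allowed).
#' @param rna_rise,dna_rise curve landmark lengths in bp.
#' @return A list of class `SizeClassConfig`.
#' @export
size_class_config <- function(classes = data.frame(
                                class = c("small", "medium", "jumbo"),
                                min_bp = c(0, 1e5, 1.8e5),
                                max_bp = c(25000, 1.8e5, Inf),
                                stringsAsFactors = FALSE),
                              rna_rise = 17500, dna_rise = 60000) {
  stopifnot(all(classes$max_bp > classes$min_bp))
  o <- order(classes$min_bp)
  cl <- classes[o, , drop = FALSE]
  if (nrow(cl) > 1 && any(cl$min_bp[-1] < cl$max_bp[-nrow(cl)])) {
    stop("size classes overlap")
  }
  structure(list(classes = classes, rna_rise = rna_rise, dna_rise = dna_rise),
            class = "SizeClassConfig")
}

# class name per length; "unclassed" outside all bounds
size_class_of <- function(lengths, config) {
  cl <- config$classes
  out <- rep("unclassed", length(lengths))
  for (i in seq_len(nrow(cl))) {
    out[lengths >= cl$min_bp[i] & lengths < cl$max_bp[i]] <- cl$class[i]
  }
  out
}

#' Prevalence curve over genome-length thresholds
#'
#' For each threshold, counts the genomes with length at or above the
#' threshold and the fraction of them that are positive (carry at least one
#' network domain). Thresholds above the largest genome give empty strata and
#' are omitted.
#'
#' @param genomes metadata data.frame with `genome_id`, `genome_length`.
#' @param positives character vector of positive genome ids (must be a subset
#'   of the genome ids).
#' @param thresholds ascending numeric lengths in bp.
#' @return A data.frame `threshold`, `n_genomes`, `n_positive`, `fraction`.
#' @export
prevalence_curve <- function(genomes, positives, thresholds) {
  stopifnot(all(positives %in% genomes$genome_id))
  thresholds <- sort(thresholds)
  pos <- genomes$genome_id %in% positives
  rows <- lapply(thresholds, function(t) {
    in_stratum <- genomes$genome_length >= t
    n <- sum(in_stratum)
    if (n == 0L) return(NULL)
    np <- sum(pos & in_stratum)
    data.frame(threshold = t, n_genomes = n, n_positive = np, fraction = np / n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(threshold = numeric(), n_genomes = integer(),
                      n_positive = integer(), fraction = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Per-size-class prevalence
#'
#' @param genomes metadata data.frame with `genome_id`, `genome_length`.
#' @param positives character vector of positive genome ids.
#' @param size_classes a [size_class_config()].
#' @return A data.frame `class`, `n`, `n_positive`, `fraction` (NA when the
#'   class is empty); genomes matching no class are reported under
#'   `"unclassed"`.
#' @export
class_prevalence <- function(genomes, positives,
                             size_classes = size_class_config()) {
  stopifnot(all(positives %in% genomes$genome_id))
  cls <- size_class_of(genomes$genome_length, size_classes)
  pos <- genomes$genome_id %in% positives
  levels <- c(size_classes$classes$class, "unclassed")
  rows <- lapply(levels, function(cl) {
    sel <- cls == cl
    n <- sum(sel)
    np <- sum(pos & sel)
    data.frame(class = cl, n = n, n_positive = np,
               fraction = if (n > 0) np / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carriage rates per 1000 genomes by morphology
#'
#' @param genomes metadata data.frame with `genome_id`, `morphology`.
#' @param positives character vector of positive genome ids.
#' @return A data.frame `morphology`, `n`, `n_positive`, `per_1000`.
#' @export
per_1000 <- function(genomes, positives) {
  stopifnot(all(positives %in% genomes$genome_id))
  pos <- genomes$genome_id %in% positives
  rows <- lapply(sort(unique(genomes$morphology)), function(m) {
    sel <- genomes$morphology == m
    data.frame(morphology = m, n = sum(sel), n_positive = sum(pos & sel),
               per_1000 = 1000 * sum(pos & sel) / sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square enrichment test on an r x c contingency table
#'
#' Uncorrected Pearson chi-square with `df = (r-1)(c-1)`. If any expected
#' count falls below 5 a warning is issued and, for 2x2 tables, the Fisher
#' exact p-value is reported alongside.
#'
#' @param contingency numeric matrix of counts (no zero rows or columns).
#' @return A list `chi2`, `df`, `p`, `expected`, and `fisher_p` (NA unless
#'   computed).
#' @export
enrichment_test <- function(contingency) {
  tab <- as.matrix(contingency)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table: zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expected <- ct$expected
  fisher_p <- NA_real_
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-square approximation may be poor")
    if (all(dim(tab) == c(2L, 2L))) {
      fisher_p <- fisher.test(tab)$p.value
    }
  }
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = expected, fisher_p = fisher_p)
}

#' Pairwise family co-occurrence across genomes
#'
#' For each family pair within the stratum: the 2x2 genome contingency
#' (both / a-only / b-only / neither), the expected overlap under the
#' fixed-margin independence null (`n_a * n_b / N`), the odds ratio,
#' one-sided hypergeometric p-values for enrichment (`P[X >= both]`) and
#' depletion (`P[X <= both]`), and Benjamini-Hochberg q-values computed
#' separately per direction across all tested pairs. Pairs in which either
#' family is absent from the stratum are skipped (with a message).
#'
#' @param genome_families data.frame with `genome_id`, `family` (one row per
#'   carried family per genome).
#' @param genome_ids genome ids of the stratum (the universe `N`).
#' @param families families to test (>= 2); default all in `genome_families`.
#' @return A data.frame with one row per tested pair: `family_a`, `family_b`,
#'   `both`, `a_only`, `b_only`, `neither`, `expected_both`, `odds_ratio`,
#'   `p_enrich`, `p_deplete`, `q_enrich`, `q_deplete`.
#' @export
cooccurrence <- function(genome_families, genome_ids,
                         families = sort(unique(genome_families$family))) {
  stopifnot(length(genome_ids) >= 1, length(families) >= 2)
  N <- length(genome_ids)
  gf <- genome_families[genome_families$genome_id %in% genome_ids, , drop = FALSE]
  sets <- lapply(setNames(families, families), function(f) {
    unique(gf$genome_id[gf$family == f])
  })
  rows <- list()
  pairs <- utils::combn(families, 2L)
  for (k in seq_len(ncol(pairs))) {
    fa <- pairs[1, k]; fb <- pairs[2, k]
    na_ <- length(sets[[fa]]); nb <- length(sets[[fb]])
    if (na_ == 0L || nb == 0L) {
      message("skipping pair ", fa, "-", fb, ": family absent from stratum")
      next
    }
    both <- length(intersect(sets[[fa]], sets[[fb]]))
    a_only <- na_ - both; b_only <- nb - both
    neither <- N - both - a_only - b_only
    rows[[length(rows) + 1L]] <- data.frame(
      family_a = fa, family_b = fb, both = both, a_only = a_only,
      b_only = b_only, neither = neither,
      expected_both = na_ * nb / N,
      odds_ratio = (both * neither) / (a_only * b_only),
      p_enrich = phyper(both - 1, na_, N - na_, nb, lower.tail = FALSE),
      p_deplete = phyper(both, na_, N - na_, nb),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(family_a = character(), family_b = character(),
                      both = integer(), a_only = integer(), b_only = integer(),
                      neither = integer(), expected_both = numeric(),
                      odds_ratio = numeric(), p_enrich = numeric(),
                      p_deplete = numeric(), q_enrich = numeric(),
                      q_deplete = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_enrich <- p.adjust(out$p_enrich, method = "BH")
  out$q_deplete <- p.adjust(out$p_deplete, method = "BH")
  rownames(out) <- NULL
  out
}

#' Euler-style exclusive intersection counts
#'
#' For up to 4 chosen families, counts genomes by the exact subset of those
#' families they carry. The counts over non-empty subsets sum to the number of
#' genomes carrying at least one of the chosen families.
#'
#' @param genome_families data.frame with `genome_id`, `family`.
#' @param families 2 to 4 family names.
#' @param genome_ids stratum genome ids; defaults to all in `genome_families`.
#' @return Named integer vector: names are subsets joined with `+` (e.g.
#'   `"Macro+NADAR"`), plus a `"none"` entry when `genome_ids` includes
#'   genomes carrying none of the families.
#' @export
euler_counts <- function(genome_families, families,
                         genome_ids = sort(unique(genome_families$genome_id))) {
  stopifnot(length(families) >= 2, length(families) <= 4)
  gf <- genome_families[genome_families$genome_id %in% genome_ids &
                          genome_families$family %in% families, , drop = FALSE]
  pattern <- vapply(genome_ids, function(g) {
    fams <- sort(intersect(families, gf$family[gf$genome_id == g]))
    if (!length(fams)) "none" else paste(fams, collapse = "+")
  }, character(1))
  tab <- table(pattern)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
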