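# Synthetic viral genome collections with planted, parameterized structure.
#
# The generator emulates the statistical features the survey pipeline is
# meant to detect: genome-length-dependent domain carriage with distinct
# DNA/RNA rise points, morphology-biased carriage among tailed phages,
# conserved anchor/partner gene neighborhoods, and positive pairwise
# co-occurrence of the network families. Everything is driven by one seed and
# accompanied by complete truth tables.

RNA_CLASSES <- c("dsRNA", "ssRNA_pos", "ssRNA_neg", "retro")

#' Generator configuration
#'
#' Returns the default configuration, optionally overridden field by field.
#'
#' Carriage of family `f` by a genome of length `L` is Bernoulli with
#' probability `plogis(a + b * log10(L) + morph_shift * is_myovirus +
#' cooccur_rho * z)`, where `(a, b)` are the DNA or RNA intercept/slope for
#' that family, `z` is a genome-level latent N(0,1) shared by all families
#' flagged `cooccur` (inducing positive pairwise co-occurrence when
#' `cooccur_rho > 0`). A `step_carriage` entry for a family replaces the
#' logistic model with fixed per-size-class probabilities (used for
#' calibration experiments).
#'
#' @param ... named overrides of the default fields: `n_genomes`, `seed`,
#'   `class_mix`, `morphology_mix`, `length_model`, `min_length`,
#'   `genome_lengths` (explicit lengths, overriding `length_model`),
#'   `gene_length_model`, `gap_model`, `family_params`, `context_params`,
#'   `cooccur_rho`, `identity_target`, `step_carriage`, `size_classes`,
#'   `taxid_dup_frac`, `domain_length`.
#' @return A list of class `GeneratorConfig`.
#' @export
generator_config <- function(...) {
  fam <- builtin_family_names()
  # logistic defaults: slopes/intercepts placing the per-family rise so that
  # carriage of >= 1 network family echoes the survey's size gradient
  # (rare < 25 kb, common > 100 kb, near-universal > 180 kb for DNA viruses;
  # rise near 17.5 kb for RNA viruses).
  mid_dna <- c(Macro = 8e4, NADAR = 9e4, SLOG = 1.2e5, Nudix = 1e5, ART = 7e4,
               ARG = 1.5e5, NadV = 1.1e5, NadM = 1.6e5, Sirtuin = 2e5,
               Terminase = NA)
  b_dna <- 2.7
  family_params <- data.frame(
    family = fam,
    a_dna = ifelse(is.na(mid_dna[fam]), 2.2, -b_dna * log10(mid_dna[fam])),
    b_dna = ifelse(is.na(mid_dna[fam]), 0, b_dna),
    a_rna = ifelse(fam %in% c("Macro", "NADAR", "Nudix"), -8 * log10(2.2e4), NA_real_),
    b_rna = ifelse(fam %in% c("Macro", "NADAR", "Nudix"), 8, NA_real_),
    morph_shift = ifelse(fam == "ART", 1.5, 0),
    cooccur = fam %in% c("Macro", "NADAR", "SLOG", "Nudix"),
    stringsAsFactors = FALSE
  )
  rownames(family_params) <- NULL
  cfg <- list(
    n_genomes = 300L,
    seed = 1L,
    class_mix = data.frame(
      na_class = c("dsDNA", "ssDNA", "dsRNA", "ssRNA_pos", "ssRNA_neg", "retro"),
      host = c("bacteria", "bacteria", "eukaryote", "eukaryote", "eukaryote", "eukaryote"),
      prop = c(0.70, 0.05, 0.05, 0.15, 0.04, 0.01),
      stringsAsFactors = FALSE
    ),
    morphology_mix = c(myovirus = 0.35, siphovirus = 0.45, podovirus = 0.15,
                       other = 0.05),
    length_model = data.frame(
      na_class = c("dsDNA", "ssDNA", "dsRNA", "ssRNA_pos", "ssRNA_neg", "retro"),
      meanlog = log(c(45000, 5500, 9000, 12000, 11000, 8500)),
      sdlog = c(0.85, 0.35, 0.40, 0.50, 0.35, 0.25),
      stringsAsFactors = FALSE
    ),
    min_length = 2000L,
    genome_lengths = NULL,
    gene_length_model = list(shape = 4, scale = 75, min_codons = 80L),
    gap_model = list(within = c(0L, 60L), between = c(150L, 500L),
                     break_prob = 0.25),
    family_params = family_params,
    context_params = data.frame(
      anchor = c("NADAR", "NadM", "Terminase", "ARG", "SLOG"),
      partner = c("NadM", "NadV", "ART", "ART", "Macro"),
      prob = c(0.6, 0.7, 0.4, 0.6, 0.4),
      max_gap = c(60L, 60L, 60L, 60L, 60L),
      stringsAsFactors = FALSE
    ),
    cooccur_rho = 0.8,
    identity_target = 0.9,
    step_carriage = NULL,
    size_classes = NULL,   # filled by size_class_config() when needed
    taxid_dup_frac = 0,
    domain_length = 60L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(abs(sum(cfg$class_mix$prop) - 1) < 1e-8,
            cfg$identity_target >= 0, cfg$identity_target <= 1)
  class(cfg) <- "GeneratorConfig"
  cfg
}

# --- metadata + carriage (no gene layout): fast path for calibration work ---

sample_meta_carriage <- function(cfg) {
  n <- cfg$n_genomes
  mix <- cfg$class_mix
  cls_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prop)
  na_class <- mix$na_class[cls_idx]
  host <- mix$host[cls_idx]
  if (!is.null(cfg$genome_lengths)) {
    stopifnot(length(cfg$genome_lengths) == n)
    L <- as.integer(cfg$genome_lengths)
  } else {
    lm <- cfg$length_model
    i <- match(na_class, lm$na_class)
    L <- as.integer(pmax(cfg$min_length,
                         round(rlnorm(n, lm$meanlog[i], lm$sdlog[i]))))
  }
  morphology <- rep("unknown", n)
  phage <- na_class == "dsDNA" & host == "bacteria"
  if (any(phage)) {
    morphology[phage] <- sample(names(cfg$morphology_mix), sum(phage),
                                replace = TRUE, prob = cfg$morphology_mix)
  }
  taxid <- 100000L + seq_len(n)
  if (cfg$taxid_dup_frac > 0 && n > 1) {
    ndup <- floor(cfg$taxid_dup_frac * n)
    if (ndup > 0) {
      dup_at <- sample(2:n, ndup)
      taxid[dup_at] <- taxid[sapply(dup_at, function(j) sample(j - 1L, 1L))]
    }
  }
  genomes <- data.frame(
    genome_id = sprintf("G%05d", seq_len(n)),
    taxid = taxid, genome_length = L, na_class = na_class, host = host,
    morphology = morphology, stringsAsFactors = FALSE
  )

  fp <- cfg$family_params
  z <- rnorm(n)
  carried <- matrix(FALSE, n, nrow(fp), dimnames = list(NULL, fp$family))
  is_rna <- na_class %in% RNA_CLASSES
  myo <- morphology == "myovirus"
  classes <- size_class_of(L, cfg$size_classes %||% size_class_config())
  for (j in seq_len(nrow(fp))) {
    famj <- fp$family[j]
    step <- cfg$step_carriage[[famj]]
    if (!is.null(step)) {
      p <- unname(ifelse(classes %in% names(step), step[classes], 0))
      p[is.na(p)] <- 0
    } else {
      a <- ifelse(is_rna, fp$a_rna[j], fp$a_dna[j])
      b <- ifelse(is_rna, fp$b_rna[j], fp$b_dna[j])
      logit <- a + b * log10(L) + fp$morph_shift[j] * myo
      if (fp$cooccur[j]) logit <- logit + cfg$cooccur_rho * z
      p <- ifelse(is.na(a), 0, stats::plogis(logit))
    }
    carried[, j] <- runif(n) < p
  }
  list(genomes = genomes, carried = carried)
}

#' Sample genome metadata and family carriage only
#'
#' The metadata-level half of [generate_collection()]: genome classes,
#' lengths, morphologies and planted family carriage, without gene layout or
#' sequence emission. Useful for statistical calibration experiments at sizes
#' where full sequence emission is unnecessary.
#'
#' @param config a [generator_config()].
#' @return List with `genomes` (metadata data.frame) and `genome_truth`
#'   (data.frame `genome_id`, `family`).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  mc <- with_seed(config$seed, sample_meta_carriage(config))
  idx <- which(mc$carried, arr.ind = TRUE)
  truth <- data.frame(
    genome_id = mc$genomes$genome_id[idx[, 1]],
    family = colnames(mc$carried)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$genome_id, truth$family), , drop = FALSE]
  rownames(truth) <- NULL
  list(genomes = mc$genomes, genome_truth = truth)
}

# --- full collection with gene layout and sequence emission ---

#' Generate a synthetic collection with planted ground truth
#'
#' Genomes are drawn per the class mix; genes tile each genome with
#' gamma-distributed lengths, operon-structured gaps and strands; carried
#' families (see [generator_config()]) are realized by splicing a domain
#' segment — the family consensus mutated to `identity_target` — into a
#' background protein; planted anchor/partner contexts are inserted as
#' adjacent genes with an inter-gene gap at most `max_gap`. All randomness is
#' governed by `config$seed`: equal seeds give identical collections.
#'
#' @param config a [generator_config()].
#' @return List with `collection` (a `Collection`) and `truth` (class
#'   `TruthTables`: `genome_truth`, `hit_truth`, `context_truth`).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  with_seed(config$seed, {
    mc <- sample_meta_carriage(config)
    build_planted_collection(config, mc)
  })
}

build_planted_collection <- function(cfg, mc) {
  genomes <- mc$genomes
  carried <- mc$carried
  dlen <- cfg$domain_length
  cons <- setNames(lapply(colnames(carried), family_consensus, length = dlen),
                   colnames(carried))
  bg <- aa_background()

  prot_rows <- vector("list", nrow(genomes))
  gt_rows <- list(); hit_rows <- list(); ctx_rows <- list()

  for (g in seq_len(nrow(genomes))) {
    gid <- genomes$genome_id[g]
    L <- genomes$genome_length[g]
    sk <- gene_skeleton(L, cfg$gene_length_model, cfg$gap_model)
    if (nrow(sk) == 0L) {
      if (any(carried[g, ])) {
        stop("infeasible layout: no gene fits in genome ", gid,
             " (length ", L, " bp)")
      }
      prot_rows[[g]] <- NULL
      next
    }
    fams <- colnames(carried)[carried[g, ]]
    is_rna <- genomes$na_class[g] %in% RNA_CLASSES
    plant <- plant_families(sk, fams, cfg, polyprotein = is_rna)
    planted <- plant$planted        # data.frame: gene, family, start_aa
    kept_fams <- unique(planted$family)

    # conserved-context insertion: partner gene adjacent to the anchor gene.
    # Neighborhoods are an operonic, DNA-virus feature; RNA viruses carry
    # their domains inside polyproteins instead.
    ctx <- if (is_rna) cfg$context_params[0, , drop = FALSE] else cfg$context_params
    for (k in seq_len(nrow(ctx))) {
      if (!(ctx$anchor[k] %in% kept_fams)) next
      if (runif(1) >= ctx$prob[k]) next
      anchor_gene <- planted$gene[match(ctx$anchor[k], planted$family)]
      cand <- c(anchor_gene + 1L, anchor_gene - 1L)
      cand <- cand[cand >= 1L & cand <= nrow(sk)]
      placed <- FALSE
      for (pg in cand) {
        pos <- domain_slot(sk$codons[pg], planted$start_aa[planted$gene == pg], dlen)
        if (is.na(pos)) next
        planted <- rbind(planted, data.frame(gene = pg, family = ctx$partner[k],
                                             start_aa = pos))
        # force operon-like adjacency and orientation; only ever shrink the
        # gap so the layout still fits within the genome
        down <- max(anchor_gene, pg)
        tgt <- min(60L, ctx$max_gap[k])
        if (sk$gap_before[down] > tgt) {
          sk$gap_before[down] <- sample.int(tgt + 1L, 1L) - 1L
        }
        sk$strand[pg] <- sk$strand[anchor_gene]
        ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
          genome_id = gid, anchor_gene = anchor_gene, partner_gene = pg,
          anchor_family = ctx$anchor[k], partner_family = ctx$partner[k],
          stringsAsFactors = FALSE
        )
        kept_fams <- unique(c(kept_fams, ctx$partner[k]))
        placed <- TRUE
        break
      }
    }

    # coordinates (gaps were only ever shrunk, so everything still fits)
    starts <- cumsum(sk$gap_before + c(1L, rep(0L, nrow(sk) - 1L))) +
      c(0L, cumsum(3L * sk$codons)[-nrow(sk)])
    ends <- starts + 3L * sk$codons - 1L
    stopifnot(all(ends <= L))

    # sequence emission
    seqs <- character(nrow(sk))
    for (i in seq_len(nrow(sk))) {
      chars <- sample(AA20, sk$codons[i], replace = TRUE, prob = bg)
      rows_i <- planted[planted$gene == i, , drop = FALSE]
      for (r in seq_len(nrow(rows_i))) {
        seg <- mutate_sequence(cons[[rows_i$family[r]]], cfg$identity_target)
        chars[rows_i$start_aa[r]:(rows_i$start_aa[r] + dlen - 1L)] <-
          strsplit(seg, "")[[1]]
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    pid <- sprintf("%s_p%03d", gid, seq_len(nrow(sk)))
    prot_rows[[g]] <- data.frame(
      protein_id = pid, genome_id = gid, start = starts, end = ends,
      strand = sk$strand, sequence = seqs, stringsAsFactors = FALSE
    )
    if (nrow(planted)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = pid[planted$gene], family = planted$family,
        start = planted$start_aa, end = planted$start_aa + dlen - 1L,
        stringsAsFactors = FALSE
      )
    }
    if (length(kept_fams)) {
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        genome_id = gid, family = sort(kept_fams), stringsAsFactors = FALSE
      )
    }
    # resolve context gene indices to protein ids
    n_ctx <- length(ctx_rows)
    if (n_ctx) {
      for (k in seq_len(n_ctx)) {
        if (ctx_rows[[k]]$genome_id == gid && is.numeric(ctx_rows[[k]]$anchor_gene)) {
          ctx_rows[[k]]$anchor_protein <- pid[ctx_rows[[k]]$anchor_gene]
          ctx_rows[[k]]$partner_protein <- pid[ctx_rows[[k]]$partner_gene]
        }
      }
    }
  }

  proteins <- do.call(rbind, prot_rows)
  collection <- new_collection(genomes, proteins)
  genome_truth <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(genome_id = character(), family = character(), stringsAsFactors = FALSE)
  hit_truth <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(protein_id = character(), family = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  context_truth <- if (length(ctx_rows)) {
    ct <- do.call(rbind, ctx_rows)
    ct[, c("genome_id", "anchor_protein", "partner_protein",
           "anchor_family", "partner_family")]
  } else {
    data.frame(genome_id = character(), anchor_protein = character(),
               partner_protein = character(), anchor_family = character(),
               partner_family = character(), stringsAsFactors = FALSE)
  }
  rownames(genome_truth) <- rownames(hit_truth) <- rownames(context_truth) <- NULL
  truth <- structure(list(genome_truth = genome_truth, hit_truth = hit_truth,
                          context_truth = context_truth), class = "TruthTables")
  list(collection = collection, truth = truth)
}

# Tile a genome with genes: gamma lengths (codons), operon-structured gaps and
# strands. Only genes that fit entirely within L are kept.
gene_skeleton <- function(L, glm, gap_model) {
  unit <- 3 * glm$shape * glm$scale * 0.6
  n_est <- max(6L, ceiling(L / unit) + 4L)
  codons <- pmax(glm$min_codons, as.integer(round(rgamma(n_est, shape = glm$shape,
                                                         scale = glm$scale))))
  brk <- runif(n_est) < gap_model$break_prob
  brk[1] <- TRUE
  gap <- ifelse(brk,
                sample_range(gap_model$between, n_est),
                sample_range(gap_model$within, n_est))
  operon <- cumsum(brk)
  op_strand <- sample(c("+", "-"), max(operon), replace = TRUE)
  strand <- op_strand[operon]
  ends <- cumsum(gap + 3L * codons)
  keep <- ends <= L
  data.frame(codons = codons, gap_before = as.integer(gap), strand = strand,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

sample_range <- function(rng, n) {
  as.integer(rng[1]) + sample.int(as.integer(rng[2]) - as.integer(rng[1]) + 1L,
                                  n, replace = TRUE) - 1L
}

# Find a free start position for a domain of length dlen on a gene of given
# codon count, avoiding already-used intervals; NA if it does not fit.
domain_slot <- function(codons, used_starts, dlen) {
  margin <- 2L
  slots <- sort(used_starts)
  cursor <- margin + 1L
  for (s in slots) {
    if (s - cursor >= dlen + margin) break
    cursor <- max(cursor, s + dlen + margin)
  }
  if (cursor + dlen - 1L > codons - margin) return(NA_integer_)
  # random jitter within the free room before the next used interval (or end)
  nxt <- slots[slots >= cursor]
  limit <- if (length(nxt)) nxt[1] - margin else codons - margin + 1L
  room <- limit - dlen - cursor
  if (room > 0) cursor <- cursor + sample.int(room + 1L, 1L) - 1L
  cursor
}

# Assign each carried family a gene and a free in-protein slot. DNA viruses
# spread domains over distinct genes; RNA viruses stack them into one
# polyprotein-style gene (successive families share the longest gene while it
# has room), mirroring how these domains occur in nature. Families that no
# gene can host are absent from this genome's truth (capacity exhausted).
plant_families <- function(sk, fams, cfg, polyprotein = FALSE) {
  dlen <- cfg$domain_length
  planted <- data.frame(gene = integer(), family = character(),
                        start_aa = integer(), stringsAsFactors = FALSE)
  if (!length(fams) || !nrow(sk)) return(list(sk = sk, planted = planted))
  order_f <- sample(fams)
  gene_order <- if (polyprotein) order(-sk$codons) else sample(seq_len(nrow(sk)))
  free_genes <- gene_order
  for (f in order_f) {
    placed <- FALSE
    if (polyprotein) {
      for (gidx in gene_order) {
        pos <- domain_slot(sk$codons[gidx],
                           planted$start_aa[planted$gene == gidx], dlen)
        if (!is.na(pos)) {
          planted <- rbind(planted, data.frame(gene = gidx, family = f,
                                               start_aa = pos))
          placed <- TRUE
          break
        }
      }
    } else {
      for (i in seq_along(free_genes)) {
        gidx <- free_genes[i]
        pos <- domain_slot(sk$codons[gidx],
                           planted$start_aa[planted$gene == gidx], dlen)
        if (!is.na(pos)) {
          planted <- rbind(planted, data.frame(gene = gidx, family = f,
                                               start_aa = pos))
          free_genes <- free_genes[-i]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # no unused gene left: share a gene if any has room
        for (gidx in gene_order) {
          pos <- domain_slot(sk$codons[gidx],
                             planted$start_aa[planted$gene == gidx], dlen)
          if (!is.na(pos)) {
            planted <- rbind(planted, data.frame(gene = gidx, family = f,
                                                 start_aa = pos))
            placed <- TRUE
            break
          }
        }
      }
    }
  }
  list(sk = sk, planted = planted)
}

#' Write truth tables as TSVs
#' @param truth `TruthTables` from [generate_collection()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_truth <- function(truth, out_dir) {
  stopifnot(inherits(truth, "TruthTables"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome_truth = file.path(out_dir, "genome_truth.tsv"),
             hit_truth = file.path(out_dir, "hit_truth.tsv"),
             context_truth = file.path(out_dir, "context_truth.tsv"))
  write_tsv(truth$genome_truth, paths[["genome_truth"]])
  write_tsv(truth$hit_truth, paths[["hit_truth"]])
  write_tsv(truth$context_truth, paths[["context_truth"]])
  invisible(paths)
}

#' Read truth tables written by [write_truth()]
#' @param dir directory containing the three truth TSVs.
#' @return A `TruthTables` list.
#' @export
read_truth <- function(dir) {
  structure(list(
    genome_truth = read_tsv(file.path(dir, "genome_truth.tsv")),
    hit_truth = read_tsv(file.path(dir, "hit_truth.tsv")),
    context_truth = read_tsv(file.path(dir, "context_truth.tsv"))
  ), class = "TruthTables")
}
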