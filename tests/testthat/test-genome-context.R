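# Architectures, neighborhood extraction, context mining, absence queries.

test_that("non-overlapping hits give an ordered architecture string", {
  hits <- data.frame(
    protein_id = "p1", family_id = c("Macro", "NADAR"),
    ali_start = c(100L, 5L), ali_end = c(220L, 80L), score = c(50, 40)
  )
  arch <- detect_architectures(hits)
  expect_equal(arch$architecture, "NADAR+Macro")
  expect_equal(arch$n_domains, 2L)
})

test_that("identical spans keep only the higher-scoring family", {
  hits <- data.frame(
    protein_id = "p1", family_id = c("A", "B"),
    ali_start = 10L, ali_end = 60L, score = c(50, 30)
  )
  arch <- detect_architectures(hits)
  expect_equal(arch$architecture, "A")
})

test_that("greedy overlap resolution matches a stepwise oracle", {
  oracle_greedy <- function(h, frac) {
    h <- h[order(-h$score, h$ali_start, h$family_id), ]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      if (nrow(kept)) {
        ov <- pmin(h$ali_end[i], kept$ali_end) - pmax(h$ali_start[i], kept$ali_start) + 1L
        shorter <- pmin(h$ali_end[i] - h$ali_start[i], kept$ali_end - kept$ali_start) + 1L
        ok <- all(ov <= frac * shorter)
      }
      if (ok) kept <- rbind(kept, h[i, ])
    }
    paste(kept$family_id[order(kept$ali_start)], collapse = "+")
  }
  set.seed(31)
  for (rep in 1:25) {
    n <- 5L
    st <- sample(1:150, n)
    hits <- data.frame(
      protein_id = "px", family_id = LETTERS[1:n],
      ali_start = st, ali_end = st + sample(20:80, n, replace = TRUE),
      score = round(runif(n, 10, 90), 1)
    )
    expect_equal(detect_architectures(hits)$architecture,
                 oracle_greedy(hits, 0.5), info = paste("rep", rep))
  }
})

test_that("gap arithmetic bounds the neighborhood walk", {
  coll <- coords_collection(starts = c(100L, 500L, 1100L),
                            ends = c(400L, 900L, 1500L),
                            strands = c("+", "+", "+"))
  nb <- extract_neighborhoods(coll, "p1")
  # gaps are 99 (passes) and 199 (blocks)
  expect_equal(nb$protein_id, c("p1", "p2"))
  expect_equal(nb$gap_prev, c(NA_integer_, 99L))
  # isolated anchor: both sides stopped
  coll2 <- coords_collection(starts = c(100L, 2000L), ends = c(400L, 2400L),
                             strands = c("+", "+"))
  nb2 <- extract_neighborhoods(coll2, "p1")
  expect_equal(nb2$protein_id, "p1")
  # unknown anchor errors
  expect_error(extract_neighborhoods(coll, "nope"), "anchor not in collection")
})

test_that("minus-strand anchors are canonicalized and the flip is an involution", {
  coll <- coords_collection(starts = c(100L, 500L), ends = c(400L, 900L),
                            strands = c("-", "+"))
  nb <- extract_neighborhoods(coll, "p1")
  # p2 is genomically downstream of the - anchor: canonically upstream, on -
  expect_equal(nb$protein_id, c("p2", "p1"))
  expect_equal(nb$offset, c(-1L, 0L))
  expect_equal(nb$rel_strand, c("-", "+"))
  # involution: flipping the genome's strands twice restores the original view
  flip <- coll
  flip$proteins$strand <- ifelse(flip$proteins$strand == "+", "-", "+")
  flip2 <- flip
  flip2$proteins$strand <- ifelse(flip2$proteins$strand == "+", "-", "+")
  expect_identical(extract_neighborhoods(flip2, "p1"),
                   extract_neighborhoods(coll, "p1"))
  # and the flipped genome gives the + anchor view
  nbf <- extract_neighborhoods(flip, "p1")
  expect_equal(nbf$protein_id, c("p1", "p2"))
  expect_equal(nbf$rel_strand, c("+", "-"))
})

test_that("overlapping genes count as gap zero and pass the filter", {
  coll <- coords_collection(starts = c(100L, 380L), ends = c(400L, 700L),
                            strands = c("+", "+"))
  nb <- extract_neighborhoods(coll, "p1")
  expect_equal(nb$protein_id, c("p1", "p2"))
  expect_equal(nb$gap_prev[2], 0L)
})

test_that("context mining counts support and applies both filters", {
  # 4 genomes with planted A-B adjacency across 3 taxids; 1 pair genome only
  mk <- function(gid, taxid, fams) {
    n <- length(fams)
    g <- data.frame(genome_id = gid, taxid = taxid, genome_length = 10000L,
                    na_class = "dsDNA", host = "bacteria", morphology = "unknown")
    p <- data.frame(protein_id = sprintf("%s_p%d", gid, 1:n), genome_id = gid,
                    start = seq(1L, by = 400L, length.out = n),
                    end = seq(350L, by = 400L, length.out = n),
                    strand = "+",
                    sequence = vapply(1:n, function(i) random_protein(40L), ""))
    list(g = g, p = p, ann = data.frame(protein_id = p$protein_id, family = fams))
  }
  set.seed(41)
  parts <- list(mk("g1", 1L, c("A", "B")), mk("g2", 2L, c("A", "B")),
                mk("g3", 3L, c("B", "A")), mk("g4", 3L, c("A", "B")),
                mk("g5", 4L, c("C", "D")))
  coll <- new_collection(do.call(rbind, lapply(parts, `[[`, "g")),
                         do.call(rbind, lapply(parts, `[[`, "p")))
  ann <- do.call(rbind, lapply(parts, `[[`, "ann"))
  nbs <- extract_neighborhoods(coll, ann$protein_id, gap_cutoff = 100L)
  ctx <- mine_contexts(nbs, ann, coll$genomes, min_support = 3L, min_taxa = 2L)
  ab <- ctx[ctx$anchor_family == "A" & ctx$partner_family == "B", ]
  expect_equal(ab$support, 4L)
  expect_equal(ab$distinct_taxa, 3L)
  expect_equal(ab$orientation, "same_strand")
  # C-D support 1 < min_support: absent
  expect_false(any(ctx$anchor_family == "C"))

  # same pair in 5 genomes of one taxid fails the phyletic filter
  parts2 <- lapply(1:5, function(i) mk(paste0("h", i), 99L, c("E", "F")))
  coll2 <- new_collection(do.call(rbind, lapply(parts2, `[[`, "g")),
                          do.call(rbind, lapply(parts2, `[[`, "p")))
  ann2 <- do.call(rbind, lapply(parts2, `[[`, "ann"))
  nbs2 <- extract_neighborhoods(coll2, ann2$protein_id, gap_cutoff = 100L)
  ctx2 <- mine_contexts(nbs2, ann2, coll2$genomes, min_support = 3L, min_taxa = 2L)
  expect_equal(nrow(ctx2), 0L)
})

test_that("mined support equals brute-force pair counting on a small instance", {
  sim <- generate_collection(generator_config(n_genomes = 40L, seed = 55L))
  ann <- data.frame(protein_id = sim$truth$hit_truth$protein_id,
                    family = sim$truth$hit_truth$family)
  nbs <- extract_neighborhoods(sim$collection, unique(ann$protein_id))
  ctx <- mine_contexts(nbs, ann, sim$collection$genomes,
                       min_support = 1L, min_taxa = 1L)
  # brute force: for each anchor neighborhood, collect family pairs per genome
  fam_of <- split(ann$family, ann$protein_id)
  seen <- list()
  for (a in unique(nbs$anchor)) {
    nb <- nbs[nbs$anchor == a, ]
    for (fa in fam_of[[a]]) {
      others <- setdiff(nb$protein_id, a)
      for (o in others) for (fp in fam_of[[o]] %||% character(0)) {
        key <- paste(fa, fp, sep = "|")
        seen[[key]] <- union(seen[[key]], nb$genome_id[1])
      }
    }
  }
  for (i in seq_len(nrow(ctx))) {
    key <- paste(ctx$anchor_family[i], ctx$partner_family[i], sep = "|")
    expect_equal(ctx$support[i], length(seen[[key]]), info = key)
  }
  expect_equal(nrow(ctx), length(seen))
})

test_that("absence query reports loci lacking coupled partners", {
  set.seed(61)
  mkg <- function(gid, fams) {
    n <- length(fams)
    g <- data.frame(genome_id = gid, taxid = match(gid, c("gx", "gy")),
                    genome_length = 10000L, na_class = "dsDNA",
                    host = "bacteria", morphology = "unknown")
    p <- data.frame(protein_id = sprintf("%s_p%d", gid, 1:n), genome_id = gid,
                    start = seq(1L, by = 400L, length.out = n),
                    end = seq(350L, by = 400L, length.out = n), strand = "+",
                    sequence = vapply(1:n, function(i) random_protein(40L), ""))
    ann <- data.frame(protein_id = p$protein_id, family = fams)
    list(g = g, p = p, ann = ann[fams != "none", ])
  }
  gx <- mkg("gx", c("ARG", "ART", "none"))          # ARG coupled to ART
  gy <- mkg("gy", c("ARG", "Phosphatase", "TF"))    # ARG with neutral partners
  coll <- new_collection(rbind(gx$g, gy$g), rbind(gx$p, gy$p))
  ann <- rbind(gx$ann, gy$ann)
  res <- absence_query(coll, ann, target_families = "ARG",
                       excluded_partner_families = c("ART", "Sirtuin"))
  expect_equal(res$genome_id, "gy")
  expect_equal(res$protein_id, "gy_p1")
  expect_equal(res$neighbor_families, "Phosphatase,TF")
  # empty target set gives an empty result
  expect_equal(nrow(absence_query(coll, ann, "NoSuch", "ART")), 0L)
})
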