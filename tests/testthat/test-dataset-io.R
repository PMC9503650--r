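# Collection I/O, validation, and taxid de-duplication.

make_two_genome_fixture <- function(dir) {
  meta <- data.frame(
    genome_id = c("GA", "GB"), taxid = c(11L, 22L),
    genome_length = c(5000L, 8000L),
    na_class = c("dsDNA", "ssRNA_pos"), host = c("bacteria", "eukaryote"),
    morphology = c("myovirus", "unknown")
  )
  gff <- c(
    "##gff-version 3",
    "GA\tsrc\tCDS\t100\t400\t.\t+\t0\tID=GA_p1",
    "GA\tsrc\tCDS\t500\t900\t.\t-\t0\tID=GA_p2",
    "GA\tsrc\tCDS\t1200\t1500\t.\t+\t0\tID=GA_p3",
    "GB\tsrc\tCDS\t10\t310\t.\t+\t0\tID=GB_p1",
    "GB\tsrc\tCDS\t400\t700\t.\t+\t0\tID=GB_p2"
  )
  fasta <- unlist(lapply(c("GA_p1", "GA_p2", "GA_p3", "GB_p1", "GB_p2"),
                         function(id) c(paste0(">", id), random_protein(40L))))
  paths <- list(metadata = file.path(dir, "m.tsv"), gff = file.path(dir, "g.gff3"),
                fasta = file.path(dir, "p.faa"))
  write.table(meta, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(gff, paths$gff)
  writeLines(fasta, paths$fasta)
  paths
}

test_that("read_collection parses a small fixture with sorted proteins", {
  dir <- withr::local_tempdir()
  paths <- make_two_genome_fixture(dir)
  coll <- read_collection(paths$metadata, paths$gff, paths$fasta)
  expect_s3_class(coll, "Collection")
  expect_equal(nrow(coll$genomes), 2L)
  expect_equal(nrow(coll$proteins), 5L)
  expect_equal(coll$genomes$protein_count, c(3L, 2L))
  ga <- coll$proteins[coll$proteins$genome_id == "GA", ]
  expect_false(is.unsorted(ga$start))
  expect_equal(ga$strand, c("+", "-", "+"))
})

test_that("malformed coordinates and orphan records are rejected with context", {
  dir <- withr::local_tempdir()
  paths <- make_two_genome_fixture(dir)
  bad <- readLines(paths$gff)
  bad[3] <- "GA\tsrc\tCDS\t900\t500\t.\t-\t0\tID=GA_p2"
  writeLines(bad, paths$gff)
  expect_error(read_collection(paths$metadata, paths$gff, paths$fasta),
               "end < start at line 3")

  paths <- make_two_genome_fixture(dir)
  cat(">ORPHAN\nMKLV\n", file = paths$fasta, append = TRUE)
  expect_error(read_collection(paths$metadata, paths$gff, paths$fasta),
               "ORPHAN")
})

test_that("write/read round-trip is the identity on every field", {
  sim <- generate_collection(generator_config(n_genomes = 50L, seed = 101L))
  dir <- withr::local_tempdir()
  paths <- write_collection(sim$collection, dir)
  back <- read_collection(paths["metadata"], paths["gff"], paths["fasta"])
  expect_identical(back$genomes, sim$collection$genomes)
  expect_identical(back$proteins, sim$collection$proteins)
})

test_that("degenerate collections round-trip: no proteins, or none at all", {
  g <- data.frame(genome_id = "G0", taxid = 5L, genome_length = 3000L,
                  na_class = "dsDNA", host = "bacteria", morphology = "unknown")
  coll <- new_collection(g)
  dir <- withr::local_tempdir()
  paths <- write_collection(coll, dir)
  back <- read_collection(paths["metadata"], paths["gff"], paths["fasta"])
  expect_equal(back$genomes$genome_id, "G0")
  expect_equal(back$genomes$protein_count, 0L)
  expect_equal(nrow(back$proteins), 0L)

  empty <- new_collection(g[0, , drop = FALSE])
  dir2 <- withr::local_tempdir()
  paths2 <- write_collection(empty, dir2)
  back2 <- read_collection(paths2["metadata"], paths2["gff"], paths2["fasta"])
  expect_equal(nrow(back2$genomes), 0L)
  expect_equal(nrow(back2$proteins), 0L)
})

test_that("non-alphabet residues map to X on construction", {
  g <- data.frame(genome_id = "G1", taxid = 1L, genome_length = 1000L,
                  na_class = "dsDNA", host = "bacteria", morphology = "unknown")
  p <- data.frame(protein_id = "p1", genome_id = "G1", start = 1L, end = 30L,
                  strand = "+", sequence = "MKLB*JZU")
  coll <- new_collection(g, p)
  expect_equal(coll$proteins$sequence, "MKLXXXXX")
})

test_that("deduplicate_by_taxid keeps the largest proteome per taxid", {
  set.seed(7)
  g <- data.frame(
    genome_id = c("A1", "A2", "B1"), taxid = c(77L, 77L, 88L),
    genome_length = c(40000L, 42000L, 30000L),
    na_class = "dsDNA", host = "bacteria", morphology = "unknown"
  )
  mk <- function(gid, n) data.frame(
    protein_id = sprintf("%s_p%d", gid, 1:n), genome_id = gid,
    start = seq(1L, by = 400L, length.out = n),
    end = seq(300L, by = 400L, length.out = n),
    strand = "+", sequence = replicate(n, random_protein(30L))
  )
  coll <- new_collection(g, rbind(mk("A1", 12L), mk("A2", 10L), mk("B1", 8L)))
  out <- deduplicate_by_taxid(coll)
  expect_setequal(out$genomes$genome_id, c("A1", "B1"))
  expect_setequal(dropped_genomes(out), "A2")
  expect_false(any(out$proteins$genome_id == "A2"))
})

test_that("dedup tie on protein count breaks by genome length, then id", {
  set.seed(8)
  g <- data.frame(
    genome_id = c("Z9", "A9"), taxid = 9L,
    genome_length = c(41000L, 39000L),
    na_class = "dsDNA", host = "bacteria", morphology = "unknown"
  )
  mk <- function(gid, n) data.frame(
    protein_id = sprintf("%s_p%d", gid, 1:n), genome_id = gid,
    start = seq(1L, by = 400L, length.out = n),
    end = seq(300L, by = 400L, length.out = n),
    strand = "+", sequence = replicate(n, random_protein(30L))
  )
  coll <- new_collection(g, rbind(mk("Z9", 8L), mk("A9", 8L)))
  out <- deduplicate_by_taxid(coll)
  # exhaustive check of the documented rule: equal counts, so larger genome wins
  expect_equal(out$genomes$genome_id, "Z9")

  # equal counts and equal lengths: lexicographically smallest id wins
  g2 <- g; g2$genome_length <- c(40000L, 40000L)
  coll2 <- new_collection(g2, rbind(mk("Z9", 8L), mk("A9", 8L)))
  expect_equal(deduplicate_by_taxid(coll2)$genomes$genome_id, "A9")
})

test_that("dedup is idempotent and preserves per-taxid max proteome size", {
  sim <- generate_collection(generator_config(n_genomes = 40L, seed = 5L,
                                              taxid_dup_frac = 0.3))
  coll <- sim$collection
  once <- deduplicate_by_taxid(coll)
  twice <- deduplicate_by_taxid(once)
  expect_identical(once$genomes, twice$genomes)
  expect_setequal(once$genomes$taxid, unique(coll$genomes$taxid))
  agg <- tapply(coll$genomes$protein_count, coll$genomes$taxid, max)
  expect_equal(as.vector(agg[as.character(once$genomes$taxid)]),
               once$genomes$protein_count)
  # identity when all taxids are distinct
  sim2 <- generate_collection(generator_config(n_genomes = 20L, seed = 6L))
  out2 <- deduplicate_by_taxid(sim2$collection)
  expect_identical(out2$genomes, sim2$collection$genomes)
  expect_length(dropped_genomes(out2), 0L)
})
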