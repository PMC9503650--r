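# Profile construction, window scanning, empirical E-values and the
# iterative inclusion procedure.

test_that("profile emissions follow the pseudocount formula", {
  # column-wise hand computation: (counts + bg) / (n + 1) at pseudocount 1
  rows <- c(s1 = "AVD", s2 = "AVE", s3 = "VVD")
  prof <- build_profile(rows, pseudocount_weight = 1)
  bg <- aa_background()
  expect_equal(unname(prof$emission_probs[1, "A"]), (2 + bg[["A"]]) / 4)
  expect_equal(unname(prof$emission_probs[1, "V"]), (1 + bg[["V"]]) / 4)
  expect_equal(unname(prof$emission_probs[2, "V"]), (3 + bg[["V"]]) / 4)
  expect_equal(unname(prof$emission_probs[3, "D"]), (2 + bg[["D"]]) / 4)
  expect_equal(unname(prof$emission_probs[3, "C"]), bg[["C"]] / 4)
  # invariants: rows normalized, log-odds definition in half-bits
  expect_true(all(abs(rowSums(prof$emission_probs) - 1) < 1e-9))
  expect_equal(prof$log_odds,
               2 * log2(prof$emission_probs / outer(rep(1, 3), unname(bg))),
               tolerance = 1e-12)
})

test_that("zero pseudocounts make counts dominate", {
  prof <- build_profile(c("MKV"), pseudocount_weight = 0)
  expect_equal(profile_consensus(prof), "MKV")
  expect_equal(unname(prof$emission_probs[1, "M"]), 1)
  # column with residues {A:2, V:2} at pseudocount 0: emission 0.5/0.5
  prof2 <- build_profile(c("A", "A", "V", "V"), pseudocount_weight = 0)
  expect_equal(unname(prof2$emission_probs[1, "A"]), 0.5)
  expect_equal(unname(prof2$emission_probs[1, "V"]), 0.5)
  expect_equal(sum(prof2$emission_probs[1, ] > 0), 2L)
})

test_that("majority-gap columns are dropped by the match-column rule", {
  rows <- c("A-CD", "A-CE", "AWC-")
  prof <- build_profile(rows)  # column 2 has 2/3 gaps -> dropped
  expect_equal(prof$length, 3L)
  expect_equal(substr(profile_consensus(prof), 1, 2), "AC")
})

test_that("scanning the consensus attains the per-column maximum score", {
  prof <- builtin_profiles("Nudix")$Nudix
  hit <- scan_protein(prof, profile_consensus(prof))
  expect_equal(hit$score, sum(apply(prof$log_odds, 1, max)))
  expect_equal(hit$ali_start, 1L)
  expect_equal(hit$ali_end, prof$length)
})

test_that("proteins shorter than the profile yield the no-hit sentinel", {
  prof <- builtin_profiles("Macro")$Macro
  hit <- scan_protein(prof, "MKV")
  expect_identical(hit$score, -Inf)
  expect_true(is.na(hit$ali_start))
})

test_that("scan matches exhaustive window enumeration, ties to smallest start", {
  set.seed(404)
  for (rep in 1:50) {
    m <- sample(3:10, 1)
    aln <- replicate(sample(1:4, 1), random_protein(m))
    prof <- build_profile(aln, pseudocount_weight = runif(1, 0.1, 2))
    seq <- random_protein(sample(m:40, 1))
    got <- scan_protein(prof, seq)
    want <- oracle_scan(prof, seq)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    if (is.finite(want$score)) expect_equal(got$ali_start, want$start)
  }
  # a length-2 profile against a length-4 protein: 3 windows by hand
  prof <- build_profile("AC", pseudocount_weight = 1)
  seqv <- "ACAC"
  ws <- window_scores(prof, seqv)
  expect_length(ws, 3L)
  lo <- prof$log_odds
  expect_equal(ws, c(lo[1, "A"] + lo[2, "C"], lo[1, "C"] + lo[2, "A"],
                     lo[1, "A"] + lo[2, "C"]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # tie between windows 1 and 3: smallest start wins
  expect_equal(scan_protein(prof, seqv)$ali_start, 1L)
})

test_that("E-values hit the documented extremes and smoothing floor", {
  prof <- builtin_profiles("SLOG")$SLOG
  null <- calibrate_null(prof, database_size = 500L, n_decoys = 999L,
                         decoy_length = 120L, seed = 3L)
  n <- null$n_decoys
  expect_equal(evalue(null, min(null$decoy_scores) - 1),
               500 * (n + 1) / (n + 1))           # below all decoys: E = db
  expect_equal(evalue(null, max(null$decoy_scores) + 1),
               500 * 1 / (n + 1))                 # above all: smoothing floor
  expect_true(all(diff(evalue(null, sort(runif(20, -300, 0)))) <= 0))
})

test_that("empirical E-values are calibrated on fresh background decoys", {
  prof <- builtin_profiles("Macro")$Macro
  null <- calibrate_null(prof, database_size = 1000L, n_decoys = 1999L,
                         decoy_length = 200L, seed = 11L)
  fresh <- calibrate_null(prof, database_size = 1000L, n_decoys = 3000L,
                          decoy_length = 200L, seed = 12L)$decoy_scores
  E <- evalue(null, fresh)
  for (q in c(0.01, 0.1)) {
    frac <- mean(E <= 1000 * q)
    ci <- qbinom(c(0.005, 0.995), length(fresh), q) / length(fresh)
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
  }
})

test_that("iterative search recovers a planted family and stays clean", {
  withr::local_seed(501)
  prots <- data.frame(
    protein_id = c(sprintf("pl%02d", 1:15), sprintf("bg%03d", 1:120)),
    sequence = c(vapply(1:15, function(i) planted_protein("ARG", 0.9), ""),
                 vapply(1:120, function(i) random_protein(300L), "")),
    stringsAsFactors = FALSE
  )
  res <- iterative_search(builtin_profiles("ARG")$ARG, prots, seed = 8L)
  expect_true(res$converged)
  expect_setequal(res$hits$protein_id[grepl("^pl", res$hits$protein_id)],
                  sprintf("pl%02d", 1:15))
  expect_equal(sum(grepl("^bg", res$hits$protein_id)), 0L)
  expect_true(all(res$hits$e_value <= 0.01))
  expect_true(all(res$hits$ali_end - res$hits$ali_start + 1L == 60L))
})

test_that("no passing protein means one iteration and an empty result", {
  withr::local_seed(502)
  prots <- data.frame(protein_id = sprintf("bg%02d", 1:50),
                      sequence = vapply(1:50, function(i) random_protein(200L), ""))
  res <- iterative_search(builtin_profiles("NadM")$NadM, prots, seed = 2L)
  expect_equal(nrow(res$hits), 0L)
  expect_equal(res$n_iter, 1L)
  expect_true(res$converged)
})

test_that("recall is non-decreasing in planted identity", {
  withr::local_seed(503)
  recall_at <- function(identity) {
    prots <- data.frame(
      protein_id = c(sprintf("pl%02d", 1:20), sprintf("bg%02d", 1:60)),
      sequence = c(vapply(1:20, function(i) planted_protein("SLOG", identity), ""),
                   vapply(1:60, function(i) random_protein(300L), "")))
    res <- iterative_search(builtin_profiles("SLOG")$SLOG, prots, seed = 4L)
    mean(sprintf("pl%02d", 1:20) %in% res$hits$protein_id)
  }
  r <- vapply(c(0.35, 0.65, 0.95), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gte(r[3], 0.95)
})
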