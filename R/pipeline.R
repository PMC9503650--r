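# End-to-end orchestration: simulate (or load) -> dedup -> scan -> cluster ->
# context -> stats, with a manifest recording config, seed, per-stage row
# counts and output digests. A single global seed is fanned out to per-stage
# substreams so reruns with the same config are byte-identical.

#' Pipeline configuration
#'
#' Defaults match the procedure's stated values where it states them:
#' profile-inclusion E-value 0.01, inter-gene distance cutoff 100 nt, and the
#' 25/100/180 kb size classes.
#'
#' @param simulate logical; if `TRUE` the input collection is generated by
#'   [generate_collection()] from `generator`.
#' @param generator a [generator_config()] used when `simulate = TRUE`.
#' @param metadata,gff,fasta input paths used when `simulate = FALSE`.
#' @param families families to scan (built-in profiles); default the
#'   generator's planted families.
#' @param inclusion_E profile-inclusion threshold (default 0.01).
#' @param max_iter iterative-search iteration cap (default 5).
#' @param gap_cutoff neighborhood inter-gene distance cutoff in nt
#'   (default 100).
#' @param window neighborhood window in genes per side (default 5).
#' @param min_support,min_taxa conserved-context support filters.
#' @param clustering a [scoring_params()].
#' @param size_classes a [size_class_config()].
#' @param seed global seed fanned out to stages.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulate = TRUE, generator = generator_config(),
                            metadata = NULL, gff = NULL, fasta = NULL,
                            families = builtin_family_names(),
                            inclusion_E = 0.01, max_iter = 5L,
                            gap_cutoff = 100L, window = 5L,
                            min_support = 3L, min_taxa = 2L,
                            clustering = scoring_params(),
                            size_classes = size_class_config(),
                            seed = 1L) {
  structure(list(simulate = simulate, generator = generator,
                 metadata = metadata, gff = gff, fasta = fasta,
                 families = families, inclusion_E = inclusion_E,
                 max_iter = as.integer(max_iter),
                 gap_cutoff = as.integer(gap_cutoff),
                 window = as.integer(window),
                 min_support = as.integer(min_support),
                 min_taxa = as.integer(min_taxa),
                 clustering = clustering, size_classes = size_classes,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be set in the file; nested
#' `generator` and `clustering` sections override the corresponding defaults
#' field by field.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(generator_config, y$generator %||% list())
  clu <- do.call(scoring_params, y$clustering %||% list())
  y$generator <- NULL; y$clustering <- NULL
  do.call(pipeline_config, c(y, list(generator = gen, clustering = clu)))
}

#' Run the full pipeline
#'
#' Executes simulate/load, taxid de-duplication, iterative profile scanning,
#' clustering of hit proteins, architecture and conserved-context mining, and
#' the survey statistics, writing stage TSVs plus `manifest.json` under
#' `out_dir`. Rerunning with an identical config and seed reproduces all TSVs
#' byte for byte. A stage failure halts the run with the stage name in the
#' error; outputs of completed stages are retained and the manifest is marked
#' failed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return `out_dir`, invisibly; the manifest lists every output file with
#'   its md5 digest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("viranet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_digest = digest_config(config),
    stages = list(), files = list(), warnings = list(), status = "running"
  )
  stage_seed <- function(k) (config$seed %% 10000000L) * 100L + k
  warn_collect <- character(0)
  run_stage <- function(name, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$status <<- "failed"
        manifest$failed_stage <<- name
        manifest$error <<- conditionMessage(e)
        write_manifest(manifest, out_dir)
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warn_collect <<- c(warn_collect, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    res
  }

  # stage 1: simulate or load -------------------------------------------
  truth <- NULL
  collection <- run_stage("dataset_io", {
    if (isTRUE(config$simulate)) {
      gen <- config$generator
      gen$seed <- stage_seed(1L)
      sim <- generate_collection(gen)
      truth <<- sim$truth
      write_collection(sim$collection, file.path(out_dir, "data"))
      write_truth(sim$truth, file.path(out_dir, "truth"))
      sim$collection
    } else {
      read_collection(config$metadata, config$gff, config$fasta)
    }
  })
  manifest$stages$dataset_io <- list(genomes = nrow(collection$genomes),
                                     proteins = nrow(collection$proteins))

  # stage 2: de-duplication ---------------------------------------------
  collection <- run_stage("dedup", deduplicate_by_taxid(collection))
  writeLines(dropped_genomes(collection),
             file.path(out_dir, "dropped_genomes.txt"))
  manifest$stages$dedup <- list(genomes = nrow(collection$genomes),
                                dropped = length(dropped_genomes(collection)))

  # stage 3: profile scan ------------------------------------------------
  scan <- run_stage("profile_scan", {
    profiles <- builtin_profiles(config$families)
    scan_collection(profiles, collection, seed = stage_seed(3L),
                    inclusion_E = config$inclusion_E,
                    max_iter = config$max_iter)
  })
  hits <- scan$hits[order(scan$hits$protein_id, scan$hits$family_id), , drop = FALSE]
  write_tsv(hits, file.path(out_dir, "hits.tsv"))
  write_tsv(scan$candidates, file.path(out_dir, "candidate_hits.tsv"))
  if (any(!scan$reports$converged)) {
    warn_collect <- c(warn_collect, paste0(
      "profile_scan: non-convergent families: ",
      paste(scan$reports$family_id[!scan$reports$converged], collapse = ", ")))
  }
  manifest$stages$profile_scan <- list(hits = nrow(hits),
                                       candidates = nrow(scan$candidates))

  # stage 4: clustering of matched domain segments -----------------------
  # Clustering operates on the hit segments rather than whole proteins:
  # multidomain fusion proteins would otherwise chain unrelated families
  # into one component. Segment ids are protein_id|family_id.
  clusters <- run_stage("seqcluster", {
    if (nrow(hits) >= 1) {
      seg_id <- paste(hits$protein_id, hits$family_id, sep = "|")
      seqs <- setNames(substr(
        collection$proteins$sequence[match(hits$protein_id,
                                           collection$proteins$protein_id)],
        hits$ali_start, hits$ali_end), seg_id)
      seg_hits <- data.frame(protein_id = seg_id, family_id = hits$family_id,
                             stringsAsFactors = FALSE)
      cl <- cluster_proteins(seqs, config$clustering)
      merge_clusters(cl, seqs, hits = seg_hits, params = config$clustering)
    } else {
      data.frame(cluster_id = character(), protein_id = character(),
                 is_representative = logical(), stringsAsFactors = FALSE)
    }
  })
  write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  manifest$stages$seqcluster <- list(clusters = length(unique(clusters$cluster_id)),
                                     members = nrow(clusters))

  # stage 5: genome context ----------------------------------------------
  ctx <- run_stage("genome_context", {
    arch <- detect_architectures(hits)
    ann <- data.frame(protein_id = hits$protein_id, family = hits$family_id,
                      stringsAsFactors = FALSE)
    anchors <- unique(hits$protein_id)
    nbs <- if (length(anchors)) {
      extract_neighborhoods(collection, anchors, window = config$window,
                            gap_cutoff = config$gap_cutoff)
    } else {
      data.frame(anchor = character(), genome_id = character(),
                 protein_id = character(), offset = integer(),
                 rel_strand = character(), gap_prev = integer())
    }
    contexts <- mine_contexts(nbs, ann, collection$genomes,
                              min_support = config$min_support,
                              min_taxa = config$min_taxa)
    list(arch = arch, contexts = contexts)
  })
  write_tsv(ctx$arch, file.path(out_dir, "architectures.tsv"))
  write_tsv(ctx$contexts, file.path(out_dir, "contexts.tsv"))
  manifest$stages$genome_context <- list(architectures = nrow(ctx$arch),
                                         contexts = nrow(ctx$contexts))

  # stage 6: survey statistics -------------------------------------------
  stats_out <- run_stage("netstats", {
    g <- collection$genomes
    pos_genomes <- sort(unique(
      collection$proteins$genome_id[match(unique(hits$protein_id),
                                          collection$proteins$protein_id)]))
    curve <- prevalence_curve(g, pos_genomes,
                              thresholds = c(0, 5e3, 1e4, 1.75e4, 2.5e4, 5e4,
                                             6e4, 1e5, 1.8e5))
    classes <- class_prevalence(g, pos_genomes, config$size_classes)
    phage <- g[g$morphology != "unknown", , drop = FALSE]
    rates <- per_1000(phage, intersect(pos_genomes, phage$genome_id))
    enr <- NULL
    if (nrow(phage) && length(unique(phage$morphology)) >= 2) {
      tab <- table(phage$morphology, phage$genome_id %in% pos_genomes)
      if (all(dim(tab) >= c(2, 2)) && !any(rowSums(tab) == 0) &&
          !any(colSums(tab) == 0)) {
        enr <- enrichment_test(as.matrix(tab))
      }
    }
    gf <- data.frame(
      genome_id = collection$proteins$genome_id[match(hits$protein_id,
                                                      collection$proteins$protein_id)],
      family = hits$family_id, stringsAsFactors = FALSE)
    gf <- unique(gf)
    cooc <- if (length(unique(gf$family)) >= 2) {
      cooccurrence(gf, g$genome_id)
    } else NULL
    list(curve = curve, classes = classes, rates = rates, enr = enr,
         cooc = cooc, genome_families = gf)
  })
  write_tsv(stats_out$curve, file.path(out_dir, "prevalence_curve.tsv"))
  write_tsv(stats_out$classes, file.path(out_dir, "class_prevalence.tsv"))
  write_tsv(stats_out$rates, file.path(out_dir, "per_1000.tsv"))
  write_tsv(stats_out$genome_families, file.path(out_dir, "genome_families.tsv"))
  if (!is.null(stats_out$cooc)) {
    write_tsv(stats_out$cooc, file.path(out_dir, "cooccurrence.tsv"))
  }
  if (!is.null(stats_out$enr)) {
    write_tsv(data.frame(chi2 = stats_out$enr$chi2, df = stats_out$enr$df,
                         p = stats_out$enr$p),
              file.path(out_dir, "morphology_enrichment.tsv"))
  }
  manifest$stages$netstats <- list(
    curve_points = nrow(stats_out$curve),
    cooccurrence_pairs = if (is.null(stats_out$cooc)) 0L else nrow(stats_out$cooc))

  manifest$warnings <- as.list(warn_collect)
  manifest$status <- "ok"
  manifest$files <- file_digests(out_dir)
  write_manifest(manifest, out_dir)
  invisible(out_dir)
}

digest_config <- function(config) {
  # order-stable digest of the config via its serialized JSON
  j <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  writeLines(j, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

file_digests <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  mapply(function(f, d) list(path = f, md5 = unname(d)), files, md5,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}
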