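# End-to-end orchestration: simulate (optional) -> depth -> scan ->
# reconcile -> predict -> classify -> summarize, with every intermediate
# written in a standard format and a run manifest capturing the
# configuration, input checksums, per-stage record counts and seed.
# Rerunning with an identical config and seed reproduces byte-identical
# outputs.

#' Default pipeline configuration
#'
#' @param simulate Logical; generate synthetic inputs instead of reading
#'   files.
#' @param genome,annotation,alignments Input paths (FASTA / GFF3 / SAM),
#'   ignored when `simulate = TRUE`.
#' @param domain_tsv Optional InterProScan TSV of domain hits for the
#'   refined proteins; when absent the internal consensus scanner is
#'   used.
#' @param synth A [synth_config()] used when simulating.
#' @param coverage A [coverage_config()].
#' @param max_gap Motif clustering gap (bases, see
#'   [cluster_motifs_to_loci()]).
#' @param ok_cds_fraction,min_cov_fraction Reconciliation thresholds
#'   (see [overlap_classify()]).
#' @param predictor A [predictor_config()].
#' @param chromosome_pattern See [summarize_nlrome()].
#' @param seed Integer seed (propagated into `synth`).
#' @return A `nlrome_config` list.
#' @export
nlrome_config <- function(simulate = TRUE, genome = NULL, annotation = NULL,
                          alignments = NULL, domain_tsv = NULL,
                          synth = synth_config(), coverage = coverage_config(),
                          max_gap = 10000L, ok_cds_fraction = 0.8,
                          min_cov_fraction = 0.5,
                          predictor = predictor_config(),
                          chromosome_pattern = "^[AC][0-9]{2}$",
                          seed = 42L) {
  synth$seed <- as.integer(seed)
  structure(list(simulate = simulate, genome = genome,
                 annotation = annotation, alignments = alignments,
                 domain_tsv = domain_tsv, synth = synth,
                 coverage = coverage, max_gap = as.integer(max_gap),
                 ok_cds_fraction = ok_cds_fraction,
                 min_cov_fraction = min_cov_fraction,
                 predictor = predictor,
                 chromosome_pattern = chromosome_pattern,
                 seed = as.integer(seed)),
            class = "nlrome_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [nlrome_config()]; nested
#' `synth`, `coverage` and `predictor` blocks override the respective
#' sub-configurations field by field.
#'
#' @param path Path to a YAML file.
#' @return An `nlrome_config` list.
#' @export
read_nlrome_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- nlrome_config()
  for (nm in intersect(names(y), setdiff(names(cfg),
                                         c("synth", "coverage", "predictor")))) {
    cfg[[nm]] <- y[[nm]]
  }
  if (!is.null(y$synth)) cfg$synth <- do.call(
    synth_config, utils::modifyList(list(), y$synth))
  if (!is.null(y$coverage)) cfg$coverage <- do.call(
    coverage_config, utils::modifyList(list(), y$coverage))
  if (!is.null(y$predictor)) cfg$predictor <- do.call(
    predictor_config, utils::modifyList(list(), y$predictor))
  cfg$synth$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full NLRome refinement pipeline
#'
#' Executes (optionally) simulation, depth computation, motif-based locus
#' prediction, reconciliation against the annotation, de novo prediction
#' in problem regions, longest-isoform selection, NLR-signature
#' filtering, annotation merging, domain-architecture classification and
#' per-chromosome summarization. All intermediates are written under
#' `out_dir` in standard formats; a JSON run manifest records the
#' configuration, checksums, per-stage counts and the seed.
#'
#' @param config An [nlrome_config()], or a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list: `summary` ([summarize_nlrome()] result), `calls`,
#'   `records` (reconciliation table), `refined` ([gene_models]),
#'   `novel_ids`, `kept_ids`, `loci`, `hicov`, `manifest`, `paths`, and
#'   when simulating also `truth` (`manifest`, `annotation`,
#'   `corruption_log`).
#' @export
run_nlrome <- function(config = nlrome_config(), out_dir = tempfile("nlrome_"),
                       quiet = TRUE) {
  if (is.character(config)) config <- read_nlrome_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  counts <- list()
  truth <- NULL

  if (isTRUE(config$simulate)) {
    say("simulating synthetic study (seed %d)", config$seed)
    gen <- generate_genome(config$synth)
    corr <- corrupt_annotation(gen$annotation, gen$manifest, config$synth)
    sim <- simulate_reads(gen$genome, gen$manifest, config$synth, out_dir)
    genome <- gen$genome
    annotation <- corr$annotation
    paths$genome <- file.path(out_dir, "genome.fa")
    write_fasta(genome, paths$genome)
    paths$truth_annotation <- file.path(out_dir, "truth.gff3")
    write_gff3(gen$annotation, paths$truth_annotation)
    paths$annotation <- file.path(out_dir, "annotation.gff3")
    write_gff3(annotation, paths$annotation)
    paths$alignments <- sim$sam
    paths$fastq1 <- sim$fastq1
    paths$fastq2 <- sim$fastq2
    data.table::fwrite(gen$manifest, file.path(out_dir, "truth_manifest.tsv"),
                       sep = "\t")
    data.table::fwrite(corr$log, file.path(out_dir, "corruption_log.tsv"),
                       sep = "\t")
    truth <- list(manifest = gen$manifest, annotation = gen$annotation,
                  corruption_log = corr$log)
    counts$planted_genes <- nrow(gen$manifest)
  } else {
    stopifnot(!is.null(config$genome), !is.null(config$annotation),
              !is.null(config$alignments))
    genome <- read_fasta(config$genome)
    annotation <- read_gff3(config$annotation)
    paths$genome <- config$genome
    paths$annotation <- config$annotation
    paths$alignments <- config$alignments
  }

  say("computing depth")
  aln <- read_alignments(paths$alignments)
  counts$alignments <- length(aln)
  track <- depth_track(aln, genome)
  paths$depth <- file.path(out_dir, "depth.bedgraph")
  write_bedgraph(track, paths$depth)
  hicov <- call_high_coverage_regions(track, config$coverage)
  counts$high_coverage_regions <- length(hicov)
  paths$hicov <- file.path(out_dir, "high_coverage.bed")
  write_bed(hicov, paths$hicov)

  say("scanning motifs")
  frames <- six_frame_translate(genome)
  hits <- scan_motifs(frames)
  counts$motif_hits <- length(hits)
  loci <- cluster_motifs_to_loci(hits, max_gap = config$max_gap)
  counts$predicted_loci <- length(loci)
  paths$loci <- file.path(out_dir, "predicted_loci.bed")
  lo <- loci
  S4Vectors::mcols(lo)$name <- S4Vectors::mcols(loci)$locus_id
  write_bed(lo, paths$loci)

  say("reconciling")
  records <- overlap_classify(annotation, loci, hicov,
                              ok_cds_fraction = config$ok_cds_fraction,
                              min_cov_fraction = config$min_cov_fraction)
  paths$reconciliation <- file.path(out_dir, "reconciliation.tsv")
  data.table::fwrite(records, paths$reconciliation, sep = "\t")
  counts$loci_ok <- sum(records$category == "ok")
  counts$loci_missing <- sum(records$category == "missing")
  counts$loci_misannotated <- sum(records$category == "misannotated")
  counts$loci_fused <- sum(records$category == "fused")

  prob <- extract_problem_regions(records, genome,
                                  flank = config$coverage$flank)
  counts$problem_regions <- length(prob$regions)
  if (length(prob$regions) > 0L) {
    paths$problem_bed <- file.path(out_dir, "problem_regions.bed")
    write_bed(prob$regions, paths$problem_bed)
    paths$problem_fa <- file.path(out_dir, "problem_regions.fa")
    write_fasta(prob$sequences, paths$problem_fa)
  }

  say("predicting genes in %d problem region(s)", length(prob$regions))
  novel_local <- predict_genes(prob$sequences, config$predictor)
  novel_local <- longest_isoform(novel_local)
  novel <- lift_models(novel_local)
  counts$novel_candidates <- length(novel)

  # NLR-signature filter: keep candidates whose protein carries at least
  # one canonical NLR domain
  novel_prot <- if (length(cds_of(novel)) > 0L)
    translate_models(novel, genome) else Biostrings::AAStringSet()
  novel_hits <- if (length(novel_prot) > 0L) {
    assign_categories(internal_domain_scan(novel_prot))
  } else internal_domain_scan(Biostrings::AAStringSet())
  canonical <- c("TIR", "CC", "RPW8", "NBARC", "LRR", "CJID")
  keep_tx <- unique(novel_hits$protein_id[novel_hits$category %in% canonical])
  novel <- if (length(keep_tx) > 0L)
    subset_models(novel, transcript_ids = keep_tx) else empty_gene_models()
  counts$novel_nlr_models <- length(novel)

  say("merging annotations")
  supporting <- unique(unlist(strsplit(records$genes[nzchar(records$genes)],
                                       ",", fixed = TRUE)))
  ok_rec <- records$category == "ok" & records$coverage_support
  keep_ids <- unique(unlist(strsplit(records$genes[ok_rec], ",", fixed = TRUE)))
  # a gene supporting both an ok locus and a problem locus is not kept
  bad_ids <- unique(unlist(strsplit(records$genes[records$category != "ok"],
                                    ",", fixed = TRUE)))
  keep_ids <- setdiff(keep_ids, bad_ids)
  refined <- merge_annotations(annotation, supporting, keep_ids, novel)
  conflicts <- attr(refined, "conflicts")
  if (length(conflicts) > 0L) {
    novel <- subset_models(novel, transcript_ids = setdiff(
      tx_table(novel)$transcript_id, conflicts))
  }
  counts$novel_nlr_models <- length(novel)
  counts$kept_ok_models <- length(keep_ids)
  counts$refined_nlr_models <- length(keep_ids) + length(novel)
  paths$refined <- file.path(out_dir, "refined.gff3")
  write_gff3(refined, paths$refined)

  say("classifying")
  nlr_models <- subset_models(refined, gene_ids = c(
    keep_ids, unique(tx_table(novel)$gene_id)))
  proteins <- translate_models_safely(nlr_models, genome)
  paths$proteins <- file.path(out_dir, "nlr_proteins.faa")
  if (length(proteins) > 0L) write_fasta(proteins, paths$proteins)
  dom_hits <- if (!is.null(config$domain_tsv)) {
    read_domain_tsv(config$domain_tsv)
  } else {
    internal_domain_scan(proteins)
  }
  dom_hits <- assign_categories(dom_hits)
  calls <- classify_architecture(dom_hits, protein_ids = names(proteins))
  paths$calls <- file.path(out_dir, "architecture_calls.tsv")
  write_calls_tsv(calls, paths$calls)
  nbarc <- extract_nbarc(dom_hits, proteins)
  if (length(nbarc) > 0L) {
    paths$nbarc <- file.path(out_dir, "nbarc_domains.faa")
    write_fasta(nbarc, paths$nbarc)
  }
  counts$classified_proteins <- nrow(calls)

  say("summarizing")
  summ <- summarize_nlrome(calls, models = nlr_models,
                           chromosome_pattern = config$chromosome_pattern)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ[setdiff(names(summ), "per_chromosome_class")],
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), c("synth", "coverage", "predictor"))],
    synth = if (isTRUE(config$simulate)) unclass(config$synth) else NULL,
    coverage = unclass(config$coverage),
    predictor = unclass(config$predictor)[
      !vapply(unclass(config$predictor), is.null, logical(1L))],
    input_checksums = as.list(tools::md5sum(unlist(
      paths[intersect(c("genome", "annotation", "alignments"), names(paths))]))),
    stage_counts = counts)
  paths$manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")

  list(summary = summ, calls = calls, records = records, refined = refined,
       novel_ids = unique(tx_table(novel)$gene_id), kept_ids = keep_ids,
       loci = loci, hicov = hicov, proteins = proteins,
       manifest = manifest, paths = paths, truth = truth,
       out_dir = out_dir)
}

# translate models, skipping (with a warning) any that fail -- real
# annotations can contain models with internal stops or frame problems
translate_models_safely <- function(gm, genome) {
  tx <- tx_table(gm)
  out <- character(0L)
  for (id in tx$transcript_id) {
    p <- tryCatch(
      as.character(translate_models(subset_models(gm, transcript_ids = id),
                                    genome)),
      error = function(e) {
        warning("skipping untranslatable model ", id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(p)) out[id] <- p
  }
  Biostrings::AAStringSet(out)
}
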