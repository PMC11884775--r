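# Overlay of three evidence tracks -- annotation CDS, predicted NLR loci,
# and high-coverage regions -- and the three-way misannotation taxonomy:
#   missing      predicted locus with no annotated CDS overlap
#   misannotated an annotated gene covers too little of the locus
#   fused        one annotated gene supports two or more loci
# plus ok for loci whose gene covers them sufficiently.

#' Classify predicted loci against the existing annotation
#'
#' For every predicted locus: no overlapping annotated CDS means
#' `missing`; an overlapping gene whose CDS covers at least
#' `ok_cds_fraction` of the locus means `ok`; less means `misannotated`;
#' and any single gene whose CDS overlaps two or more loci drags all its
#' loci into `fused` (fused takes precedence, because the repair — model
#' splitting — differs fundamentally). Coverage support is a flag
#' (`>= min_cov_fraction` of locus bases inside a high-coverage region);
#' unsupported loci keep their category but are excluded from repair by
#' default downstream.
#'
#' @param genes A [gene_models] object (the existing annotation).
#' @param loci A `GRanges` of predicted loci (see
#'   [cluster_motifs_to_loci()]).
#' @param hicov A `GRanges` of high-coverage regions (see
#'   [call_high_coverage_regions()]).
#' @param ok_cds_fraction Minimum fraction of locus bases covered by one
#'   gene's CDS to call it correctly annotated (default 0.8).
#' @param min_cov_fraction Minimum fraction of locus bases inside a
#'   high-coverage region for coverage support (default 0.5).
#' @return A `data.frame`, one row per locus: `locus_id`, `seqnames`,
#'   `start`, `end`, `strand`, `completeness`, `category`, `genes`
#'   (comma-separated supporting gene ids), `cds_overlap_fraction`,
#'   `coverage_support`.
#' @export
overlap_classify <- function(genes, loci, hicov, ok_cds_fraction = 0.8,
                             min_cov_fraction = 0.5) {
  n <- length(loci)
  out <- data.frame(
    locus_id = if (n) S4Vectors::mcols(loci)$locus_id else character(),
    seqnames = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci), end = GenomicRanges::end(loci),
    strand = as.character(GenomicRanges::strand(loci)),
    completeness = if (n) S4Vectors::mcols(loci)$completeness else character(),
    category = character(n), genes = character(n),
    cds_overlap_fraction = numeric(n), coverage_support = logical(n),
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  # coverage support: fraction of locus bases inside hicov
  cov_frac <- rep(0, n)
  if (length(hicov) > 0L) {
    ov <- GenomicRanges::findOverlaps(loci, hicov, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      inter <- IRanges::pintersect(
        IRanges::ranges(loci)[S4Vectors::queryHits(ov)],
        IRanges::ranges(hicov)[S4Vectors::subjectHits(ov)])
      bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      cov_frac[as.integer(names(bp))] <- as.numeric(bp) /
        GenomicRanges::width(loci)[as.integer(names(bp))]
    }
  }
  out$coverage_support <- cov_frac >= min_cov_fraction

  # per locus x gene CDS overlap (strand-blind: a misannotated model may
  # even sit on the wrong strand)
  cds <- cds_of(genes)
  best_frac <- rep(0, n)
  support <- vector("list", n)
  gene_loci <- list()
  if (length(cds) > 0L) {
    ov <- GenomicRanges::findOverlaps(loci, cds, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      inter <- IRanges::pintersect(IRanges::ranges(loci)[q],
                                   IRanges::ranges(cds)[s])
      dt <- data.table::data.table(
        locus = q, gene = S4Vectors::mcols(cds)$gene_id[s],
        bp = IRanges::width(inter))
      per <- dt[, list(bp = sum(bp)), by = c("locus", "gene")]
      per[, frac := bp / GenomicRanges::width(loci)[locus]]
      for (j in unique(per$locus)) {
        sub <- per[per$locus == j]
        support[[j]] <- sort(unique(sub$gene))
        best_frac[j] <- max(sub$frac)
      }
      gene_loci <- split(per$locus, per$gene)
    }
  }
  out$cds_overlap_fraction <- best_frac
  out$genes <- vapply(support, function(g)
    paste(g, collapse = ","), character(1L))

  out$category <- ifelse(lengths(support) == 0L, "missing",
                         ifelse(best_frac >= ok_cds_fraction,
                                "ok", "misannotated"))
  # fused precedence: any gene supporting >= 2 loci
  fused_genes <- names(gene_loci)[lengths(lapply(gene_loci, unique)) >= 2L]
  if (length(fused_genes) > 0L) {
    fused_loci <- unique(unlist(gene_loci[fused_genes]))
    out$category[fused_loci] <- "fused"
  }
  out
}

#' Extract problem regions around repair-worthy loci
#'
#' Takes the loci classified as anything but `ok` that have coverage
#' support, flanks them, clips to sequence bounds, merges overlaps, and
#' slices the corresponding genome sequence. Region ids encode
#' `seqid:start-end` (1-based inclusive).
#'
#' @param records Output of [overlap_classify()].
#' @param genome A named `DNAStringSet`.
#' @param flank Flank size in bases (default 1000).
#' @return A list with `regions` (a `GRanges` with `name`, source
#'   `categories` and `locus_ids` columns) and `sequences` (a
#'   `DNAStringSet` of the region sequences).
#' @export
extract_problem_regions <- function(records, genome, flank = 1000L) {
  sel <- records$category != "ok" & records$coverage_support
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(regions = GenomicRanges::GRanges(),
                sequences = Biostrings::DNAStringSet()))
  }
  loci <- GenomicRanges::GRanges(sub$seqnames,
                                 IRanges::IRanges(sub$start, sub$end))
  regions <- add_flanks(loci, genome, flank)
  ov <- GenomicRanges::findOverlaps(loci, regions, ignore.strand = TRUE)
  cats <- vapply(seq_along(regions), function(j) {
    paste(sort(unique(sub$category[S4Vectors::queryHits(ov)[
      S4Vectors::subjectHits(ov) == j]])), collapse = ",")
  }, character(1L))
  lids <- vapply(seq_along(regions), function(j) {
    paste(sub$locus_id[S4Vectors::queryHits(ov)[
      S4Vectors::subjectHits(ov) == j]], collapse = ",")
  }, character(1L))
  ids <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(regions)),
                 GenomicRanges::start(regions), GenomicRanges::end(regions))
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    name = ids, categories = cats, locus_ids = lids)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(j) {
    as.character(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(regions))[j]]],
      GenomicRanges::start(regions)[j], GenomicRanges::end(regions)[j]))
  }, character(1L)))
  names(seqs) <- ids
  list(regions = regions, sequences = seqs)
}

#' Lift region-local gene models to genome coordinates
#'
#' @param gm A [gene_models] object whose seqnames are region ids of the
#'   form `seqid:start-end` (1-based), as produced by
#'   [extract_problem_regions()].
#' @return A [gene_models] object in genome coordinates.
#' @export
lift_models <- function(gm) {
  cds <- cds_of(gm)
  if (length(cds) == 0L) return(gm)
  rid <- as.character(GenomicRanges::seqnames(cds))
  m <- regmatches(rid, regexec("^(.*):(\\d+)-(\\d+)$", rid))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("seqnames are not region ids: ", rid[bad][1L])
  seqid <- vapply(m, `[`, character(1L), 2L)
  offset <- as.integer(vapply(m, `[`, character(1L), 3L)) - 1L
  out <- GenomicRanges::GRanges(
    seqid,
    IRanges::IRanges(GenomicRanges::start(cds) + offset,
                     GenomicRanges::end(cds) + offset),
    strand = GenomicRanges::strand(cds))
  S4Vectors::mcols(out) <- S4Vectors::mcols(cds)
  gene_models(out)
}

#' Merge the kept annotation with novel gene models
#'
#' Produces the refined annotation: original genes minus the NLR-related
#' models judged wrong, plus the novel models predicted in problem
#' regions. Non-NLR genes (those never supporting a predicted locus) pass
#' through untouched. A novel model sharing more than 50% reciprocal CDS
#' overlap with a kept model is rejected and reported in the
#' `conflicts` attribute.
#'
#' @param original A [gene_models] object (full original annotation).
#' @param nlr_gene_ids Gene ids that support any predicted locus.
#' @param keep_gene_ids Subset of `nlr_gene_ids` judged correctly
#'   annotated (category `ok`).
#' @param novel A [gene_models] object in genome coordinates.
#' @return A [gene_models] object; attribute `conflicts` lists rejected
#'   novel transcript ids.
#' @export
merge_annotations <- function(original, nlr_gene_ids, keep_gene_ids, novel) {
  orig_tx <- tx_table(original)
  drop <- setdiff(nlr_gene_ids, keep_gene_ids)
  kept <- subset_models(original, gene_ids = setdiff(unique(orig_tx$gene_id), drop))
  novel_tx <- tx_table(novel)
  if (any(novel_tx$gene_id %in% unique(orig_tx$gene_id))) {
    stop("novel gene id(s) collide with original annotation: ",
         paste(intersect(novel_tx$gene_id, orig_tx$gene_id), collapse = ", "))
  }
  conflicts <- character(0L)
  if (nrow(novel_tx) > 0L && length(cds_of(kept)) > 0L) {
    kcds <- cds_of(kept)
    ncds <- cds_of(novel)
    ov <- GenomicRanges::findOverlaps(ncds, kcds, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      inter <- IRanges::pintersect(
        IRanges::ranges(ncds)[S4Vectors::queryHits(ov)],
        IRanges::ranges(kcds)[S4Vectors::subjectHits(ov)])
      dt <- data.table::data.table(
        ntx = S4Vectors::mcols(ncds)$transcript_id[S4Vectors::queryHits(ov)],
        ktx = S4Vectors::mcols(kcds)$transcript_id[S4Vectors::subjectHits(ov)],
        bp = IRanges::width(inter))
      per <- dt[, list(bp = sum(bp)), by = c("ntx", "ktx")]
      nlen <- setNames(novel_tx$cds_len, novel_tx$transcript_id)
      ktx_tab <- tx_table(kept)
      klen <- setNames(ktx_tab$cds_len, ktx_tab$transcript_id)
      recip <- per$bp / nlen[per$ntx] > 0.5 & per$bp / klen[per$ktx] > 0.5
      conflicts <- sort(unique(per$ntx[recip]))
    }
  }
  novel_ok <- if (length(conflicts) > 0L) {
    subset_models(novel,
                  transcript_ids = setdiff(novel_tx$transcript_id, conflicts))
  } else novel
  out <- combine_models(kept, novel_ok)
  attr(out, "conflicts") <- conflicts
  out
}
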