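#' Read a GFF3 annotation into gene models
#'
#' Parses a gene/mRNA/CDS hierarchy (features linked by `ID`/`Parent`) via
#' [rtracklayer::import()]. A CDS whose `Parent` points directly at a gene
#' (no mRNA tier) is accepted, with the gene id doubling as transcript id.
#' GFF3's 1-based inclusive coordinates are kept as-is internally (the
#' GenomicRanges convention).
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_gene_models())
  type <- as.character(gr$type)
  cds <- gr[type == "CDS"]
  if (length(cds) == 0L) return(empty_gene_models())
  parents <- gr$Parent
  cds_parent <- vapply(as.list(cds$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1L))
  if (anyNA(cds_parent)) stop("CDS feature without Parent in ", path)
  # transcript -> gene map from the mRNA tier (fall back to self-parenting)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  tx2gene <- setNames(
    vapply(as.list(mrna$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else p[[1L]]
    }, character(1L)),
    as.character(mrna$ID)
  )
  gene_id <- ifelse(cds_parent %in% names(tx2gene),
                    unname(tx2gene[cds_parent]), cds_parent)
  gene_id[is.na(gene_id)] <- cds_parent[is.na(gene_id)]
  phase <- cds$phase
  if (is.null(phase)) phase <- rep(0L, length(cds))
  phase[is.na(phase)] <- 0L
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(cds),
    ranges = IRanges::ranges(cds),
    strand = GenomicRanges::strand(cds),
    gene_id = gene_id,
    transcript_id = cds_parent,
    phase = as.integer(phase)
  )
  gene_models(out)
}

#' Write gene models as GFF3 (gene/mRNA/CDS hierarchy)
#'
#' @param gm A [gene_models] object.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gm, path, source = "nlromer") {
  tx <- tx_table(gm)
  cds <- cds_of(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tx) == 0L) return(invisible(path))
  # gene spans = hull over the gene's transcripts
  gdt <- data.table::as.data.table(tx)
  genes <- gdt[, list(seqnames = seqnames[1L], start = min(start),
                      end = max(end), strand = strand[1L]), by = "gene_id"]
  lines <- character(0L)
  fmt <- function(seqid, type, start, end, strand, phase, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, source, type, start, end, strand, phase, attrs)
  }
  lines <- c(lines, fmt(genes$seqnames, "gene", genes$start, genes$end,
                        genes$strand, ".", sprintf("ID=%s", genes$gene_id)))
  lines <- c(lines, fmt(tx$seqnames, "mRNA", tx$start, tx$end, tx$strand, ".",
                        sprintf("ID=%s;Parent=%s", tx$transcript_id, tx$gene_id)))
  lines <- c(lines, fmt(as.character(GenomicRanges::seqnames(cds)), "CDS",
                        GenomicRanges::start(cds), GenomicRanges::end(cds),
                        as.character(GenomicRanges::strand(cds)),
                        as.character(S4Vectors::mcols(cds)$phase),
                        sprintf("ID=cds-%s;Parent=%s",
                                S4Vectors::mcols(cds)$transcript_id,
                                S4Vectors::mcols(cds)$transcript_id)))
  # stable order: by position then feature rank for readable output
  writeLines(lines, con)
  invisible(path)
}

#' Export intervals as BED6
#'
#' @param gr A `GRanges`; `name`/`score` metadata columns are used when
#'   present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name)) name <- sprintf("region_%05d", seq_along(gr))
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(0L, length(gr))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,  # BED is 0-based half-open
                   GenomicRanges::end(gr),
                   name, as.character(score),
                   as.character(GenomicRanges::strand(gr)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a depth track as bedGraph
#'
#' @param track An `RleList` of per-base depths (see [depth_track()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- methods::as(track, "GRanges")
  lines <- sprintf("%s\t%d\t%d\t%g",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   S4Vectors::mcols(gr)$score)
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}
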