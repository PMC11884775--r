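#' Gene model container
#'
#' A `gene_models` object is a thin S3 wrapper around a
#' [GenomicRanges::GRanges] of CDS parts carrying `gene_id`,
#' `transcript_id` and `phase` metadata columns. Transcript and gene spans
#' are derived, never stored, so the CDS ranges are the single source of
#' truth. Coordinates are 1-based closed (the GenomicRanges convention);
#' conversion to and from the 1-based GFF3 and 0-based BED conventions
#' happens only inside the readers and writers.
#'
#' @param cds A `GRanges` of CDS parts with metadata columns `gene_id`,
#'   `transcript_id` and optionally `phase` (defaults to 0).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(cds) {
  stopifnot(methods::is(cds, "GRanges"))
  mc <- S4Vectors::mcols(cds)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id)) {
    stop("cds must carry gene_id and transcript_id metadata columns")
  }
  if (is.null(mc$phase)) S4Vectors::mcols(cds)$phase <- 0L
  # sort parts within transcript by position; reject overlapping parts
  ord <- order(S4Vectors::mcols(cds)$transcript_id,
               as.character(GenomicRanges::seqnames(cds)),
               GenomicRanges::start(cds))
  cds <- cds[ord]
  if (length(cds) > 1L) {
    tx <- S4Vectors::mcols(cds)$transcript_id
    same <- tx[-1L] == tx[-length(tx)]
    ov <- GenomicRanges::start(cds)[-1L] <= GenomicRanges::end(cds)[-length(cds)] &
      as.character(GenomicRanges::seqnames(cds))[-1L] ==
        as.character(GenomicRanges::seqnames(cds))[-length(cds)]
    if (any(same & ov)) {
      stop("overlapping CDS parts within transcript(s): ",
           paste(unique(tx[-1L][same & ov]), collapse = ", "))
    }
  }
  structure(list(cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  tx <- tx_table(x)
  cat(sprintf("<gene_models> %d gene(s), %d transcript(s), %d CDS part(s)\n",
              length(unique(tx$gene_id)), nrow(tx), length(x$cds)))
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(unique(cds_of(x)$transcript_id))

#' CDS parts of a gene model set
#' @param gm A `gene_models` object.
#' @return A `GRanges` of CDS parts.
#' @export
cds_of <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  gr <- gm$cds
  S4Vectors::mcols(gr)$gene_id <- as.character(S4Vectors::mcols(gr)$gene_id)
  S4Vectors::mcols(gr)$transcript_id <- as.character(S4Vectors::mcols(gr)$transcript_id)
  gr
}

#' Per-transcript summary table
#'
#' @param gm A `gene_models` object.
#' @return A `data.frame` with one row per transcript: `gene_id`,
#'   `transcript_id`, `seqnames`, `start`, `end`, `strand`, `cds_len`.
#' @export
tx_table <- function(gm) {
  cds <- cds_of(gm)
  if (length(cds) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      cds_len = integer(), stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(cds)$gene_id,
    transcript_id = S4Vectors::mcols(cds)$transcript_id,
    seqnames = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    width = GenomicRanges::width(cds)
  )
  out <- dt[, list(gene_id = gene_id[1L], seqnames = seqnames[1L],
                   start = min(start), end = max(end), strand = strand[1L],
                   cds_len = sum(width)),
            by = "transcript_id"]
  data.table::setcolorder(out, c("gene_id", "transcript_id", "seqnames",
                                 "start", "end", "strand", "cds_len"))
  as.data.frame(out)
}

#' Subset gene models by transcript or gene id
#' @param gm A `gene_models` object.
#' @param transcript_ids,gene_ids Character vectors; keep matching models.
#' @return A `gene_models` object.
#' @export
subset_models <- function(gm, transcript_ids = NULL, gene_ids = NULL) {
  cds <- cds_of(gm)
  keep <- rep(TRUE, length(cds))
  if (!is.null(transcript_ids)) {
    keep <- keep & S4Vectors::mcols(cds)$transcript_id %in% transcript_ids
  }
  if (!is.null(gene_ids)) {
    keep <- keep & S4Vectors::mcols(cds)$gene_id %in% gene_ids
  }
  gene_models(cds[keep])
}

#' Concatenate gene model sets
#' @param ... `gene_models` objects.
#' @return A combined `gene_models` object; duplicated transcript ids are an
#'   error.
#' @export
combine_models <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(g) length(cds_of(g)) > 0L, logical(1L))]
  if (length(sets) == 0L) return(empty_gene_models())
  cds <- suppressWarnings(do.call(c, lapply(sets, cds_of)))
  ids <- lapply(sets, function(g) unique(cds_of(g)$transcript_id))
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids)) {
    stop("transcript id collision: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  gene_models(cds)
}

empty_gene_models <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$gene_id <- character()
  S4Vectors::mcols(gr)$transcript_id <- character()
  S4Vectors::mcols(gr)$phase <- integer()
  gene_models(gr)
}
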