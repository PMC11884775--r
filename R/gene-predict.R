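#' Gene predictor configuration
#'
#' @param min_orf_length Minimum ORF length in nucleotides, including the
#'   stop codon; must be divisible by 3 (default 300).
#' @param external_cmd Optional command template for an external de novo
#'   predictor (e.g. AUGUSTUS); `{fasta}` is replaced by the region FASTA
#'   path and the command must print GFF3 on stdout.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(min_orf_length = 300L, external_cmd = NULL) {
  stopifnot(min_orf_length %% 3L == 0L, min_orf_length >= 3L)
  structure(list(min_orf_length = as.integer(min_orf_length),
                 external_cmd = external_cmd),
            class = "predictor_config")
}

# maximal ORFs (ATG..stop, stop included) in one frame of one sequence;
# returns local 1-based closed coordinates on the read strand
orfs_in_frame <- function(seq_chr, frame) {
  L <- nchar(seq_chr)
  n_codon <- (L - frame + 1L) %/% 3L
  if (n_codon < 2L) return(NULL)
  starts <- frame + 3L * (0:(n_codon - 1L))
  codons <- substring(seq_chr, starts, starts + 2L)
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  is_atg <- codons == "ATG"
  stop_idx <- which(is_stop)
  if (length(stop_idx) == 0L) return(NULL)
  seg_start <- c(1L, utils::head(stop_idx, -1L) + 1L)
  res <- NULL
  for (i in seq_along(stop_idx)) {
    rng <- seg_start[i]:stop_idx[i]
    atg <- rng[is_atg[rng]]
    if (length(atg) == 0L) next
    a <- atg[1L]
    res <- rbind(res, c(start = starts[a], end = starts[stop_idx[i]] + 2L))
  }
  res
}

#' De novo gene prediction inside extracted regions
#'
#' Internal mode finds all maximal open reading frames (first ATG after
#' the previous in-frame stop, through the next stop, stop codon
#' included) of at least `min_orf_length` nucleotides in all six frames;
#' ORFs nested inside a longer same-strand ORF are suppressed. The
#' predictor is intronless by design — spliced prediction is delegated to
#' an external tool via `external_cmd`, whose GFF3 output is parsed under
#' the same contract. Coordinates are region-local; lift with
#' [lift_models()].
#'
#' @param regions A named `DNAStringSet` of region sequences.
#' @param cfg A [predictor_config()].
#' @return A [gene_models] object with region-local coordinates; gene ids
#'   are `<region>_g<i>`, transcripts `<gene>.t1`.
#' @export
predict_genes <- function(regions, cfg = predictor_config()) {
  if (!is.null(cfg$external_cmd)) return(predict_genes_external(regions, cfg))
  rows <- list()
  for (rid in names(regions)) {
    s <- as.character(regions[[rid]])
    L <- nchar(s)
    rc <- as.character(Biostrings::reverseComplement(regions[[rid]]))
    orfs <- NULL
    for (f in 1:3) {
      o <- orfs_in_frame(s, f)
      if (!is.null(o)) orfs <- rbind(orfs, cbind(o, strand = 1L))
      o <- orfs_in_frame(rc, f)
      if (!is.null(o)) {
        # map revcomp coordinates back to the forward strand
        o2 <- cbind(start = L - o[, "end"] + 1L, end = L - o[, "start"] + 1L)
        orfs <- rbind(orfs, cbind(o2, strand = 2L))
      }
    }
    if (is.null(orfs)) next
    orfs <- as.data.frame(orfs)
    orfs <- orfs[orfs$end - orfs$start + 1L >= cfg$min_orf_length, , drop = FALSE]
    if (nrow(orfs) == 0L) next
    # suppress ORFs nested within a longer same-strand ORF
    keep <- rep(TRUE, nrow(orfs))
    len <- orfs$end - orfs$start + 1L
    for (i in seq_len(nrow(orfs))) {
      nested <- orfs$strand == orfs$strand[i] & seq_len(nrow(orfs)) != i &
        orfs$start >= orfs$start[i] & orfs$end <= orfs$end[i] & len < len[i]
      keep[nested] <- FALSE
    }
    orfs <- orfs[keep, , drop = FALSE]
    orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
    rows[[rid]] <- data.frame(region = rid, start = orfs$start,
                              end = orfs$end,
                              strand = c("+", "-")[orfs$strand],
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_gene_models())
  df <- do.call(rbind, rows)
  idx <- stats::ave(seq_len(nrow(df)), df$region, FUN = seq_along)
  gid <- sprintf("%s_g%d", df$region, idx)
  gr <- GenomicRanges::GRanges(df$region,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand,
                               gene_id = gid,
                               transcript_id = paste0(gid, ".t1"),
                               phase = 0L)
  gene_models(gr)
}

predict_genes_external <- function(regions, cfg) {
  fa <- tempfile(fileext = ".fa")
  write_fasta(regions, fa)
  cmd <- gsub("{fasta}", fa, cfg$external_cmd, fixed = TRUE)
  out <- tryCatch(system(cmd, intern = TRUE),
                  warning = function(w) stop("external predictor failed: ",
                                             conditionMessage(w)),
                  error = function(e) stop("external predictor failed: ",
                                           conditionMessage(e)))
  gff <- tempfile(fileext = ".gff3")
  writeLines(out, gff)
  read_gff3(gff)
}

#' Keep the longest isoform of every gene
#'
#' One transcript per gene: maximal total CDS length, ties broken by the
#' lexicographically smallest transcript id.
#'
#' @param gm A [gene_models] object.
#' @return A [gene_models] object with one transcript per gene.
#' @export
longest_isoform <- function(gm) {
  tx <- tx_table(gm)
  if (nrow(tx) == 0L) return(gm)
  tx <- tx[order(tx$gene_id, -tx$cds_len, tx$transcript_id), ]
  keep <- tx$transcript_id[!duplicated(tx$gene_id)]
  subset_models(gm, transcript_ids = keep)
}

#' Translate gene models to proteins
#'
#' Concatenates each transcript's CDS parts in transcript orientation,
#' translates with the standard code, and strips the trailing stop. An
#' internal stop codon is an error naming the offending model.
#'
#' @param gm A [gene_models] object.
#' @param seqs A named `DNAStringSet` containing every seqname used by
#'   `gm` (genome or region sequences, matching the model coordinates).
#' @return A named `AAStringSet`, one protein per transcript.
#' @export
translate_models <- function(gm, seqs) {
  cds <- cds_of(gm)
  tx_ids <- unique(S4Vectors::mcols(cds)$transcript_id)
  prots <- character(length(tx_ids))
  for (i in seq_along(tx_ids)) {
    p <- cds[S4Vectors::mcols(cds)$transcript_id == tx_ids[i]]
    strand <- as.character(GenomicRanges::strand(p))[1L]
    p <- p[order(GenomicRanges::start(p),
                 decreasing = identical(strand, "-"))]
    parts <- vapply(seq_along(p), function(j) {
      s <- Biostrings::subseq(seqs[[as.character(GenomicRanges::seqnames(p))[j]]],
                              GenomicRanges::start(p)[j],
                              GenomicRanges::end(p)[j])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1L))
    nt <- paste(parts, collapse = "")
    if (nchar(nt) %% 3L != 0L) {
      stop("CDS length of ", tx_ids[i], " is not divisible by 3")
    }
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "X")))
    if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", aa, fixed = TRUE)) {
      stop("internal stop codon in model ", tx_ids[i])
    }
    prots[i] <- aa
  }
  out <- Biostrings::AAStringSet(prots)
  names(out) <- tx_ids
  out
}
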