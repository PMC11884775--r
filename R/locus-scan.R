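#' Six-frame translation with genome coordinate maps
#'
#' Translates every genome sequence in all six frames with the standard
#' codon table. Stops become `*`; codons containing an ambiguous base (N)
#' become `X`. Each frame keeps the arithmetic needed to map peptide
#' positions back to stranded genomic coordinates.
#'
#' @param genome A named `DNAStringSet`.
#' @return A list, one element per sequence, each a list of six frames
#'   (`+1,+2,+3,-1,-2,-3`) with fields `aa` (peptide string), `frame`,
#'   `seq_id` and `seq_len`.
#' @export
six_frame_translate <- function(genome) {
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (i in seq_along(genome)) {
    s <- genome[[i]]
    L <- length(s)
    rc <- Biostrings::reverseComplement(s)
    frames <- vector("list", 6L)
    names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
    for (f in 1:3) {
      for (strand in c("+", "-")) {
        src <- if (strand == "+") s else rc
        n_codon <- (L - f + 1L) %/% 3L
        aa <- if (n_codon < 1L) "" else {
          sub <- Biostrings::subseq(src, f, f + 3L * n_codon - 1L)
          as.character(suppressWarnings(
            Biostrings::translate(sub, if.fuzzy.codon = "X",
                                  no.init.codon = TRUE)))
        }
        frames[[paste0(strand, f)]] <- list(
          aa = aa, frame = if (strand == "+") f else -f,
          seq_id = names(genome)[i], seq_len = L)
      }
    }
    out[[i]] <- frames
  }
  out
}

# peptide match [a, b] (1-based aa positions) -> genomic 1-based closed
# interval for a given frame on a sequence of length L
frame_to_genomic <- function(a, b, frame, L) {
  f <- abs(frame)
  s1 <- f + 3L * (a - 1L)         # nt start on the read strand
  e1 <- f + 3L * b - 1L           # nt end on the read strand
  if (frame > 0L) {
    cbind(start = s1, end = e1)
  } else {
    cbind(start = L - e1 + 1L, end = L - s1 + 1L)
  }
}

#' Scan six-frame translations for NLR motifs
#'
#' Finds every non-overlapping match of each degenerate motif pattern in
#' every frame and reports it in stranded genomic coordinates.
#'
#' @param frames Output of [six_frame_translate()].
#' @param motif_set A motif table (default [nlr_motif_table()]): columns
#'   `motif_id`, `pattern`, `domain`, `group`.
#' @return A `GRanges` of motif hits with metadata columns `motif_id`,
#'   `domain`, `group`, `frame`, `aa_start`.
#' @export
scan_motifs <- function(frames, motif_set = nlr_motif_table()) {
  bad <- vapply(motif_set$pattern, function(p)
    inherits(try(grepl(p, "A", perl = TRUE), silent = TRUE), "try-error"),
    logical(1L))
  if (any(bad)) {
    stop("malformed motif pattern(s): ",
         paste(motif_set$motif_id[bad], collapse = ", "))
  }
  res <- list()
  k <- 0L
  for (seq_frames in frames) {
    for (fr in seq_frames) {
      if (!nzchar(fr$aa)) next
      for (m in seq_len(nrow(motif_set))) {
        hits <- gregexpr(motif_set$pattern[m], fr$aa, perl = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        a <- as.integer(hits)
        b <- a + attr(hits, "match.length") - 1L
        coords <- frame_to_genomic(a, b, fr$frame, fr$seq_len)
        k <- k + 1L
        res[[k]] <- data.frame(
          seqnames = fr$seq_id, start = coords[, "start"],
          end = coords[, "end"],
          strand = if (fr$frame > 0L) "+" else "-",
          motif_id = motif_set$motif_id[m],
          domain = motif_set$domain[m],
          group = motif_set$group[m],
          frame = fr$frame, aa_start = a,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motif_id = character(), domain = character(), group = character(),
      frame = integer(), aa_start = integer())
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motif_id = df$motif_id, domain = df$domain, group = df$group,
    frame = df$frame, aa_start = df$aa_start)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Cluster motif hits into predicted NLR loci
#'
#' Single-linkage clustering of same-sequence, same-strand hits whose gap
#' is at most `max_gap` bases; a locus interval is the hull of its member
#' hits. Completeness follows the NB-ARC two-sided rule: `complete` needs
#' at least one P-loop-side motif (P-loop/Kinase-2/RNBS-B) *and* one
#' GLPL/MHD-side motif on the same reading frame; both sides present but
#' only across different frames is flagged `pseudogene-like` (a frameshift
#' indicator); anything else is `partial`.
#'
#' @param hits A `GRanges` from [scan_motifs()].
#' @param max_gap Maximum within-locus gap in bases (default 10000).
#' @return A `GRanges` of predicted loci with metadata columns `locus_id`,
#'   `n_hits`, `completeness`, `motifs`.
#' @export
cluster_motifs_to_loci <- function(hits, max_gap = 10000L) {
  empty <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_id = character(), n_hits = integer(),
      completeness = character(), motifs = character())
    gr
  }
  if (length(hits) == 0L) return(empty())
  clusters <- GenomicRanges::reduce(hits, min.gapwidth = max_gap + 1L,
                                    ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(hits, clusters)
  stopifnot(length(ov) == length(hits))
  idx <- S4Vectors::subjectHits(ov)
  mc <- S4Vectors::mcols(hits)
  comp <- vapply(seq_along(clusters), function(j) {
    g <- mc$group[idx == j]
    fr <- mc$frame[idx == j]
    by_frame <- split(g, fr)
    same_frame_complete <- any(vapply(by_frame, function(gg)
      any(gg == "ploop") && any(gg == "mhd"), logical(1L)))
    if (same_frame_complete) "complete"
    else if (any(g == "ploop") && any(g == "mhd")) "pseudogene-like"
    else "partial"
  }, character(1L))
  motifs <- vapply(seq_along(clusters), function(j)
    paste(mc$motif_id[idx == j], collapse = ","), character(1L))
  ord <- order(as.character(GenomicRanges::seqnames(clusters)),
               GenomicRanges::start(clusters))
  clusters <- clusters[ord]
  S4Vectors::mcols(clusters) <- S4Vectors::DataFrame(
    locus_id = sprintf("locus_%04d", seq_along(clusters)),
    n_hits = tabulate(idx, nbins = length(ord))[ord],
    completeness = comp[ord], motifs = motifs[ord])
  clusters
}

#' Import NLR-Annotator output as predicted loci
#'
#' Adapter for the external locus predictor: accepts its tab-separated text
#' output (sequence, start, end, strand, completeness in columns 1-5; extra
#' columns ignored) or BED, and returns loci under the same contract as
#' [cluster_motifs_to_loci()]. Coordinates in the text format are treated
#' as 1-based inclusive; BED as 0-based half-open.
#'
#' @param path Path to the external predictor's output.
#' @param format `"txt"` or `"bed"`.
#' @return A `GRanges` of predicted loci.
#' @export
read_nlr_annotator <- function(path, format = c("txt", "bed")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) return(cluster_motifs_to_loci(GenomicRanges::GRanges()))
  start <- as.integer(dt[[2L]])
  end <- as.integer(dt[[3L]])
  if (format == "bed") start <- start + 1L
  strand <- if (ncol(dt) >= 4L) dt[[4L]] else "."
  strand[!(strand %in% c("+", "-"))] <- "*"
  comp <- if (ncol(dt) >= 5L) dt[[5L]] else "partial"
  comp[!(comp %in% c("complete", "partial", "pseudogene-like"))] <- "partial"
  gr <- GenomicRanges::GRanges(dt[[1L]], IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = sprintf("locus_%04d", seq_along(gr)),
    n_hits = NA_integer_, completeness = comp,
    motifs = NA_character_)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
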