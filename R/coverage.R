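#' Coverage-caller configuration
#'
#' Parameters of the high-coverage region caller used to find loci with
#' sufficient RenSeq support. The depth floor (50x) and the flank size
#' (1 kb) mirror the published extraction criterion; the run-length floor
#' and merge gap make the manual "sufficient depth" inspection reproducible
#' and are configurable.
#'
#' @param min_depth Per-base depth threshold, strict `>=` (default 50).
#' @param min_run_length Discard called runs shorter than this many bases
#'   (default 100).
#' @param merge_gap Merge runs separated by at most this many bases
#'   (default 200).
#' @param flank Bases added on both sides when extracting regions
#'   (default 1000).
#' @return A `coverage_config` list.
#' @export
coverage_config <- function(min_depth = 50L, min_run_length = 100L,
                            merge_gap = 200L, flank = 1000L) {
  stopifnot(min_depth >= 1L, min_run_length >= 0L, merge_gap >= 0L,
            flank >= 0L)
  structure(list(min_depth = as.integer(min_depth),
                 min_run_length = as.integer(min_run_length),
                 merge_gap = as.integer(merge_gap),
                 flank = as.integer(flank)),
            class = "coverage_config")
}

#' Per-base read depth from alignment spans
#'
#' Depth at a base is the number of included alignments whose reference
#' span contains it (gap-free: the whole CIGAR reference span contributes,
#' matching what a coverage display shows). Sequences without alignments
#' get all-zero tracks.
#'
#' @param alignments A `GRanges` of alignment reference spans (see
#'   [read_alignments()]).
#' @param genome A named `DNAStringSet` (defines sequence universe and
#'   lengths).
#' @return An `RleList`, one integer run-length vector per genome sequence.
#' @export
depth_track <- function(alignments, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  sn <- as.character(GenomicRanges::seqnames(alignments))
  bad <- !(sn %in% names(lens))
  if (any(bad)) {
    stop("alignment target sequence(s) absent from genome: ",
         paste(unique(sn[bad]), collapse = ", "))
  }
  over <- GenomicRanges::end(alignments) > lens[sn] |
    GenomicRanges::start(alignments) < 1L
  if (any(over)) {
    stop(sum(over), " alignment(s) extend beyond their sequence end")
  }
  gr <- GenomicRanges::GRanges(sn, IRanges::ranges(alignments),
                               seqlengths = lens)
  GenomicRanges::coverage(gr)
}

#' Call high-coverage regions
#'
#' Maximal runs of bases with depth at or above the threshold; runs
#' separated by at most `merge_gap` bases are merged, and merged runs
#' shorter than `min_run_length` are discarded. Output is sorted with
#' strand `*`.
#'
#' @param track An `RleList` from [depth_track()].
#' @param cfg A [coverage_config()].
#' @return A `GRanges` of called regions.
#' @export
call_high_coverage_regions <- function(track, cfg = coverage_config()) {
  sliced <- IRanges::slice(track, lower = cfg$min_depth, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sliced)
  if (length(gr) > 0L) {
    gr <- GenomicRanges::reduce(gr, min.gapwidth = cfg$merge_gap + 1L)
    gr <- gr[GenomicRanges::width(gr) >= cfg$min_run_length]
  }
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::sort(gr)
}

#' Expand intervals by a flank, clip to sequence bounds, and merge
#'
#' @param regions A `GRanges`.
#' @param genome A named `DNAStringSet` giving sequence lengths.
#' @param flank Bases added on each side (default 1000).
#' @return A merged, clipped `GRanges` (strand `*`).
#' @export
add_flanks <- function(regions, genome, flank = 1000L) {
  if (length(regions) == 0L) return(GenomicRanges::granges(regions))
  lens <- setNames(Biostrings::width(genome), names(genome))
  sn <- as.character(GenomicRanges::seqnames(regions))
  if (any(!(sn %in% names(lens)))) {
    stop("unknown sequence id(s): ",
         paste(setdiff(unique(sn), names(lens)), collapse = ", "))
  }
  start <- pmax(1L, GenomicRanges::start(regions) - as.integer(flank))
  end <- pmin(unname(lens[sn]), GenomicRanges::end(regions) + as.integer(flank))
  gr <- GenomicRanges::GRanges(sn, IRanges::IRanges(start, end))
  GenomicRanges::sort(GenomicRanges::reduce(gr))
}
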