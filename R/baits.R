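# Hybridization-capture bait tiling: 80 nt probes at 3x tiling, with the
# N-replacement rule used when preparing capture targets (short N runs
# become T; long runs split the target).

#' Bait design configuration
#'
#' @param probe_length Probe length in nt (default 80).
#' @param tiling_factor Probes covering each interior base (default 3).
#' @param max_n_run_replaced N runs up to this length are replaced by Ts;
#'   longer runs split the target (default 10).
#' @return A `bait_config` list.
#' @export
bait_config <- function(probe_length = 80L, tiling_factor = 3L,
                        max_n_run_replaced = 10L) {
  stopifnot(probe_length >= 20L, tiling_factor >= 1L,
            max_n_run_replaced >= 0L)
  structure(list(probe_length = as.integer(probe_length),
                 tiling_factor = as.integer(tiling_factor),
                 max_n_run_replaced = as.integer(max_n_run_replaced)),
            class = "bait_config")
}

#' Replace short N runs and split on long ones
#'
#' Every maximal run of 1..`max_run` Ns becomes a run of Ts (sequence
#' length unchanged); runs longer than `max_run` divide the target into
#' segments.
#'
#' @param seq An uppercase nucleotide string.
#' @param max_run Longest N run still replaced (default 10).
#' @return A list with `segments` (character vector, N-free except for
#'   the T replacements) and `split_points` (0-based offsets of each
#'   removed long run's first base).
#' @export
replace_n_runs <- function(seq, max_run = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  runs <- gregexpr("N+", seq)[[1L]]
  if (runs[1L] == -1L) {
    return(list(segments = seq, split_points = integer(0L)))
  }
  starts <- as.integer(runs)
  lens <- attr(runs, "match.length")
  short <- lens <= max_run
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in which(short)) {
    chars[starts[i]:(starts[i] + lens[i] - 1L)] <- "T"
  }
  replaced <- paste(chars, collapse = "")
  long_starts <- starts[!short]
  long_ends <- starts[!short] + lens[!short] - 1L
  seg_bounds <- cbind(c(1L, long_ends + 1L),
                      c(long_starts - 1L, nchar(seq)))
  segs <- substring(replaced, seg_bounds[, 1L], seg_bounds[, 2L])
  segs <- segs[nzchar(segs)]
  list(segments = segs, split_points = long_starts - 1L)
}

#' Tile baits over capture targets
#'
#' Probes are laid on the phase-rounded grid `round(i * probe_length /
#' tiling_factor)` (0-based offsets 0, 27, 53, 80, ... for 80 nt at 3x);
#' because the grid repeats exactly every `probe_length` bases, every base
#' at least `probe_length` from both segment ends is covered by exactly
#' `tiling_factor` probes. A final end-anchored probe at
#' `length - probe_length` is added when the grid does not already end
#' there. Segments shorter than the probe are dropped and reported.
#'
#' @param targets A named `DNAStringSet` or named character vector of
#'   N-processed target segments (see [replace_n_runs()]).
#' @param cfg A [bait_config()].
#' @return A `data.frame` of probes: `target_id`, `offset` (0-based),
#'   `sequence`, `gc`; attribute `dropped` lists segments shorter than
#'   the probe length.
#' @export
tile_baits <- function(targets, cfg = bait_config()) {
  if (!is.character(targets)) targets <- as.character(targets)
  P <- cfg$probe_length
  TF <- cfg$tiling_factor
  rows <- list()
  dropped <- character(0L)
  for (id in names(targets)) {
    L <- nchar(targets[[id]])
    if (L < P) {
      dropped <- c(dropped, id)
      next
    }
    i_max <- max(0L, floor((L - P) * TF / P))
    offs <- unique(as.integer(round(seq(0L, i_max) * P / TF)))
    offs <- offs[offs <= L - P]
    if (offs[length(offs)] != L - P) offs <- c(offs, L - P)
    rows[[id]] <- data.frame(
      target_id = id, offset = offs,
      sequence = substring(targets[[id]], offs + 1L, offs + P),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    target_id = character(), offset = integer(), sequence = character(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$gc <- if (nrow(out)) gc_fraction(out$sequence) else numeric(0L)
  attr(out, "dropped") <- dropped
  out
}

gc_fraction <- function(x) {
  (nchar(gsub("[^GC]", "", x))) / nchar(x)
}

#' Summary statistics for a bait set
#'
#' @param probes Output of [tile_baits()].
#' @param targets The target segments the probes were tiled over
#'   (optional; enables total target size).
#' @return A list: `n_probes`, `total_target_size` (sum of target segment
#'   lengths, `NA` if targets not given), `mean_gc` (`NA` when there are
#'   no probes).
#' @export
bait_stats <- function(probes, targets = NULL) {
  total <- if (is.null(targets)) NA_integer_ else {
    if (!is.character(targets)) targets <- as.character(targets)
    sum(nchar(targets))
  }
  list(n_probes = nrow(probes),
       total_target_size = total,
       mean_gc = if (nrow(probes) == 0L) NA_real_ else mean(probes$gc))
}
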