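# Fixtures built in code: small synthetic configurations, random SAM
# generators with an independent CIGAR interpreter, and rejection-sampled
# motif-free sequences.

small_cfg <- function(seed = 7L, ...) {
  synth_config(
    seq_lengths = c(A01 = 150000L, C01 = 150000L),
    n_tnl = 4L, n_cnl = 2L, n_rnl = 1L, n_partial = 3L, n_cjid = 2L,
    n_fusion_pairs = 1L, on_target_depth = 80, background_depth = 2,
    seed = seed, ...)
}

random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# DNA guaranteed free of NLR motif hits in all six frames
motif_free_dna <- function(n, gc = 0.4) {
  repeat {
    s <- random_dna(n, gc)
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "bg"
    if (length(scan_motifs(six_frame_translate(g))) == 0L) return(s)
  }
}

# protein guaranteed free of consensus domain hits
motif_free_protein <- function(n) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  repeat {
    s <- paste(sample(aa20, n, replace = TRUE), collapse = "")
    h <- internal_domain_scan(stats::setNames(Biostrings::AAStringSet(s), "p"))
    if (nrow(h) == 0L) return(s)
  }
}

# random SAM over one reference with mixed CIGARs; returns the path and a
# data.frame with the expected reference span computed by a brute-force
# CIGAR walk (independent of the htslib-backed reader)
random_sam <- function(n, ref_len = 10000L, ref = "chr1") {
  ops <- c("M", "I", "D", "S")
  recs <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1L)
    op <- sample(ops, k, replace = TRUE)
    # CIGAR must contain at least one M and cannot start/end mid-read
    op[sample(k, 1L)] <- "M"
    len <- sample(1:60, k, replace = TRUE)
    cigar <- paste0(paste0(len, op), collapse = "")
    qlen <- sum(len[op %in% c("M", "I", "S")])
    rlen <- sum(len[op %in% c("M", "D")])
    pos <- sample.int(ref_len - rlen, 1L)
    list(cigar = cigar, pos = pos, qlen = qlen, rlen = rlen)
  })
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
             vapply(seq_along(recs), function(i) {
               r <- recs[[i]]
               sprintf("r%04d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       i, ref, r$pos, r$cigar,
                       strrep("A", r$qlen))
             }, character(1L)))
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  list(path = path,
       expected = data.frame(
         qname = sprintf("r%04d", seq_len(n)),
         start = vapply(recs, function(r) r$pos, numeric(1L)),
         end = vapply(recs, function(r) r$pos + r$rlen - 1L, numeric(1L))))
}

# brute-force transitive-closure clustering oracle (O(n^2))
closure_clusters <- function(df, max_gap) {
  n <- nrow(df)
  if (n == 0L) return(integer(0L))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j]) - 1L
      adj[i, j] <- df$seq[i] == df$seq[j] & df$strand[i] == df$strand[j] &
        gap <= max_gap
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0L) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}
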