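# Six-frame translation, motif scanning, and locus clustering.

test_that("six-frame translation matches seqinr on random sequences", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_dna(sample(60:200, 1L))
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "s"
    fr <- six_frame_translate(g)$s
    for (f in 1:3) {
      exp_f <- paste(seqinr::translate(strsplit(s, "")[[1L]],
                                       frame = f - 1L, sens = "F"),
                     collapse = "")
      exp_r <- paste(seqinr::translate(strsplit(s, "")[[1L]],
                                       frame = f - 1L, sens = "R"),
                     collapse = "")
      expect_identical(fr[[paste0("+", f)]]$aa, exp_f)
      expect_identical(fr[[paste0("-", f)]]$aa, exp_r)
    }
  }
})

test_that("translation handles starts, ambiguity and short frames", {
  g <- Biostrings::DNAStringSet(c(s = "ATGGCC"))
  fr <- six_frame_translate(g)$s
  expect_identical(fr[["+1"]]$aa, "MA")
  g <- Biostrings::DNAStringSet(c(s = "ATNGCC"))
  expect_identical(six_frame_translate(g)$s[["+1"]]$aa, "XA")
})

test_that("planted motifs are recovered at exact genomic coordinates", {
  set.seed(31)
  bg <- motif_free_dna(2000L)
  ploop_nt <- nlromer:::reverse_translate("GGVGKTT")
  s <- paste0(substr(bg, 1, 300), ploop_nt,
              substr(bg, 301 + nchar(ploop_nt), 2000))
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr"
  hits <- scan_motifs(six_frame_translate(g))
  hits <- hits[S4Vectors::mcols(hits)$motif_id == "ploop"]
  expect_length(hits, 1L)
  expect_equal(GenomicRanges::start(hits), 301L)
  expect_equal(as.character(GenomicRanges::strand(hits)), "+")

  # motif-free background yields nothing
  g0 <- Biostrings::DNAStringSet(bg)
  names(g0) <- "chr"
  expect_length(scan_motifs(six_frame_translate(g0)), 0L)
})

test_that("motifs planted on random frames and strands are all recovered", {
  set.seed(3)
  motifs <- nlr_motif_table()
  literals <- c(ploop = "GGVGKTT", glpl = "CGGLPLAL", mhd = "TLKVHDVLR",
                tir1 = "DVFLSFRGED", cc_edvid = "KELLEDVIDT")
  bg <- motif_free_dna(30000L)
  placed <- data.frame(motif = character(0), start = numeric(0),
                       strand = character(0))
  s <- bg
  slots <- seq(1000L, 28000L, by = 1400L)[1:20]
  for (i in seq_along(slots)) {
    m <- sample(names(literals), 1L)
    nt <- nlromer:::reverse_translate(literals[[m]])
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    }
    pos <- slots[i] + sample(0:2, 1L)  # random frame
    substr(s, pos, pos + nchar(nt) - 1L) <- nt
    placed <- rbind(placed, data.frame(motif = m, start = pos,
                                       strand = strand))
  }
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr"
  hits <- scan_motifs(six_frame_translate(g))
  got <- data.frame(motif = S4Vectors::mcols(hits)$motif_id,
                    start = GenomicRanges::start(hits),
                    strand = as.character(GenomicRanges::strand(hits)))
  got <- got[order(got$start), ]
  placed <- placed[order(placed$start), ]
  expect_equal(got$motif, placed$motif, ignore_attr = TRUE)
  expect_equal(got$start, placed$start, ignore_attr = TRUE)
  expect_equal(got$strand, placed$strand, ignore_attr = TRUE)
})

make_hits <- function(df) {
  gr <- GenomicRanges::GRanges(df$seq, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motif_id = df$motif_id, domain = df$domain, group = df$group,
    frame = df$frame, aa_start = 1L)
  gr
}

test_that("clustering matches the transitive-closure oracle", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(2:15, 1L)
    df <- data.frame(
      seq = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample.int(60000L, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      motif_id = "ploop", domain = "NBARC", group = "ploop",
      frame = 1L)
    df$end <- df$start + 20L
    loci <- cluster_motifs_to_loci(make_hits(df), max_gap = 5000L)
    comp <- closure_clusters(df, max_gap = 5000L)
    expect_length(loci, length(unique(comp)))
    # hulls agree
    exp_hulls <- do.call(rbind, lapply(split(df, comp), function(d)
      data.frame(seq = d$seq[1], start = min(d$start), end = max(d$end),
                 strand = d$strand[1])))
    exp_hulls <- exp_hulls[order(exp_hulls$seq, exp_hulls$start), ]
    expect_equal(GenomicRanges::start(loci), exp_hulls$start,
                 ignore_attr = TRUE)
    expect_equal(GenomicRanges::end(loci), exp_hulls$end,
                 ignore_attr = TRUE)
  }
})

test_that("clustering is invariant to input order and respects strand", {
  set.seed(19)
  df <- data.frame(seq = "c1",
                   start = c(1000L, 3000L, 30000L, 31000L, 31500L),
                   strand = c("+", "+", "+", "-", "+"),
                   motif_id = "ploop", domain = "NBARC", group = "ploop",
                   frame = 1L)
  df$end <- df$start + 20L
  a <- cluster_motifs_to_loci(make_hits(df))
  b <- cluster_motifs_to_loci(make_hits(df[sample(nrow(df)), ]))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # the minus-strand hit never joins the plus-strand cluster
  expect_equal(sum(as.character(GenomicRanges::strand(a)) == "-"), 1L)
})

test_that("locus completeness follows the two-sided NB-ARC rule", {
  df <- data.frame(seq = "c1", start = c(1000L, 3000L),
                   strand = "+", motif_id = c("ploop", "mhd"),
                   domain = "NBARC", group = c("ploop", "mhd"),
                   frame = c(1L, 1L))
  df$end <- df$start + 20L
  loci <- cluster_motifs_to_loci(make_hits(df))
  expect_length(loci, 1L)
  expect_identical(S4Vectors::mcols(loci)$completeness, "complete")

  # two P-loop-side hits far apart: two partial loci
  df2 <- data.frame(seq = "c1", start = c(1000L, 51000L), strand = "+",
                    motif_id = "ploop", domain = "NBARC", group = "ploop",
                    frame = 1L)
  df2$end <- df2$start + 20L
  loci2 <- cluster_motifs_to_loci(make_hits(df2))
  expect_length(loci2, 2L)
  expect_true(all(S4Vectors::mcols(loci2)$completeness == "partial"))

  # both sides present but on different frames: pseudogene-like
  df3 <- df
  df3$frame <- c(1L, 2L)
  loci3 <- cluster_motifs_to_loci(make_hits(df3))
  expect_identical(S4Vectors::mcols(loci3)$completeness, "pseudogene-like")
})

test_that("the NLR-Annotator adapter reads text and BED output", {
  txt <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t1001\t5000\t+\tcomplete",
               "chr1\t9000\t9500\t-\tpartial"), txt)
  loci <- read_nlr_annotator(txt)
  expect_length(loci, 2L)
  expect_equal(GenomicRanges::start(loci), c(1001L, 9000L))
  expect_identical(S4Vectors::mcols(loci)$completeness,
                   c("complete", "partial"))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t5000\t+\tcomplete", bed)
  lb <- read_nlr_annotator(bed, format = "bed")
  expect_equal(GenomicRanges::start(lb), 1001L)
})
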