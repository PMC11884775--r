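# Category assignment, problem-region extraction, annotation merging.

simple_models <- function(df) {
  gene_models(GenomicRanges::GRanges(
    df$seq, IRanges::IRanges(df$start, df$end), strand = df$strand,
    gene_id = df$gene_id, transcript_id = paste0(df$gene_id, ".t1"),
    phase = 0L))
}

simple_loci <- function(df) {
  gr <- GenomicRanges::GRanges(df$seq, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = sprintf("locus_%04d", seq_along(gr)),
    n_hits = 5L, completeness = "complete", motifs = "")
  gr
}

full_cov <- function(seq = "chr1", end = 100000L) {
  GenomicRanges::GRanges(seq, IRanges::IRanges(1, end))
}

test_that("loci are assigned missing / ok / misannotated / fused", {
  loci <- simple_loci(data.frame(seq = "chr1", start = 5001L, end = 7000L,
                                 strand = "+"))
  rec <- overlap_classify(empty_gene_models(), loci, full_cov())
  expect_identical(rec$category, "missing")
  expect_true(rec$coverage_support)

  genes <- simple_models(data.frame(seq = "chr1", start = 5001L, end = 6900L,
                                    strand = "+", gene_id = "g1"))
  rec <- overlap_classify(genes, loci, full_cov())
  expect_identical(rec$category, "ok")   # 95% of the locus covered
  expect_identical(rec$genes, "g1")

  genes2 <- simple_models(data.frame(seq = "chr1", start = 5001L,
                                     end = 5800L, strand = "+",
                                     gene_id = "g1"))
  rec2 <- overlap_classify(genes2, loci, full_cov())
  expect_identical(rec2$category, "misannotated")  # 40% coverage

  # one gene spanning two complete loci -> both fused
  loci2 <- simple_loci(data.frame(seq = "chr1",
                                  start = c(5001L, 9001L),
                                  end = c(7000L, 11000L), strand = "+"))
  gene_span <- simple_models(data.frame(seq = "chr1", start = 5001L,
                                        end = 11000L, strand = "+",
                                        gene_id = "gBig"))
  rec3 <- overlap_classify(gene_span, loci2, full_cov())
  expect_identical(rec3$category, c("fused", "fused"))
})

test_that("coverage support uses the configured base fraction", {
  loci <- simple_loci(data.frame(seq = "chr1", start = 1001L, end = 2000L,
                                 strand = "+"))
  hicov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
  rec <- overlap_classify(empty_gene_models(), loci, hicov)
  expect_false(rec$coverage_support)    # 40% < 50%
  hicov2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1600))
  expect_true(overlap_classify(empty_gene_models(), loci,
                               hicov2)$coverage_support)
})

test_that("problem regions are flanked, merged, and sliced exactly", {
  set.seed(8)
  g <- Biostrings::DNAStringSet(random_dna(20000L))
  names(g) <- "chr1"
  loci <- simple_loci(data.frame(seq = "chr1", start = 5001L, end = 7000L,
                                 strand = "+"))
  rec <- overlap_classify(empty_gene_models(), loci, full_cov(end = 20000L))
  out <- extract_problem_regions(rec, g, flank = 1000L)
  expect_length(out$regions, 1L)
  expect_equal(GenomicRanges::start(out$regions), 4001L)
  expect_equal(GenomicRanges::end(out$regions), 8000L)
  expect_identical(names(out$sequences), "chr1:4001-8000")
  expect_identical(as.character(out$sequences[[1L]]),
                   substr(as.character(g[[1L]]), 4001L, 8000L))

  # all-ok input -> nothing to extract
  rec$category <- "ok"
  expect_length(extract_problem_regions(rec, g)$regions, 0L)

  # adjacent flanked loci merge into one region whose sequence equals the
  # direct genome slice
  loci2 <- simple_loci(data.frame(seq = "chr1",
                                  start = c(5001L, 8501L),
                                  end = c(7000L, 9500L), strand = "+"))
  rec2 <- overlap_classify(empty_gene_models(), loci2,
                           full_cov(end = 20000L))
  out2 <- extract_problem_regions(rec2, g, flank = 1000L)
  expect_length(out2$regions, 1L)
  expect_identical(as.character(out2$sequences[[1L]]),
                   substr(as.character(g[[1L]]), 4001L, 10500L))
})

test_that("merging keeps non-NLR genes and dedups novel models", {
  orig <- simple_models(data.frame(
    seq = "chr1", start = c(1001L, 20001L, 40001L),
    end = c(2000L, 21000L, 41000L), strand = "+",
    gene_id = c("nlr_ok", "nlr_bad", "housekeeping")))
  novel <- simple_models(data.frame(seq = "chr1", start = 20001L,
                                    end = 21200L, strand = "+",
                                    gene_id = "novel_1"))
  merged <- merge_annotations(orig, nlr_gene_ids = c("nlr_ok", "nlr_bad"),
                              keep_gene_ids = "nlr_ok", novel = novel)
  tx <- tx_table(merged)
  expect_setequal(tx$gene_id, c("nlr_ok", "housekeeping", "novel_1"))

  # no novel models: refined NLR set equals the kept set
  merged0 <- merge_annotations(orig, c("nlr_ok", "nlr_bad"), "nlr_ok",
                               empty_gene_models())
  expect_setequal(tx_table(merged0)$gene_id, c("nlr_ok", "housekeeping"))

  # a novel model duplicating a kept model's CDS is rejected and logged
  dup <- simple_models(data.frame(seq = "chr1", start = 1001L, end = 2000L,
                                  strand = "+", gene_id = "novel_dup"))
  merged2 <- merge_annotations(orig, c("nlr_ok", "nlr_bad"), "nlr_ok", dup)
  expect_false("novel_dup" %in% tx_table(merged2)$gene_id)
  expect_identical(attr(merged2, "conflicts"), "novel_dup.t1")

  # id collision is an error
  clash <- simple_models(data.frame(seq = "chr1", start = 60001L,
                                    end = 61000L, strand = "+",
                                    gene_id = "nlr_ok"))
  expect_error(merge_annotations(orig, "nlr_bad", character(0), clash),
               "collide|collision")
})

test_that("region-local models lift back to genome coordinates", {
  local <- simple_models(data.frame(seq = "chr1:4001-8000", start = 501L,
                                    end = 1400L, strand = "-",
                                    gene_id = "r1_g1"))
  lifted <- lift_models(local)
  tx <- tx_table(lifted)
  expect_identical(tx$seqnames, "chr1")
  expect_equal(tx$start, 4501L)  # local base 1 maps to genome base 4001
  expect_equal(tx$end, 5400L)
  expect_identical(tx$strand, "-")
})
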