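# The seeded synthetic study generator.

test_that("the generated genome hits the configured GC and is reproducible", {
  cfg <- small_cfg(seed = 42L)
  gen <- generate_genome(cfg)
  gc <- sum(Biostrings::letterFrequency(gen$genome, "GC")) /
    sum(Biostrings::width(gen$genome))
  expect_lt(abs(gc - 0.376), 0.01)

  gen2 <- generate_genome(cfg)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))
  expect_identical(gen$manifest, gen2$manifest)

  # zero planted genes -> pure background, empty annotation
  cfg0 <- synth_config(seq_lengths = c(A01 = 50000L), n_tnl = 0L,
                       n_cnl = 0L, n_rnl = 0L, n_partial = 0L,
                       n_cjid = 0L, n_fusion_pairs = 0L, seed = 1L)
  gen0 <- generate_genome(cfg0)
  expect_identical(nrow(gen0$manifest), 0L)
  expect_identical(nrow(tx_table(gen0$annotation)), 0L)
})

test_that("planted genes have consistent manifest entries", {
  gen <- generate_genome(small_cfg(seed = 5L))
  man <- gen$manifest
  # CDS length divisible by 3, starts with ATG, ends with a stop
  for (i in seq_len(nrow(man))) {
    s <- Biostrings::subseq(gen$genome[[man$seqid[i]]], man$start[i],
                            man$end[i])
    if (man$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    s <- as.character(s)
    expect_equal(nchar(s) %% 3L, 0L)
    expect_identical(substr(s, 1L, 3L), "ATG")
    expect_true(substr(s, nchar(s) - 2L, nchar(s)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  # fusion partners are adjacent (< 2 kb apart) on the same sequence
  paired <- man[!is.na(man$partner), ]
  for (i in seq_len(nrow(paired))) {
    j <- match(paired$partner[i], man$gene_id)
    expect_identical(paired$seqid[i], man$seqid[j])
    gap <- max(man$start[j], paired$start[i]) -
      min(man$end[j], paired$end[i])
    expect_lt(gap, 2000L)
  }
})

test_that("every planted gene is detected as exactly one predicted locus", {
  gen <- generate_genome(small_cfg(seed = 42L))
  loci <- cluster_motifs_to_loci(scan_motifs(six_frame_translate(gen$genome)))
  truth <- GenomicRanges::GRanges(gen$manifest$seqid,
                                  IRanges::IRanges(gen$manifest$start,
                                                   gen$manifest$end))
  ov <- GenomicRanges::countOverlaps(truth, loci, ignore.strand = TRUE)
  expect_true(all(ov == 1L))
  expect_equal(length(loci), nrow(gen$manifest))
  bg <- GenomicRanges::countOverlaps(loci, truth, ignore.strand = TRUE)
  expect_true(all(bg >= 1L))   # no loci in background
})

test_that("corruption follows its documented RNG contract", {
  cfg <- small_cfg(seed = 11L)
  gen <- generate_genome(cfg)
  corr <- corrupt_annotation(gen$annotation, gen$manifest, cfg)
  # independent re-draw of the category stream
  set.seed(cfg$seed + 1L)
  u <- runif(nrow(gen$manifest))
  drawn <- ifelse(u < cfg$p_miss, "missing",
                  ifelse(u < cfg$p_miss + cfg$p_trunc, "truncated",
                         ifelse(u < cfg$p_miss + cfg$p_trunc + cfg$p_fuse,
                                "fused", "none")))
  # apply the same fusion-fallback rule
  man <- gen$manifest
  expected <- drawn
  for (i in seq_along(drawn)) {
    if (drawn[i] != "fused") next
    p <- match(man$partner[i], man$gene_id)
    if (!is.na(p) && drawn[p] %in% c("none", "fused")) {
      expected[i] <- "fused"; expected[p] <- "fused"
    } else expected[i] <- "truncated"
  }
  expect_identical(corr$log$action, expected)

  # all rates zero: annotation passes through identical
  cfg0 <- small_cfg(seed = 11L)
  cfg0$p_miss <- 0; cfg0$p_trunc <- 0; cfg0$p_fuse <- 0
  corr0 <- corrupt_annotation(gen$annotation, gen$manifest, cfg0)
  expect_identical(tx_table(corr0$annotation), tx_table(gen$annotation))
  expect_true(all(corr0$log$action == "none"))

  # certain loss: everything missing, and logged as such
  cfg1 <- small_cfg(seed = 11L)
  cfg1$p_miss <- 1; cfg1$p_trunc <- 0; cfg1$p_fuse <- 0
  corr1 <- corrupt_annotation(gen$annotation, gen$manifest, cfg1)
  expect_identical(nrow(tx_table(corr1$annotation)), 0L)
  expect_true(all(corr1$log$action == "missing"))
})

test_that("truncation keeps a codon-aligned 30-60% prefix", {
  cfg <- small_cfg(seed = 19L)
  gen <- generate_genome(cfg)
  corr <- corrupt_annotation(gen$annotation, gen$manifest, cfg)
  tr_ids <- corr$log$gene_id[corr$log$action == "truncated"]
  expect_gt(length(tr_ids), 0L)   # deterministic for this seed
  full_tx <- tx_table(gen$annotation)
  cor_tx <- tx_table(corr$annotation)
  for (g in tr_ids) {
    a <- full_tx[full_tx$gene_id == g, ]
    b <- cor_tx[cor_tx$gene_id == g, ]
    frac <- b$cds_len / a$cds_len
    expect_true(frac >= 0.29 && frac <= 0.61)
    expect_equal(b$cds_len %% 3L, 0L)
    if (a$strand == "+") expect_equal(a$start, b$start)
    else expect_equal(a$end, b$end)
  }
})

test_that("simulated reads give on-target and background depth as configured", {
  cfg <- small_cfg(seed = 7L)
  gen <- generate_genome(cfg)
  sim <- simulate_reads(gen$genome, gen$manifest, cfg,
                        out_dir = tempfile("reads_"))
  # every read is the configured length
  fq <- readLines(sim$fastq1)
  reads <- fq[seq(2L, length(fq), by = 4L)]
  expect_true(all(nchar(reads) == cfg$read_length))

  aln <- read_alignments(sim$sam)
  track <- depth_track(aln, gen$genome)
  man <- gen$manifest
  cds_depth <- unlist(lapply(seq_len(nrow(man)), function(i)
    as.numeric(track[[man$seqid[i]]][man$start[i]:man$end[i]])))
  expect_lt(abs(mean(cds_depth) - cfg$on_target_depth),
            0.1 * cfg$on_target_depth)
  # background: bases > 2 kb away from any planted gene
  bg_mask <- rep(TRUE, 30000L)
  near <- man[man$seqid == "A01", ]
  bg <- as.numeric(track[["A01"]][1:30000])
  for (i in seq_len(nrow(near))) {
    lo <- max(1L, near$start[i] - 2000L)
    hi <- min(30000L, near$end[i] + 2000L)
    if (lo <= 30000L) bg_mask[lo:hi] <- FALSE
  }
  expect_lt(abs(mean(bg[bg_mask]) - cfg$background_depth),
            0.5 * cfg$background_depth)

  # zero depth -> zero reads
  cfg0 <- small_cfg(seed = 7L)
  cfg0$on_target_depth <- 0; cfg0$background_depth <- 0
  sim0 <- simulate_reads(gen$genome, gen$manifest, cfg0,
                         out_dir = tempfile("reads0_"))
  expect_equal(sim0$n_fragments, 0L)

  # same seed -> byte-identical FASTQ and SAM
  sim2 <- simulate_reads(gen$genome, gen$manifest, cfg,
                         out_dir = tempfile("reads2_"))
  expect_identical(readLines(sim$fastq1), readLines(sim2$fastq1))
  expect_identical(readLines(sim$fastq2), readLines(sim2$fastq2))
  expect_identical(readLines(sim$sam), readLines(sim2$sam))
})
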