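# Fully seeded synthetic study generator: a ~2 Mb genome with planted NLR
# genes of known architecture, a deliberately corrupted annotation
# (missing / truncated / fused models), and enrichment-style paired reads
# with a truth SAM -- so every pipeline stage is testable without external
# data or tools. Draw order is documented per stage: genome and placement
# use `seed`, corruption `seed + 1`, reads `seed + 2`.

#' Synthetic study configuration
#'
#' Defaults emulate the study conditions of a RenSeq NLRome refinement:
#' a 2 Mb genome over four named sequences at 37.6% GC, 40 planted NLR
#' genes (20 TNL / 8 CNL / 4 RNL / 8 partial, some carrying C-JID or
#' integrated domains), corruption rates 0.3 / 0.2 / 0.1 for
#' missing / truncated / fused models, and 150 bp paired reads at ~100x
#' on-target and ~2x background depth with 0.1% substitution errors.
#'
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param gc Background GC fraction.
#' @param n_tnl,n_cnl,n_rnl Counts of full planted NLRs per class.
#' @param n_partial Count of partial planted NLRs (TIR-only / TIR+NB-ARC /
#'   NB-ARC+LRR mix).
#' @param n_cjid How many TNLs also carry a C-JID cassette.
#' @param p_miss,p_trunc,p_fuse Per-gene corruption probabilities.
#' @param n_fusion_pairs Designated adjacent gene pairs available for
#'   fusion corruption.
#' @param read_length,insert_mean,insert_sd Read geometry (nt).
#' @param on_target_depth,background_depth Expected per-base read depth
#'   inside planted-gene neighborhoods (+/- 500 bp) and elsewhere.
#' @param error_rate Per-base substitution error rate in reads.
#' @param seed Integer seed; every draw derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seq_lengths = c(A01 = 600000L, A09 = 500000L,
                                         C09 = 500000L,
                                         scaffold00001 = 400000L),
                         gc = 0.376,
                         n_tnl = 20L, n_cnl = 8L, n_rnl = 4L,
                         n_partial = 8L, n_cjid = 8L,
                         p_miss = 0.3, p_trunc = 0.2, p_fuse = 0.1,
                         n_fusion_pairs = 4L,
                         read_length = 150L, insert_mean = 350L,
                         insert_sd = 50L,
                         on_target_depth = 100, background_depth = 2,
                         error_rate = 0.001, seed = 42L) {
  stopifnot(p_miss >= 0, p_trunc >= 0, p_fuse >= 0,
            p_miss + p_trunc + p_fuse <= 1,
            on_target_depth >= 0, background_depth >= 0,
            insert_mean >= 2L * read_length)
  structure(as.list(environment()), class = "synth_config")
}

# one AT-leaning, stop-free codon per amino acid: reverse translation is
# deterministic so planted nucleotide cassettes are constants
aa_codon_map <- c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGA", H = "CAT", I = "ATT", L = "TTA", K = "AAA",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACA", W = "TGG",
  Y = "TAT", V = "GTT")

reverse_translate <- function(aa) {
  paste(aa_codon_map[strsplit(aa, "", fixed = TRUE)[[1L]]], collapse = "")
}

AA20 <- names(aa_codon_map)

# architecture blueprints for the planted cohort
synth_gene_specs <- function(cfg) {
  specs <- list()
  add <- function(label, cassettes, integrated = character(0L)) {
    specs[[length(specs) + 1L]] <<- list(label = label,
                                         cassettes = cassettes,
                                         integrated = integrated)
  }
  for (i in seq_len(cfg$n_tnl)) {
    cass <- c("TIR", "NBARC", "LRR")
    integ <- character(0L)
    if (i <= cfg$n_cjid) cass <- c(cass, "CJID")
    if (i == 1L) integ <- rep("Gal_oxidase", 3L)
    if (i == 2L) integ <- "Pkinase"
    if (i == 3L) integ <- "B3"
    add("TNL", cass, integ)
  }
  for (i in seq_len(cfg$n_cnl)) {
    add("CNL", c("CC", "NBARC", "LRR"), if (i == 1L) "HMA" else character(0L))
  }
  for (i in seq_len(cfg$n_rnl)) add("RNL", c("RPW8", "NBARC", "LRR"))
  part_archs <- rep(list(c("TIR"), c("TIR", "NBARC"), c("NBARC", "LRR")),
                    length.out = cfg$n_partial)
  for (a in part_archs) add(paste(a, collapse = "+"), a)
  specs
}

# build a planted protein: M + pad + cassettes with random linkers +
# C-terminal filler; rejected and redrawn until the internal scanner
# recovers exactly the intended architecture
synth_protein <- function(cassettes, integrated, min_len = 130L) {
  blocks <- nlr_cassettes()
  # integrated domains sit between NB-ARC and LRR (or at the C terminus)
  ins_at <- if ("LRR" %in% cassettes) which(cassettes == "LRR")[1L] else
    length(cassettes) + 1L
  ordered <- append(cassettes, integrated, after = ins_at - 1L)
  # single-domain partials (e.g. TIR-only) carry two copies of their
  # cassette with the length filler in between, so the motif region spans
  # most of the coding sequence, as the single large domain does in real
  # such proteins
  single <- length(ordered) == 1L
  expected_cats <- unique(c(
    cassettes[cassettes %in% c("TIR", "CC", "RPW8", "NBARC", "LRR", "CJID")],
    if (length(integrated)) "OTHER"))
  for (attempt in 1:50) {
    if (single) {
      blk <- blocks[[ordered]]
      midlen <- max(8L, min_len - 2L * nchar(blk) - 17L)
      mid <- paste(sample(AA20, midlen, replace = TRUE), collapse = "")
      aa <- paste0("M",
                   paste(sample(AA20, 8L, replace = TRUE), collapse = ""),
                   blk, mid, blk,
                   paste(sample(AA20, 8L, replace = TRUE), collapse = ""))
    } else {
      linkers <- vapply(seq_len(length(ordered) + 1L), function(i)
        paste(sample(AA20, 8L, replace = TRUE), collapse = ""), character(1L))
      body <- paste0(linkers[1L],
                     paste0(blocks[ordered], linkers[-1L], collapse = ""))
      aa <- paste0("M", body)
      if (nchar(aa) < min_len) {
        aa <- paste0(aa, paste(sample(AA20, min_len - nchar(aa),
                                      replace = TRUE), collapse = ""))
      }
    }
    hits <- internal_domain_scan(setNames(Biostrings::AAStringSet(aa), "p"))
    hits <- assign_categories(hits)
    cats <- unique(hits$category)
    oth <- hits$accession[hits$category == "OTHER"]
    ok <- setequal(cats, expected_cats) &&
      identical(sort(oth), sort(integrated))
    if (ok) return(aa)
  }
  stop("failed to assemble a clean synthetic protein; widen motif spacing")
}

#' Generate a synthetic genome with planted NLR genes
#'
#' Draws background sequence at the configured GC, plants intronless
#' ATG..stop NLR genes built from fixed cassette blocks (each preceded by
#' an in-frame stop so the gene is a maximal ORF), keeps designated
#' fusion pairs adjacent (< 2 kb apart) and all other genes >= 5 kb
#' apart, and returns the genome, the true annotation, and a truth
#' manifest.
#'
#' @param cfg A [synth_config()].
#' @return A list: `genome` (`DNAStringSet`), `annotation`
#'   ([gene_models], the truth), `manifest` (`data.frame`: `gene_id`,
#'   `transcript_id`, `seqid`, `start`, `end`, `strand`, `architecture`,
#'   `integrated`, `partner`, `protein`).
#' @export
generate_genome <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  p_gc <- cfg$gc / 2
  p_at <- (1 - cfg$gc) / 2
  seqs <- lapply(cfg$seq_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(p_at, p_gc, p_gc, p_at)), collapse = ""))
  specs <- synth_gene_specs(cfg)
  n <- length(specs)
  if (n == 0L) {
    return(list(genome = setNames(Biostrings::DNAStringSet(unlist(seqs)),
                                  names(cfg$seq_lengths)),
                annotation = empty_gene_models(),
                manifest = synth_empty_manifest()))
  }
  proteins <- vapply(specs, function(sp)
    synth_protein(sp$cassettes, sp$integrated), character(1L))
  cds <- vapply(proteins, function(p)
    paste0(reverse_translate(p), "TAA"), character(1L))

  # placement: designated fusion pairs first (adjacent), then singles
  ord <- sample.int(n)
  pair_of <- rep(NA_integer_, n)
  np <- min(cfg$n_fusion_pairs, n %/% 2L)
  if (np > 0L) {
    for (k in seq_len(np)) {
      a <- ord[2L * k - 1L]; b <- ord[2L * k]
      pair_of[a] <- b; pair_of[b] <- a
    }
  }
  margin <- 2500L
  # singles sit farther apart than the default locus-clustering gap so
  # every planted gene yields exactly one predicted locus
  min_sep <- 12000L
  occupied <- lapply(cfg$seq_lengths, function(L) NULL)
  place <- function(width) {
    for (try in 1:2000) {
      si <- sample(length(cfg$seq_lengths), 1L,
                   prob = as.numeric(cfg$seq_lengths))
      L <- cfg$seq_lengths[[si]]
      if (L < width + 2L * margin) next
      s <- sample.int(L - width - 2L * margin, 1L) + margin
      occ <- occupied[[si]]
      if (!is.null(occ) &&
          any(s <= occ[, 2L] + min_sep & s + width - 1L >= occ[, 1L] - min_sep))
        next
      occupied[[si]] <<- rbind(occ, c(s, s + width - 1L))
      return(list(seq = si, start = s))
    }
    stop("genome too small for the requested gene count")
  }
  res <- data.frame(gene_id = sprintf("NLR_gene_%03d", seq_len(n)),
                    transcript_id = sprintf("NLR_gene_%03d.t1", seq_len(n)),
                    seqid = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    architecture = vapply(specs, function(sp)
                      paste(sp$cassettes, collapse = "+"), character(1L)),
                    integrated = vapply(specs, function(sp) {
                      if (length(sp$integrated) == 0L) return("")
                      tb <- table(sp$integrated)
                      paste(sprintf("%s:%d", names(tb), as.integer(tb)),
                            collapse = ",")
                    }, character(1L)),
                    partner = NA_character_,
                    protein = proteins,
                    stringsAsFactors = FALSE)
  placed <- rep(FALSE, n)
  for (i in ord) {
    if (placed[i]) next
    j <- pair_of[i]
    if (!is.na(j)) {
      gap <- sample(400:1200, 1L)
      len_i <- nchar(cds[i]) + 3L
      len_j <- nchar(cds[j]) + 3L
      pos <- place(len_i + gap + len_j)
      starts <- c(pos$start, pos$start + len_i + gap)
      # head-to-head pair (opposite strands), the common layout of paired
      # plant NLRs; keeps the two loci distinct under same-strand
      # clustering while an erroneous fusion model still spans both
      strands <- sample(c("+", "-"))
      for (k in seq_along(c(i, j))) {
        g <- c(i, j)[k]
        strand <- strands[k]
        block <- paste0("TAA", cds[g])
        if (strand == "-") {
          block <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(block)))
        }
        b <- starts[k]
        lenb <- nchar(block)
        substr(seqs[[pos$seq]], b, b + lenb - 1L) <- block
        cstart <- if (strand == "+") b + 3L else b
        res$seqid[g] <- names(cfg$seq_lengths)[pos$seq]
        res$start[g] <- cstart
        res$end[g] <- cstart + nchar(cds[g]) - 1L
        res$strand[g] <- strand
        placed[g] <- TRUE
      }
      res$partner[i] <- res$gene_id[j]
      res$partner[j] <- res$gene_id[i]
    } else {
      lenb <- nchar(cds[i]) + 3L
      pos <- place(lenb)
      strand <- sample(c("+", "-"), 1L)
      block <- paste0("TAA", cds[i])
      if (strand == "-") {
        block <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(block)))
      }
      b <- pos$start
      substr(seqs[[pos$seq]], b, b + lenb - 1L) <- block
      cstart <- if (strand == "+") b + 3L else b
      res$seqid[i] <- names(cfg$seq_lengths)[pos$seq]
      res$start[i] <- cstart
      res$end[i] <- cstart + nchar(cds[i]) - 1L
      res$strand[i] <- strand
      placed[i] <- TRUE
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(cfg$seq_lengths)
  gr <- GenomicRanges::GRanges(res$seqid,
                               IRanges::IRanges(res$start, res$end),
                               strand = res$strand,
                               gene_id = res$gene_id,
                               transcript_id = res$transcript_id,
                               phase = 0L)
  list(genome = genome, annotation = gene_models(gr), manifest = res)
}

synth_empty_manifest <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             seqid = character(), start = integer(), end = integer(),
             strand = character(), architecture = character(),
             integrated = character(), partner = character(),
             protein = character(), stringsAsFactors = FALSE)
}

#' Corrupt a truth annotation
#'
#' Independently assigns each planted gene `missing` (model removed),
#' `truncated` (CDS cut to a random 30-60% prefix, codon-aligned),
#' `fused` (the gene and its designated adjacent partner replaced by one
#' spanning model) or `none`, with the configured rates. A fusion draw
#' without a usable adjacent partner falls back to truncation and is
#' logged. RNG contract: with seed `cfg$seed + 1`, the first
#' `nrow(manifest)` uniform draws are the per-gene category draws, in
#' manifest order; subsequent draws are truncation fractions in gene
#' order.
#'
#' @param truth A [gene_models] object (the true annotation).
#' @param manifest The truth manifest from [generate_genome()].
#' @param cfg A [synth_config()].
#' @return A list: `annotation` (corrupted [gene_models]), `log`
#'   (`data.frame` with `gene_id`, `action`, `detail`).
#' @export
corrupt_annotation <- function(truth, manifest, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(manifest)
  u <- if (n > 0L) runif(n) else numeric(0L)
  drawn <- ifelse(u < cfg$p_miss, "missing",
                  ifelse(u < cfg$p_miss + cfg$p_trunc, "truncated",
                         ifelse(u < cfg$p_miss + cfg$p_trunc + cfg$p_fuse,
                                "fused", "none")))
  action <- drawn
  detail <- rep("", n)
  # resolve fusion draws: need a partner whose own draw keeps it present
  for (i in seq_len(n)) {
    if (drawn[i] != "fused") next
    p <- match(manifest$partner[i], manifest$gene_id)
    ok <- !is.na(p) && drawn[p] %in% c("none", "fused")
    if (ok) {
      action[i] <- "fused"
      action[p] <- "fused"
      detail[i] <- paste0("with:", manifest$gene_id[p])
      if (!nzchar(detail[p])) detail[p] <- paste0("with:", manifest$gene_id[i])
    } else {
      action[i] <- "truncated"
      detail[i] <- "fallback_from_fused"
    }
  }
  tcds <- cds_of(truth)
  rows <- list()
  fused_done <- character(0L)
  for (i in seq_len(n)) {
    gid <- manifest$gene_id[i]
    part <- tcds[S4Vectors::mcols(tcds)$gene_id == gid]
    if (action[i] == "missing") {
      detail[i] <- "removed"
      next
    }
    if (action[i] == "none") {
      rows[[length(rows) + 1L]] <- part
      next
    }
    if (action[i] == "truncated") {
      frac <- runif(1L, 0.3, 0.6)
      len <- sum(GenomicRanges::width(part))
      keep <- max(3L, 3L * floor(len * frac / 3L))
      strand <- as.character(GenomicRanges::strand(part))[1L]
      if (strand == "-") {
        GenomicRanges::start(part) <- GenomicRanges::end(part) - keep + 1L
      } else {
        GenomicRanges::end(part) <- GenomicRanges::start(part) + keep - 1L
      }
      detail[i] <- sprintf("%s;kept=%d/%d", detail[i], keep, len)
      rows[[length(rows) + 1L]] <- part
      next
    }
    # fused: emit one spanning model per pair, once
    if (gid %in% fused_done) next
    pgid <- manifest$partner[i]
    p <- match(pgid, manifest$gene_id)
    ppart <- tcds[S4Vectors::mcols(tcds)$gene_id == pgid]
    both <- c(part, ppart)
    fid <- paste0("fused_", gid, "_", pgid)
    S4Vectors::mcols(both)$gene_id <- fid
    S4Vectors::mcols(both)$transcript_id <- paste0(fid, ".t1")
    GenomicRanges::strand(both) <- as.character(GenomicRanges::strand(part))[1L]
    rows[[length(rows) + 1L]] <- both
    fused_done <- c(fused_done, gid, pgid)
  }
  ann <- if (length(rows) == 0L) empty_gene_models() else
    gene_models(do.call(c, rows))
  list(annotation = ann,
       log = data.frame(gene_id = manifest$gene_id, action = action,
                        detail = detail, stringsAsFactors = FALSE))
}

#' Simulate enrichment-style paired reads with a truth SAM
#'
#' Fragments are drawn uniformly within planted-gene neighborhoods
#' (+/- 500 bp) at `on_target_depth` and genome-wide at
#' `background_depth`; insert lengths are normal (truncated at twice the
#' read length), substitution errors are injected into the FASTQ reads,
#' and the truth SAM records each read's error-free origin so coverage
#' can be computed without an aligner.
#'
#' @param genome A named `DNAStringSet`.
#' @param manifest Truth manifest (defines on-target neighborhoods; an
#'   empty manifest means background only).
#' @param cfg A [synth_config()].
#' @param out_dir Directory for `reads_R1.fastq`, `reads_R2.fastq`,
#'   `truth.sam`.
#' @return A list of paths (`fastq1`, `fastq2`, `sam`) plus
#'   `n_fragments`.
#' @export
simulate_reads <- function(genome, manifest, cfg, out_dir = tempdir()) {
  set.seed(cfg$seed + 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rl <- cfg$read_length
  lens <- setNames(Biostrings::width(genome), names(genome))
  windows <- list()
  if (nrow(manifest) > 0L && cfg$on_target_depth > cfg$background_depth) {
    tg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      manifest$seqid,
      IRanges::IRanges(pmax(1L, manifest$start - 500L),
                       pmin(unname(lens[manifest$seqid]),
                            manifest$end + 500L))))
    windows <- c(windows, lapply(seq_along(tg), function(j) list(
      seq = as.character(GenomicRanges::seqnames(tg))[j],
      start = GenomicRanges::start(tg)[j], end = GenomicRanges::end(tg)[j],
      depth = cfg$on_target_depth - cfg$background_depth)))
  }
  if (cfg$background_depth > 0) {
    windows <- c(windows, lapply(names(lens), function(sn) list(
      seq = sn, start = 1L, end = unname(lens[[sn]]),
      depth = cfg$background_depth)))
  }
  frag <- list()
  for (w in windows) {
    width <- w$end - w$start + 1L
    nf <- round(w$depth * (width + cfg$insert_mean) / (2 * rl))
    if (nf < 1L) next
    ins <- pmax(2L * rl, as.integer(round(rnorm(nf, cfg$insert_mean,
                                                cfg$insert_sd))))
    st <- w$start - ins + floor(runif(nf) * (width + ins))
    keep <- st >= 1L & st + ins - 1L <= lens[[w$seq]]
    if (!any(keep)) next
    frag[[length(frag) + 1L]] <- data.frame(seq = w$seq, start = st[keep],
                                            insert = ins[keep],
                                            stringsAsFactors = FALSE)
  }
  fr <- if (length(frag)) do.call(rbind, frag) else
    data.frame(seq = character(), start = integer(), insert = integer())
  paths <- list(fastq1 = file.path(out_dir, "reads_R1.fastq"),
                fastq2 = file.path(out_dir, "reads_R2.fastq"),
                sam = file.path(out_dir, "truth.sam"),
                n_fragments = nrow(fr))
  nf <- nrow(fr)
  if (nf == 0L) {
    file.create(paths$fastq1, paths$fastq2)
    write_sam(data.frame(qname = character(), flag = integer(),
                         rname = character(), pos = integer(),
                         mapq = integer(), cigar = character(),
                         rnext = character(), pnext = integer(),
                         tlen = integer(), seq = character(),
                         qual = character()), lens, paths$sam)
    return(paths)
  }
  fr$name <- sprintf("frag%07d", seq_len(nf))
  gch <- lapply(as.list(as.character(genome)), identity)
  r1 <- character(nf); r2fwd <- character(nf)
  for (sn in unique(fr$seq)) {
    idx <- which(fr$seq == sn)
    s <- gch[[sn]]
    r1[idx] <- substring(s, fr$start[idx], fr$start[idx] + rl - 1L)
    r2fwd[idx] <- substring(s, fr$start[idx] + fr$insert[idx] - rl,
                            fr$start[idx] + fr$insert[idx] - 1L)
  }
  inject_errors <- function(reads, rate) {
    nerr <- rbinom(length(reads), rl, rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(rl, nerr[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      reads[i] <- paste(ch, collapse = "")
    }
    reads
  }
  fq1 <- inject_errors(r1, cfg$error_rate)
  fq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(inject_errors(r2fwd, cfg$error_rate))))
  qual <- strrep("I", rl)
  writeLines(paste0("@", fr$name, "/1\n", fq1, "\n+\n", qual), paths$fastq1)
  writeLines(paste0("@", fr$name, "/2\n", fq2, "\n+\n", qual), paths$fastq2)
  pos2 <- fr$start + fr$insert - rl
  cigar <- paste0(rl, "M")
  rec <- data.frame(
    qname = c(fr$name, fr$name),
    flag = c(rep(99L, nf), rep(147L, nf)),
    rname = c(fr$seq, fr$seq),
    pos = c(fr$start, pos2),
    mapq = 60L,
    cigar = cigar,
    rnext = "=",
    pnext = c(pos2, fr$start),
    tlen = c(fr$insert, -fr$insert),
    seq = c(r1, r2fwd),
    qual = qual,
    stringsAsFactors = FALSE)
  ord <- order(rec$rname, rec$pos)
  write_sam(rec[ord, , drop = FALSE], lens, paths$sam)
  paths
}
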