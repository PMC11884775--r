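# Cohort-level NLRome summaries: totals, class counts and per-chromosome
# distribution, with sequences not matching the chromosome-name pattern
# pooled into a "scaffolds" bucket.

#' Summarize an NLRome classification
#'
#' @param calls Architecture table (see [classify_architecture()]).
#' @param models Optional [gene_models] object mapping each protein
#'   (transcript id) to a chromosome.
#' @param seqids Alternative to `models`: named character vector
#'   protein_id -> sequence name.
#' @param chromosome_pattern Regular expression for real chromosome
#'   names; everything else is pooled as `scaffolds`. The default matches
#'   the A01..C09 style of *Brassica napus*.
#' @return An `nlrome_summary` list: `total`, `full`, `partial`,
#'   `class_counts` (TNL/CNL/RNL), `tir_only`, `cjid`, `nlr_id`,
#'   `nlr_id_types`, `id_prevalence` (named vector: proteins carrying
#'   each integrated domain), `per_chromosome` (named vector of NLR
#'   counts incl. `scaffolds`), `per_chromosome_class` (matrix
#'   chromosome x class).
#' @export
summarize_nlrome <- function(calls, models = NULL, seqids = NULL,
                             chromosome_pattern = "^[AC][0-9]{2}$") {
  if (is.null(seqids)) {
    if (!is.null(models)) {
      tx <- tx_table(models)
      seqids <- setNames(tx$seqnames, tx$transcript_id)
    } else {
      seqids <- setNames(rep(NA_character_, nrow(calls)), calls$protein_id)
    }
  }
  if (nrow(calls) > 0L && !all(calls$protein_id %in% names(seqids))) {
    stop("call(s) without a gene model / sequence assignment: ",
         paste(utils::head(setdiff(calls$protein_id, names(seqids)), 3L),
               collapse = ", "))
  }
  full <- calls$completeness == "full"
  class_counts <- c(
    TNL = sum(calls$nlr_class == "TNL"),
    CNL = sum(calls$nlr_class == "CNL"),
    RNL = sum(calls$nlr_class == "RNL"))
  ids <- calls$integrated_domains[nzchar(calls$integrated_domains)]
  id_list <- lapply(strsplit(ids, ","), function(x)
    sub(":[0-9]+$", "", x))
  id_prev <- sort(table(unlist(id_list)), decreasing = TRUE)
  chrom <- unname(seqids[calls$protein_id])
  bucket <- ifelse(!is.na(chrom) & grepl(chromosome_pattern, chrom),
                   chrom, "scaffolds")
  per_chrom <- table(factor(bucket, levels = unique(
    c(sort(unique(bucket[bucket != "scaffolds"])), "scaffolds"))))
  per_chrom_class <- table(
    factor(bucket, levels = names(per_chrom)),
    factor(ifelse(full, calls$nlr_class, "partial"),
           levels = c("TNL", "CNL", "RNL", "partial")))
  out <- list(
    total = nrow(calls),
    full = sum(full),
    partial = sum(!full),
    class_counts = class_counts,
    tir_only = sum(calls$tir_only),
    cjid = sum(calls$has_cjid),
    nlr_id = sum(nzchar(calls$integrated_domains)),
    nlr_id_types = length(id_prev),
    id_prevalence = setNames(as.integer(id_prev), names(id_prev)),
    per_chromosome = setNames(as.integer(per_chrom), names(per_chrom)),
    per_chromosome_class = unclass(per_chrom_class))
  stopifnot(out$full + out$partial == out$total,
            sum(out$class_counts) == out$full,
            sum(out$per_chromosome) == out$total)
  class(out) <- "nlrome_summary"
  out
}

#' @export
print.nlrome_summary <- function(x, ...) {
  cat(sprintf("<nlrome_summary> %d NLRs: %d full (%d TNL / %d CNL / %d RNL), %d partial\n",
              x$total, x$full, x$class_counts["TNL"], x$class_counts["CNL"],
              x$class_counts["RNL"], x$partial))
  cat(sprintf("  TIR-only %d | C-JID %d | NLR-ID %d over %d domain types\n",
              x$tir_only, x$cjid, x$nlr_id, x$nlr_id_types))
  cat("  per chromosome:",
      paste(sprintf("%s=%d", names(x$per_chromosome), x$per_chromosome),
            collapse = " "), "\n")
  invisible(x)
}

#' Classify a tabulated per-gene domain-composition table
#'
#' Entry point for validating a cohort from a deposited per-gene table
#' rather than from sequences: a TSV with columns `protein_id`,
#' `chromosome` and `domains` (comma-separated ordered tokens, either
#' category names `TIR`/`CC`/`RPW8`/`NBARC`/`LRR`/`CJID` or accessions;
#' unknown tokens become integrated-domain candidates). The same
#' classification rules as the sequence pipeline are applied, then
#' aggregated.
#'
#' @param path Path to the TSV (with header), or a `data.frame` with the
#'   same columns.
#' @param chromosome_pattern See [summarize_nlrome()].
#' @return A list with `calls` (architecture table) and `summary`
#'   (`nlrome_summary`).
#' @export
classify_from_table <- function(path, chromosome_pattern = "^[AC][0-9]{2}$") {
  tab <- if (is.data.frame(path)) path else
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    colClasses = "character"))
  need <- c("protein_id", "chromosome", "domains")
  if (!all(need %in% names(tab))) {
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  toks <- strsplit(tab$domains, ",", fixed = TRUE)
  hits <- data.frame(
    protein_id = rep(tab$protein_id, lengths(toks)),
    source = "table",
    accession = trimws(unlist(toks)),
    description = "",
    start = unlist(lapply(lengths(toks), seq_len)) * 100L,
    end = unlist(lapply(lengths(toks), seq_len)) * 100L + 50L,
    evalue = 1e-10,
    stringsAsFactors = FALSE)
  hits <- hits[nzchar(hits$accession), , drop = FALSE]
  hits <- assign_categories(hits)
  calls <- classify_architecture(hits, protein_ids = tab$protein_id)
  calls <- calls[match(tab$protein_id, calls$protein_id), , drop = FALSE]
  rownames(calls) <- NULL
  summ <- summarize_nlrome(
    calls, seqids = setNames(tab$chromosome, tab$protein_id),
    chromosome_pattern = chromosome_pattern)
  list(calls = calls, summary = summ)
}

#' Write an architecture table as TSV
#'
#' @param calls Architecture table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}
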