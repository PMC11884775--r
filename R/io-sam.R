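#' Read SAM alignments as reference-space intervals
#'
#' Converts a SAM file to BAM with [Rsamtools::asBam()] and loads it with
#' [GenomicAlignments::readGAlignments()], so reference spans come from the
#' CIGAR via htslib. Unmapped, secondary and supplementary records are
#' excluded; a mapping-quality floor is optional (default 0 = keep all
#' primaries, since RenSeq depth inspection uses every primary alignment).
#'
#' @param path Path to a SAM (or BAM) file with a header.
#' @param min_mapq Minimum mapping quality to keep (default 0).
#' @return A `GRanges`, one range per kept alignment (the CIGAR reference
#'   span), with metadata columns `qname`, `mapq`, `flag`.
#' @export
read_alignments <- function(path, min_mapq = 0L) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    validate_sam_refs(path)
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        stop("failed to parse SAM ", path,
             " (is every reference name declared in the header?): ",
             conditionMessage(e))
      }
    )
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "mapq", "flag"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  gr <- GenomicRanges::granges(ga, use.mcols = TRUE)
  mapq <- S4Vectors::mcols(gr)$mapq
  mapq[is.na(mapq)] <- 0L
  gr <- gr[mapq >= min_mapq]
  GenomicRanges::strand(gr) <- "*"
  gr
}

# every mapped record's RNAME must be declared by an @SQ header line
validate_sam_refs <- function(path) {
  hdr <- character(0L)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 200L)
    if (length(l) == 0L) break
    hdr <- c(hdr, l[startsWith(l, "@")])
    if (!all(startsWith(l, "@"))) break
  }
  declared <- sub("\\t.*$", "", sub("^@SQ\\tSN:", "", hdr[startsWith(hdr, "@SQ")]))
  body <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, select = 2:3,
                      skip = sum(startsWith(hdr, "@")), fill = TRUE,
                      colClasses = "character"),
    error = function(e) NULL)
  if (is.null(body) || nrow(body) == 0L) return(invisible(TRUE))
  mapped <- bitwAnd(as.integer(body[[1L]]), 4L) == 0L
  rn <- body[[2L]][mapped]
  bad <- setdiff(unique(rn[rn != "*"]), declared)
  if (length(bad) > 0L) {
    stop("reference name(s) absent from SAM header in ", path, ": ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write alignment records as SAM text
#'
#' Emits a minimal, valid SAM file: `@HD`/`@SQ` header from the genome and
#' one line per record. Used by the read simulator for truth alignments;
#' real alignments normally come from an external aligner.
#'
#' @param records A `data.frame` with columns `qname`, `flag`, `rname`,
#'   `pos` (1-based leftmost), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`.
#' @param seqlengths Named integer vector of reference lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, seqlengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, as.integer(records$flag), records$rname,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar, records$rnext, as.integer(records$pnext),
                  as.integer(records$tlen), records$seq, records$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read InterProScan-style domain hits
#'
#' Accepts either the full InterProScan TSV layout (>= 9 columns: protein,
#' md5, length, analysis, accession, description, start, stop, e-value, ...)
#' or a minimal 7-column layout (protein, source, accession, description,
#' start, end, e-value). Protein coordinates are 1-based inclusive.
#'
#' @param path Path to a tab-separated file without header.
#' @return A `data.frame` of domain hits: `protein_id`, `source`,
#'   `accession`, `description`, `start`, `end`, `evalue`.
#' @export
read_domain_tsv <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(protein_id = character(), source = character(),
                      accession = character(), description = character(),
                      start = integer(), end = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) >= 9L) {
    cols <- c(1L, 4L, 5L, 6L, 7L, 8L, 9L)
  } else if (ncol(dt) == 7L) {
    cols <- 1:7
  } else {
    stop("expected 7 or >=9 tab-separated columns in ", path,
         ", found ", ncol(dt))
  }
  out <- as.data.frame(dt[, cols, with = FALSE])
  names(out) <- c("protein_id", "source", "accession", "description",
                  "start", "end", "evalue")
  ev <- suppressWarnings(as.numeric(out$evalue))
  if (anyNA(ev)) {
    stop("non-numeric e-value(s) in ", path, ": ",
         paste(utils::head(unique(out$evalue[is.na(ev)]), 3L), collapse = ", "))
  }
  out$evalue <- ev
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (anyNA(out$start) || anyNA(out$end) || any(out$end < out$start)) {
    stop("malformed domain coordinates in ", path)
  }
  out
}
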