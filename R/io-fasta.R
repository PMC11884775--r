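#' Read a FASTA file into a sequence set
#'
#' Thin, validating wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()]. Headers are truncated at the first
#' whitespace, sequences are uppercased, duplicate or empty ids and empty
#' sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (default) or `"aa"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 descr", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  seqs <- if (type == "dna") {
    Biostrings::readDNAStringSet(path, format = "fasta")
  } else {
    Biostrings::readAAStringSet(path, format = "fasta")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence in ", path, ": ", ids[Biostrings::width(seqs) == 0L][1L])
  }
  names(seqs) <- ids
  toupper_set(seqs, type)
}

toupper_set <- function(seqs, type) {
  out <- if (type == "dna") {
    Biostrings::DNAStringSet(toupper(as.character(seqs)))
  } else {
    Biostrings::AAStringSet(toupper(as.character(seqs)))
  }
  names(out) <- names(seqs)
  out
}

#' Write a sequence set to FASTA (60-column wrap)
#'
#' @param seqs A named `XStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
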