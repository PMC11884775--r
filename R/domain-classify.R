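# NLRtracker-style architecture classification.
#
# A protein is "full" when it has an N-terminal signaling domain (TIR, CC
# or RPW8), the central NB-ARC, and a C-terminal LRR; everything else is
# "partial". Full proteins are classed TNL/RNL/CNL with N-terminal
# precedence TIR > RPW8 > CC. Hits of category OTHER that survive the
# e-value filter on a protein that also carries NB-ARC or TIR are
# integrated-domain (NLR-ID) candidates.

#' Categorize and filter domain hits
#'
#' Maps accessions to the controlled vocabulary (`CC`, `TIR`, `RPW8`,
#' `NBARC`, `LRR`, `CJID`, `OTHER`; unknown accessions are `OTHER`, never
#' an error) and drops hits at or above the e-value threshold.
#'
#' @param hits A `data.frame` of domain hits (see [read_domain_tsv()] or
#'   [internal_domain_scan()]).
#' @param category_map Named character vector accession -> category
#'   (default [default_category_map()]).
#' @param max_evalue Strict e-value cutoff (default `1e-5`).
#' @return The filtered `data.frame` with a `category` column.
#' @export
assign_categories <- function(hits, category_map = default_category_map(),
                              max_evalue = 1e-5) {
  if (nrow(hits) == 0L) {
    hits$category <- character(0L)
    return(hits)
  }
  cat <- unname(category_map[hits$accession])
  cat[is.na(cat)] <- "OTHER"
  hits$category <- cat
  hits[hits$evalue < max_evalue, , drop = FALSE]
}

#' Classify protein domain architectures
#'
#' @param hits Categorized hits (see [assign_categories()]); columns
#'   `protein_id`, `accession`, `category`, `start`, `end`, `evalue`.
#' @param protein_ids Optional character vector of proteins to report even
#'   when they have no surviving hits (they come back with an empty
#'   domain string, `partial`, class `none`).
#' @return A `data.frame`, one row per protein: `protein_id`,
#'   `domain_string` (N-to-C order; OTHER hits shown by accession),
#'   `completeness` (`full`/`partial`), `nlr_class`
#'   (`TNL`/`CNL`/`RNL`/`none`), `tir_only`, `has_cjid`,
#'   `integrated_domains` (comma-separated `id:count`, empty if none).
#' @export
classify_architecture <- function(hits, protein_ids = NULL) {
  ids <- unique(c(if (nrow(hits)) unique(hits$protein_id), protein_ids))
  rows <- lapply(ids, function(pid) {
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    label <- ifelse(h$category == "OTHER", h$accession, h$category)
    cats <- unique(h$category)
    has_nt <- any(cats %in% c("TIR", "CC", "RPW8"))
    full <- has_nt && ("NBARC" %in% cats) && ("LRR" %in% cats)
    klass <- if (!full) "none"
    else if ("TIR" %in% cats) "TNL"
    else if ("RPW8" %in% cats) "RNL"
    else "CNL"
    data.frame(
      protein_id = pid,
      domain_string = paste(label, collapse = "-"),
      completeness = if (full) "full" else "partial",
      nlr_class = klass,
      tir_only = length(cats) > 0L && identical(cats, "TIR"),
      has_cjid = "CJID" %in% cats,
      integrated_domains = "",
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    protein_id = character(), domain_string = character(),
    completeness = character(), nlr_class = character(),
    tir_only = logical(), has_cjid = logical(),
    integrated_domains = character(), stringsAsFactors = FALSE)
  detect_integrated_domains(out, hits)
}

#' Detect integrated (non-canonical) domains
#'
#' Fills the `integrated_domains` column of an architecture table: every
#' OTHER-category hit on a protein that also carries NB-ARC or TIR
#' contributes its accession, with the copy count being the number of
#' disjoint hits of that accession on the protein.
#'
#' @param calls Architecture table (see [classify_architecture()]).
#' @param hits Categorized hits.
#' @return `calls` with `integrated_domains` updated.
#' @export
detect_integrated_domains <- function(calls, hits) {
  if (nrow(calls) == 0L || nrow(hits) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    pid <- calls$protein_id[i]
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    if (!any(h$category %in% c("NBARC", "TIR"))) next
    oth <- h[h$category == "OTHER", , drop = FALSE]
    if (nrow(oth) == 0L) next
    counts <- sort(table(oth$accession), decreasing = TRUE)
    calls$integrated_domains[i] <- paste(
      sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ",")
  }
  calls
}

#' Dependency-free consensus-pattern domain scan
#'
#' Scans amino-acid sequences for the shipped consensus patterns
#' (TIR/CC/RPW8/NB-ARC/LRR/C-JID plus named integrated-domain signatures;
#' see [protein_motif_table()]). When a P-loop and an MHD motif co-occur
#' in order, they are fused into one composite NB-ARC hit spanning
#' P-loop..MHD; likewise both TIR motifs fuse into one TIR hit. Exact
#' matches get a pseudo e-value of `1e-30` (composites `1e-50`), well
#' below the default threshold. This scanner is the internal counterpart
#' of an InterProScan/Pfam search and exists so synthetic pipelines run
#' without external software; real Pfam hits enter via
#' [read_domain_tsv()].
#'
#' @param proteins A named `AAStringSet` (or named character vector).
#' @return A `data.frame` of hits in the [read_domain_tsv()] layout.
#' @export
internal_domain_scan <- function(proteins) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  motifs <- protein_motif_table()
  rows <- list()
  k <- 0L
  for (i in seq_along(proteins)) {
    pid <- names(proteins)[i]
    aa <- as.character(proteins[[i]])
    hits <- NULL
    for (m in seq_len(nrow(motifs))) {
      g <- gregexpr(motifs$pattern[m], aa, perl = TRUE)[[1L]]
      if (g[1L] == -1L) next
      hits <- rbind(hits, data.frame(
        motif_id = motifs$motif_id[m], domain = motifs$domain[m],
        group = motifs$group[m],
        start = as.integer(g),
        end = as.integer(g) + attr(g, "match.length") - 1L,
        stringsAsFactors = FALSE))
    }
    if (is.null(hits)) next
    out <- compose_domain_hits(hits)
    if (nrow(out) == 0L) next
    k <- k + 1L
    out$protein_id <- pid
    rows[[k]] <- out
  }
  if (k == 0L) {
    return(data.frame(protein_id = character(), source = character(),
                      accession = character(), description = character(),
                      start = integer(), end = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[, c("protein_id", "source", "accession", "description",
          "start", "end", "evalue")]
}

# fold raw motif matches into domain-level hits for one protein
compose_domain_hits <- function(hits) {
  res <- list()
  add <- function(acc, desc, s, e, ev) {
    res[[length(res) + 1L]] <<- data.frame(
      source = "nlromer-motifs", accession = acc, description = desc,
      start = s, end = e, evalue = ev, stringsAsFactors = FALSE)
  }
  # composite NB-ARC: first ploop .. first mhd after it
  nb <- hits[hits$domain == "NBARC", , drop = FALSE]
  used_nb <- FALSE
  if (nrow(nb) > 0L) {
    pl <- nb[nb$motif_id == "ploop", , drop = FALSE]
    mh <- nb[nb$motif_id == "mhd", , drop = FALSE]
    if (nrow(pl) > 0L && nrow(mh) > 0L && any(mh$end > pl$start[1L])) {
      e <- min(mh$end[mh$end > pl$start[1L]])
      add("NBARC", "NB-ARC (P-loop..MHD composite)", pl$start[1L], e, 1e-50)
      used_nb <- TRUE
    }
  }
  if (!used_nb && nrow(nb) > 0L) {
    for (j in seq_len(nrow(nb))) {
      add("NBARC", paste0("NB-ARC motif ", nb$motif_id[j]),
          nb$start[j], nb$end[j], 1e-30)
    }
  }
  # composite TIR: tir1 .. tir2
  ti <- hits[hits$domain == "TIR", , drop = FALSE]
  used_ti <- FALSE
  if (nrow(ti) > 0L) {
    t1 <- ti[ti$motif_id == "tir1", , drop = FALSE]
    t2 <- ti[ti$motif_id == "tir2", , drop = FALSE]
    if (nrow(t1) > 0L && nrow(t2) > 0L && any(t2$end > t1$start[1L])) {
      add("TIR", "TIR (composite)", t1$start[1L],
          min(t2$end[t2$end > t1$start[1L]]), 1e-50)
      used_ti <- TRUE
    }
  }
  if (!used_ti && nrow(ti) > 0L) {
    for (j in seq_len(nrow(ti))) {
      add("TIR", paste0("TIR motif ", ti$motif_id[j]),
          ti$start[j], ti$end[j], 1e-30)
    }
  }
  simple <- hits[!(hits$domain %in% c("NBARC", "TIR")), , drop = FALSE]
  for (j in seq_len(nrow(simple))) {
    acc <- if (simple$domain[j] == "OTHER") simple$motif_id[j] else simple$domain[j]
    add(acc, paste0("consensus ", simple$motif_id[j]),
        simple$start[j], simple$end[j], 1e-30)
  }
  if (length(res) == 0L) {
    return(data.frame(source = character(), accession = character(),
                      description = character(), start = integer(),
                      end = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Extract NB-ARC domain sequences for phylogeny input
#'
#' For every protein with at least one NB-ARC hit, returns the
#' subsequence under the best (lowest e-value) NB-ARC hit. Proteins
#' without NB-ARC are excluded. The result is the standard input for
#' NB-ARC-based alignment and tree building.
#'
#' @param hits Categorized hits.
#' @param proteins A named `AAStringSet`.
#' @return A named `AAStringSet` of NB-ARC subsequences.
#' @export
extract_nbarc <- function(hits, proteins) {
  nb <- hits[hits$category == "NBARC", , drop = FALSE]
  if (nrow(nb) == 0L) return(Biostrings::AAStringSet())
  nb <- nb[order(nb$protein_id, nb$evalue, nb$start), , drop = FALSE]
  nb <- nb[!duplicated(nb$protein_id), , drop = FALSE]
  nb <- nb[nb$protein_id %in% names(proteins), , drop = FALSE]
  out <- Biostrings::AAStringSet(vapply(seq_len(nrow(nb)), function(j) {
    substr(as.character(proteins[[nb$protein_id[j]]]), nb$start[j], nb$end[j])
  }, character(1L)))
  names(out) <- nb$protein_id
  out
}
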