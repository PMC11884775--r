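#' Synthetic per-gene composition table for the Westar canola NLRome
#'
#' A deterministic, fully synthetic reconstruction of a per-gene
#' domain-composition table whose marginal counts match the reference
#' description of the refined *Brassica napus* cv. Westar NLRome: 715
#' NLRs of which 287 full (232 TNL, 39 CNL, 16 RNL) and 428 partial
#' (138 TIR-only); 199 C-JID carriers among 461 TIR-containing proteins;
#' 69 NLR-IDs over 49 distinct integrated-domain types, with
#' `Gal_oxidase` the most prevalent (8 proteins, 3 of them multi-copy);
#' chromosomes C09, A09 and A10 carrying 75, 68 and 9 NLRs. The deposited
#' per-gene data themselves are not redistributed here: this table is a
#' constructed stand-in (hence "synthetic") used to exercise and validate
#' the classifier and aggregator, via [classify_from_table()].
#'
#' @return A `data.frame` with columns `protein_id`, `chromosome`,
#'   `domains`.
#' @export
westar_reference_table <- function() {
  comp <- c(
    rep("TIR,NBARC,LRR", 232L),   # TNL
    rep("CC,NBARC,LRR", 39L),     # CNL
    rep("RPW8,NBARC,LRR", 16L),   # RNL
    rep("TIR", 138L),             # TIR-only partials
    rep("TIR,NBARC", 91L),        # other TIR-containing partials
    rep("NBARC,LRR", 100L),       # NL partials
    rep("NBARC", 99L))            # NB-ARC-only partials
  stopifnot(length(comp) == 715L)
  # C-JID: 199 of the 461 TIR-containing proteins (180 TNL + 19 TIR+NBARC)
  tnl_idx <- 1:232
  tn_idx <- 426:516               # the TIR,NBARC block
  cjid_idx <- c(tnl_idx[1:180], tn_idx[1:19])
  comp[cjid_idx] <- paste0(comp[cjid_idx], ",CJID")
  # integrated domains: 69 carriers, 49 distinct types; Gal_oxidase in 8
  # proteins (3 multi-copy), remaining 48 types over 61 proteins
  id_types <- c("Gal_oxidase",
                sprintf("ID_domain_%02d", 1:48))
  carriers <- c(1:60, 233:241)    # 60 TNL + 9 CNL
  tokens <- character(length(carriers))
  tokens[1:3] <- "Gal_oxidase,Gal_oxidase,Gal_oxidase"
  tokens[4:8] <- "Gal_oxidase"
  tokens[9:56] <- id_types[-1L]
  tokens[57:69] <- id_types[2:14]
  comp[carriers] <- paste0(comp[carriers], ",", tokens)
  chroms <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9), "scaffolds")
  counts <- setNames(rep(33L, 20L), chroms)
  counts["C09"] <- 75L
  counts["A09"] <- 68L
  counts["A10"] <- 9L
  counts["scaffolds"] <- 715L - sum(counts[setdiff(chroms, "scaffolds")])
  stopifnot(sum(counts) == 715L, all(counts >= 0L))
  # deterministic round-robin deal so every chromosome sees a mixture of
  # classes rather than one contiguous block
  chrom_assign <- unlist(lapply(seq_len(max(counts)), function(k)
    names(counts)[counts >= k]), use.names = FALSE)
  stopifnot(length(chrom_assign) == 715L)
  data.frame(protein_id = sprintf("WestarNLR_%03d", seq_len(715L)),
             chromosome = chrom_assign,
             domains = comp,
             stringsAsFactors = FALSE)
}
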