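# Degenerate consensus motifs and the cassette blocks built from them.
#
# The motif set is a deliberately simplified, fully documented stand-in for
# MEME-derived NLR motif libraries: ~12 short degenerate amino-acid patterns
# covering the NB-ARC core motifs (P-loop, Kinase-2, RNBS-B, GLPL, MHD), two
# TIR motifs, a double-unit LRR repeat, an EDVID-like CC motif, plus
# protein-level patterns for RPW8, C-JID and a handful of integrated
# domains. Patterns are regular expressions over the one-letter amino-acid
# alphabet; bracketed classes are the allowed residues at a position and '.'
# is any residue. Each cassette constant below contains one literal instance
# of its motifs, so planted architecture and detected architecture are
# exactly verifiable (see test suite).

# Genomic scan set: matched against six-frame translations.
# group: P-loop-side vs GLPL/MHD-side NB-ARC motifs, used for locus
# completeness calls.
nlr_motif_table <- function() {
  data.frame(
    motif_id = c("ploop", "kinase2", "rnbsb", "glpl", "mhd",
                 "tir1", "tir2", "lrr", "cc_edvid"),
    pattern = c(
      "GG[VM]GKTT",
      "KKYL[LIV]VLDDVW",
      "GSR[IL]I[IV]TTRD",
      "CGG[LIV]PLAL",
      "TLK[IV]HDV[LIV]R",
      "DVF[LIP]SFRGED",
      "WREALTE[IV]AN",
      "L..L.L..N.LL..L.L..N.L",
      "[KR]ELLE[DE]V[IV]DT"
    ),
    domain = c("NBARC", "NBARC", "NBARC", "NBARC", "NBARC",
               "TIR", "TIR", "LRR", "CC"),
    group = c("ploop", "ploop", "ploop", "mhd", "mhd",
              "tir", "tir", "lrr", "cc"),
    min_length = c(7L, 11L, 10L, 8L, 9L, 10L, 10L, 22L, 10L),
    stringsAsFactors = FALSE
  )
}

# Protein-level scan set: the genomic motifs plus N-terminal RPW8, the
# C-terminal jelly-roll C-JID, and named integrated-domain signatures.
# Integrated domains carry category OTHER so they surface as NLR-ID
# candidates rather than canonical architecture members.
protein_motif_table <- function() {
  extra <- data.frame(
    motif_id = c("rpw8", "cjid",
                 "Pkinase", "B3", "HMA", "Gal_oxidase", "zf-BED"),
    pattern = c(
      "WLPK[LIV]QE[LM]AY",
      "GPY[FY]VG[LM]PWN",
      "GSGGFGTVYK",
      "WEFRYSYWNS",
      "CEGCVSKIKK",
      "GDWETGSNSW",
      "CPKCGRSFSS"
    ),
    domain = c("RPW8", "CJID", "OTHER", "OTHER", "OTHER", "OTHER", "OTHER"),
    group = c("rpw8", "cjid", "id", "id", "id", "id", "id"),
    min_length = c(10L, 10L, 10L, 10L, 10L, 10L, 10L),
    stringsAsFactors = FALSE
  )
  rbind(nlr_motif_table(), extra)
}

# Cassette blocks: fixed amino-acid constants containing literal motif
# instances. The NB-ARC cassette starts exactly at its P-loop and ends
# exactly at its MHD so a P-loop..MHD composite hit spans the cassette
# byte-for-byte; likewise TIR spans tir1..tir2.
nlr_cassettes <- function() {
  c(
    TIR   = paste0("DVFLSFRGED", "TRKNFTSHLY", "WREALTEIAN"),
    CC    = paste0("KELLEDVIDT", "ARWVGEMSKE"),
    RPW8  = paste0("WLPKLQELAY", "EVISLRDDLE"),
    NBARC = paste0("GGVGKTT", "LAQKVYND", "KKYLIVLDDVW", "DESRSLFT",
                   "GSRIIVTTRD", "KEVLS", "CGGLPLAL", "ITLASS",
                   "TLKVHDVLR"),
    LRR   = paste0("LKSLDLSGNQL", "LESLNLSNNSL", "LKSLDLSGNQL", "LESLNLSNNSL"),
    CJID  = paste0("GPYFVGLPWN", "TSFEKVSKDW"),
    Pkinase     = paste0("GSGGFGTVYK", "AVKRLDQASE"),
    B3          = paste0("WEFRYSYWNS", "SQSRMFVLEN"),
    HMA         = paste0("CEGCVSKIKK", "ALEGVESVEV"),
    Gal_oxidase = paste0("GDWETGSNSW", "QPMPNARAYH"),
    `zf-BED`    = paste0("CPKCGRSFSS", "GKALGGHMRS")
  )
}

# Map Pfam-style accessions to the controlled category vocabulary used by
# the classifier. Anything absent from the map is OTHER (a candidate
# integrated domain), never an error.
default_category_map <- function() {
  c(
    PF00931 = "NBARC",   # NB-ARC
    PF01582 = "TIR",     # TIR
    PF13676 = "TIR",     # TIR_2
    PF05659 = "RPW8",    # RPW8
    PF18052 = "CC",      # Rx N-terminal coiled coil
    PF00560 = "LRR",     # LRR_1
    PF07725 = "LRR",     # LRR_3
    PF12799 = "LRR",     # LRR_4
    PF13306 = "LRR",     # LRR_5
    PF13855 = "LRR",     # LRR_8
    PF08263 = "LRR",     # LRRNT_2
    PF20160 = "CJID",    # C-JID
    # internal motif-scan identities
    TIR = "TIR", CC = "CC", RPW8 = "RPW8", NBARC = "NBARC",
    LRR = "LRR", CJID = "CJID"
  )
}

domain_categories <- c("CC", "TIR", "RPW8", "NBARC", "LRR", "CJID", "OTHER")
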