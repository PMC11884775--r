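# Architecture classification, e-value filtering, integrated domains,
# NB-ARC extraction.

hit_row <- function(pid, acc, start, end, ev = 1e-10) {
  data.frame(protein_id = pid, source = "t", accession = acc,
             description = "", start = start, end = end, evalue = ev,
             stringsAsFactors = FALSE)
}

test_that("category assignment maps accessions and filters by e-value", {
  hits <- rbind(hit_row("p1", "PF00931", 200, 500, 1e-30),
                hit_row("p1", "PF00069", 600, 800, 1e-3),
                hit_row("p1", "UNKNOWN123", 820, 900, 1e-8))
  out <- assign_categories(hits)
  expect_identical(out$category, c("NBARC", "OTHER"))  # 1e-3 dropped
  expect_identical(out$accession, c("PF00931", "UNKNOWN123"))

  # 100 random hits: survivors equal a brute-force filter
  set.seed(4)
  h <- do.call(rbind, lapply(1:100, function(i)
    hit_row(sprintf("p%02d", sample(5, 1)),
            sample(c("PF00931", "PF01582", "XX"), 1),
            1, 50, 10^runif(1, -20, 0))))
  out <- assign_categories(h)
  expect_identical(out$evalue, h$evalue[h$evalue < 1e-5])
})

test_that("architecture calls follow the completeness and class rules", {
  mk <- function(...) {
    cats <- c(...)
    do.call(rbind, lapply(seq_along(cats), function(i)
      hit_row("p", cats[i], i * 100, i * 100 + 50)))
  }
  call1 <- classify_architecture(assign_categories(mk("TIR", "NBARC", "LRR")))
  expect_identical(call1$completeness, "full")
  expect_identical(call1$nlr_class, "TNL")

  call2 <- classify_architecture(assign_categories(mk("NBARC")))
  expect_identical(call2$completeness, "partial")
  expect_identical(call2$nlr_class, "none")

  call3 <- classify_architecture(assign_categories(mk("TIR")))
  expect_true(call3$tir_only)
  expect_identical(call3$completeness, "partial")

  call4 <- classify_architecture(assign_categories(mk("RPW8", "NBARC", "LRR")))
  expect_identical(call4$nlr_class, "RNL")

  call5 <- classify_architecture(assign_categories(mk("CC", "NBARC", "LRR")))
  expect_identical(call5$nlr_class, "CNL")

  # N-terminal precedence TIR > RPW8 > CC when domains co-occur
  call6 <- classify_architecture(
    assign_categories(mk("CC", "TIR", "NBARC", "LRR")))
  expect_identical(call6$nlr_class, "TNL")
  call7 <- classify_architecture(
    assign_categories(mk("CC", "RPW8", "NBARC", "LRR")))
  expect_identical(call7$nlr_class, "RNL")

  # domain string preserves N->C order
  expect_identical(call1$domain_string, "TIR-NBARC-LRR")
})

test_that("integrated domains require a canonical NLR backbone", {
  tnl_kin <- rbind(hit_row("p", "TIR", 10, 100),
                   hit_row("p", "NBARC", 150, 400),
                   hit_row("p", "LRR", 450, 600),
                   hit_row("p", "Pkinase_acc", 650, 800))
  call <- classify_architecture(assign_categories(tnl_kin))
  expect_identical(call$integrated_domains, "Pkinase_acc:1")

  # three disjoint copies are counted
  multi <- rbind(hit_row("p", "TIR", 10, 100),
                 hit_row("p", "NBARC", 150, 400),
                 hit_row("p", "galox", 500, 560),
                 hit_row("p", "galox", 600, 660),
                 hit_row("p", "galox", 700, 760))
  call2 <- classify_architecture(assign_categories(multi))
  expect_identical(call2$integrated_domains, "galox:3")

  # OTHER hits without NB-ARC/TIR backbone are not NLR-IDs
  lone <- rbind(hit_row("p", "LRR", 10, 100),
                hit_row("p", "kinase_x", 200, 300))
  call3 <- classify_architecture(assign_categories(lone))
  expect_identical(call3$integrated_domains, "")
})

test_that("classification is a pure function of the hit set", {
  set.seed(33)
  h <- rbind(hit_row("p", "TIR", 10, 100), hit_row("p", "NBARC", 150, 400),
             hit_row("p", "LRR", 450, 600), hit_row("p", "xyz", 650, 700))
  a <- classify_architecture(assign_categories(h))
  b <- classify_architecture(assign_categories(h[sample(nrow(h)), ]))
  expect_identical(a, b)
})

test_that("classification algebra holds over random architectures", {
  set.seed(91)
  cats <- c("TIR", "CC", "RPW8", "NBARC", "LRR", "CJID", "OTHER")
  n <- 1000L
  hits <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1L)
    pick <- sample(cats, k)
    acc <- ifelse(pick == "OTHER", sprintf("ID_%d", sample(30, k)), pick)
    do.call(rbind, lapply(seq_len(k), function(j)
      hit_row(sprintf("p%04d", i), acc[j], j * 100, j * 100 + 50)))
  }))
  calls <- classify_architecture(assign_categories(hits))
  expect_equal(nrow(calls), n)
  expect_equal(sum(calls$completeness == "full"),
               sum(calls$nlr_class %in% c("TNL", "CNL", "RNL")))
  expect_equal(sum(calls$completeness == "full") +
                 sum(calls$completeness == "partial"), n)
  expect_true(all(calls$completeness[calls$tir_only] == "partial"))
  expect_true(all(calls$nlr_class[calls$completeness == "partial"] == "none"))
})

test_that("the consensus scanner recovers each cassette and only it", {
  cass <- nlr_cassettes()
  for (nm in c("TIR", "CC", "RPW8", "NBARC", "LRR", "CJID")) {
    p <- setNames(Biostrings::AAStringSet(
      paste0("MGSTA", cass[[nm]], "NDKEQ")), "p")
    h <- assign_categories(internal_domain_scan(p))
    expect_true(all(h$category == nm), info = nm)
    expect_gte(nrow(h), 1L)
  }
  # integrated-domain cassettes surface as OTHER with their own id
  p <- setNames(Biostrings::AAStringSet(
    paste0("MGSTA", cass[["Gal_oxidase"]], "NDKEQ")), "p")
  h <- assign_categories(internal_domain_scan(p))
  expect_identical(h$category, "OTHER")
  expect_identical(h$accession, "Gal_oxidase")
})

test_that("one substitution at a fixed motif position kills the hit", {
  cass <- nlr_cassettes()
  p_ok <- setNames(Biostrings::AAStringSet(cass[["NBARC"]]), "ok")
  h_ok <- internal_domain_scan(p_ok)
  expect_true("NBARC" %in% h_ok$accession)
  expect_equal(h_ok$evalue[h_ok$accession == "NBARC"], 1e-50)

  broken <- cass[["NBARC"]]
  substr(broken, 1L, 1L) <- "A"   # P-loop GG... -> AG...
  h_bad <- internal_domain_scan(setNames(Biostrings::AAStringSet(broken),
                                         "bad"))
  # composite NB-ARC gone; remaining motif hits are partial evidence
  expect_false(any(h_bad$evalue == 1e-50))

  # a random protein has no hits at all
  set.seed(77)
  p0 <- motif_free_protein(300L)
  expect_identical(nrow(internal_domain_scan(
    setNames(Biostrings::AAStringSet(p0), "r"))), 0L)
})

test_that("NB-ARC extraction returns the best-hit subsequence", {
  prot <- setNames(Biostrings::AAStringSet(
    paste0(strrep("G", 99L), nlr_cassettes()[["NBARC"]], strrep("S", 50L))),
    "p1")
  hits <- assign_categories(internal_domain_scan(prot))
  nb <- extract_nbarc(hits, prot)
  expect_identical(as.character(nb[["p1"]]), nlr_cassettes()[["NBARC"]])

  # TIR-only proteins are excluded
  tir <- setNames(Biostrings::AAStringSet(
    paste0("MGSTA", nlr_cassettes()[["TIR"]])), "t1")
  h2 <- assign_categories(internal_domain_scan(tir))
  expect_length(extract_nbarc(h2, tir), 0L)
})
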