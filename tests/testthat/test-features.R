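test_that("description tokenization lowers, prunes and lemmatizes", {
  expect_setequal(tokenize_description("Encoding protein X"),
                  c("encode", "protein", "x"))
  expect_identical(tokenize_description(""), character())
  expect_identical(tokenize_description("   "), character())
  expect_setequal(tokenize_description("zinc zinc finger"),
                  c("zinc", "finger"))
  expect_setequal(tokenize_description("The genes of a gene"), "gene")
})

test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("x", "y"), c("y", "x")), 1)
  expect_equal(jaccard(character(), character()), 0)
  expect_equal(jaccard(c("a"), character()), 0)
})

test_that("description similarity is order-insensitive", {
  r1 <- gb_record("D1", "ACGT", description = "zinc finger protein")
  r2 <- gb_record("D2", "ACGT", description = "protein finger zinc")
  r3 <- gb_record("D3", "ACGT", description = "heat shock factor")
  expect_equal(description_similarity(r1, r2), 1)
  expect_equal(description_similarity(r1, r3), 0)
  expect_equal(description_similarity(r1, r1), 1)
})

test_that("literature similarity applies the PMID/journal/author cascade", {
  lit <- function(...) list(gb_reference(...))
  mk <- function(refs) gb_record("L", "ACGT", references = refs)
  # both PMIDs -> Boolean match
  a <- mk(lit(authors = "A,B.", journal = "J 1", title = "t one",
              pubmed_id = "12345"))
  b <- mk(lit(authors = "C,D.", journal = "J 2", title = "t two",
              pubmed_id = "12345"))
  expect_identical(literature_similarity(a, b),
                   list(has_literature = "Yes", value = 1))
  b2 <- mk(lit(authors = "C,D.", journal = "J 2", title = "t two",
               pubmed_id = "99999"))
  expect_identical(literature_similarity(a, b2),
                   list(has_literature = "Yes", value = 0))
  # no PMIDs, both journal entries -> title token Jaccard
  c1 <- mk(lit(authors = "A,B.", journal = "J 1",
               title = "zinc finger protein"))
  c2 <- mk(lit(authors = "C,D.", journal = "J 2",
               title = "protein zinc finger"))
  expect_equal(literature_similarity(c1, c2)$value, 1)
  # authors-only fallback
  d1 <- mk(lit(authors = c("A,B.", "C,D.")))
  d2 <- mk(lit(authors = c("C,D.", "E,F.")))
  expect_equal(literature_similarity(d1, d2)$value, 1 / 3)
  # one side without literature -> missing
  e1 <- mk(list())
  out <- literature_similarity(e1, a)
  expect_identical(out$has_literature, "No")
  expect_true(is.na(out$value))
})

test_that("submitter similarity uses shared-member semantics with NA", {
  mk <- function(sub) gb_record("S", "ACGT", submitters = sub)
  expect_identical(submitter_similarity(mk("smith,j."),
                                        mk(c("smith,j.", "lee,k."))), "SAME")
  expect_identical(submitter_similarity(mk("smith,j."), mk("lee,k.")),
                   "DIFFERENT")
  expect_identical(submitter_similarity(mk(NULL), mk("lee,k.")), "NA")
})

test_that("length ratio is min/max and rejects non-positive lengths", {
  expect_equal(length_ratio(100, 100), 1)
  expect_equal(length_ratio(72, 100), 0.72)
  expect_equal(length_ratio(100, 72), 0.72)
  expect_error(length_ratio(0, 10), "positive")
})

test_that("aligned proportion follows len(I)/max(len(D), len(R))", {
  # direct substitution: 50 identical bases, lengths 100 and 80
  out <- parse_blast_tabular("50\t60\t83.3\t1e-20\t80\t1\t60\t1\t60")
  expect_equal(compute_ap(out, 100, 80), 0.5)
  # identical sequences -> 1.0
  set.seed(13)
  s <- random_dna(400)
  expect_equal(compute_ap(align_pair(s, s, align_params()), 400, 400), 1)
  # exact half-length substring -> 0.5
  sub <- substr(s, 101, 300)
  expect_equal(compute_ap(align_pair(s, sub, align_params()), 400, 200), 0.5)
  # contract: no hits means AP must be missing, not zero
  none <- parse_blast_tabular(character())
  expect_error(compute_ap(none, 10, 10), "missing")
})

test_that("alignment features honour the missing-value contract", {
  set.seed(19)
  s <- random_dna(500)
  f <- alignment_features(s, s)
  expect_identical(f$has_hits, "Yes")
  expect_equal(f$identity, 1)
  expect_equal(f$ap, 1)
  expect_identical(f$over_threshold, "No")
  # force "no hits" with a draconian report cutoff
  f2 <- alignment_features(random_dna(40), random_dna(40),
                           align_params(evalue_cutoff = 1e-30))
  expect_identical(f2$has_hits, "No")
  expect_true(is.na(f2$identity) && is.na(f2$ap) && is.na(f2$expect_value))
  expect_identical(f2$over_threshold, "Yes")
})

test_that("the pair representation has exactly the 22 features", {
  expect_length(seqdedup:::FEATURE_NAMES, 22)
  fx <- small_mixed_corpus()
  corp <- fx$corpus
  pr <- corp$pairs[1, ]
  f <- compute_pair_features(corp$records[[pr$accession_a]],
                             corp$records[[pr$accession_b]])
  expect_identical(names(f), seqdedup:::FEATURE_NAMES)
  expect_length(unclass(f), 22)
})

test_that("pair features are symmetric in the record order", {
  corp <- small_mixed_corpus()$corpus
  set.seed(3)
  idx <- sample(nrow(corp$pairs), 8)
  for (i in idx) {
    a <- corp$records[[corp$pairs$accession_a[i]]]
    b <- corp$records[[corp$pairs$accession_b[i]]]
    fab <- compute_pair_features(a, b)
    fba <- compute_pair_features(b, a)
    expect_equal(unclass(fab)[seqdedup:::FEATURE_NAMES],
                 unclass(fba)[seqdedup:::FEATURE_NAMES],
                 tolerance = 1e-12, info = paste("pair", i))
  }
})

test_that("feature ranges and missing-value couplings hold corpus-wide", {
  feats <- small_mixed_corpus()$features
  in01 <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  for (cc in c("description", "literature", "length", "identity", "ap",
               "cds_identity", "cds_ap", "trs_identity", "trs_ap"))
    expect_true(in01(feats[[cc]]), info = cc)
  for (cc in c("expect_value", "cds_expect", "trs_expect"))
    expect_true(all(is.na(feats[[cc]]) | feats[[cc]] >= 0), info = cc)
  couple <- function(hits, num_cols, thresh) {
    no <- feats[[hits]] == "No"
    for (cc in num_cols)
      expect_true(all(is.na(feats[[cc]][no])), info = paste(hits, cc))
    expect_true(all(feats[[thresh]][no] == "Yes"), info = hits)
  }
  couple("has_hits", c("identity", "ap", "expect_value"), "over_threshold")
  couple("cds_hits", c("cds_identity", "cds_ap", "cds_expect"),
         "cds_threshold")
  couple("trs_hits", c("trs_identity", "trs_ap", "trs_expect"),
         "trs_threshold")
  # literature value missing iff no shared literature evidence possible
  expect_true(all(is.na(feats$literature[feats$has_literature == "No"])))
})

test_that("pairs lacking a CDS degrade to No/missing, not errors", {
  cfg <- synth_config(seed = 9L, n_pairs = c(ES = 6L, EF = 0L, NS = 0L,
                                             DI = 6L, DI_hard = 0L),
                      length_range = c(300L, 400L), p_cds = 0)
  corp <- generate_corpus(cfg)
  feats <- compute_feature_matrix(corp$pairs, corp$records)
  expect_true(all(feats$has_cds == "No"))
  expect_true(all(feats$cds_hits == "No" & feats$trs_hits == "No"))
  expect_true(all(is.na(feats$cds_identity) & is.na(feats$trs_identity)))
})

test_that("feature matrices survive the TSV round trip", {
  feats <- small_mixed_corpus()$features
  f <- tempfile(fileext = ".tsv")
  write_features_tsv(feats, f)
  back <- read_features_tsv(f)
  expect_identical(names(back), names(feats))
  expect_equal(back$identity, feats$identity, tolerance = 1e-9)
  expect_identical(back$submitter, feats$submitter)
  expect_identical(back$label, feats$label)
  writeLines("accession_a\taccession_b\tnothing", f)
  expect_error(read_features_tsv(f), "missing columns")
})
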