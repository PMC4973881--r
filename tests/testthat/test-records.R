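test_that("generated records round-trip through the GenBank writer/parser", {
  corp <- small_mixed_corpus()$corpus
  lines <- write_genbank(unname(corp$records))
  parsed <- parse_genbank(text = lines)
  expect_length(parsed, length(corp$records))
  by_acc <- function(x) x[order(vapply(x, `[[`, character(1), "accession"))]
  expect_identical(lapply(by_acc(parsed), unclass),
                   lapply(by_acc(unname(corp$records)), unclass))
})

test_that("empty input yields an empty record list", {
  expect_identical(parse_genbank(text = character()), list())
  expect_identical(parse_genbank(text = c("", "   ")), list())
})

test_that("direct-submission references become submitters, not literature", {
  rec <- gb_record(
    accession = "TEST1", sequence = "ACGTACGTACGT",
    description = "test record",
    references = list(gb_reference(authors = c("Smith,J.", "Lee,K."),
                                   title = "Direct Submission",
                                   journal = "Submitted (01-JAN-2010) Inst",
                                   direct_submission = TRUE)),
    submitters = c("Smith,J.", "Lee,K."))
  parsed <- parse_genbank(text = write_genbank(rec))[[1]]
  expect_setequal(parsed$submitters, c("smith,j.", "lee,k."))
  expect_length(literature_refs(parsed), 0)
  # no direct-submission reference -> submitters absent
  rec2 <- gb_record("TEST2", "ACGTACGT",
                    references = list(gb_reference(authors = "Kim,H.",
                                                   title = "a title",
                                                   journal = "J. X 1 (2000)",
                                                   pubmed_id = "123")))
  parsed2 <- parse_genbank(text = write_genbank(rec2))[[1]]
  expect_null(parsed2$submitters)
})

test_that("first_cds selects the leading CDS and handles absences", {
  seq <- strrep("ACGT", 30)
  rec <- gb_record("T3", seq, cds = list(
    gb_cds(0, 12, sequence = seq, translation = "MTRA"),
    gb_cds(24, 36, sequence = seq),
    gb_cds(48, 60, sequence = seq)))
  fc <- first_cds(rec)
  expect_identical(fc$nucleotide_seq, substr(seq, 1, 12))
  expect_identical(fc$translation, "MTRA")
  expect_null(first_cds(gb_record("T4", seq)))
  fc2 <- first_cds(gb_record("T5", seq,
                             cds = list(gb_cds(4, 16, sequence = seq))))
  expect_null(fc2$translation)
  expect_identical(fc2$nucleotide_seq, substr(seq, 5, 16))
})

test_that("simple CDS slices match the record sequence after parsing", {
  corp <- small_mixed_corpus()$corpus
  parsed <- parse_genbank(text = write_genbank(unname(corp$records)))
  for (r in parsed) {
    for (x in r$cds) {
      if (is.null(x$location))  # simple forward span
        expect_identical(x$nucleotide_seq,
                         substr(r$sequence, x$start + 1, x$end))
    }
  }
})

test_that("joined and complement CDS locations follow flat-file semantics", {
  seq <- "AAAACCCCGGGGTTTTACGTACGTACGTACGT"
  txt <- c(
    "LOCUS       LOCTEST          32 bp    DNA     linear   SYN 01-JAN-2026",
    "DEFINITION  location test.",
    "ACCESSION   LOCTEST",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..4,9..12)",
    "     CDS             complement(5..8)",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//")
  rec <- parse_genbank(text = txt)[[1]]
  expect_identical(rec$cds[[1]]$nucleotide_seq, "AAAAGGGG")
  expect_identical(rec$cds[[1]]$start, 0L)
  expect_identical(rec$cds[[1]]$end, 12L)
  expect_identical(rec$cds[[2]]$nucleotide_seq, "GGGG")  # revcomp of CCCC
})

test_that("malformed blocks are rejected with the offending block named", {
  no_origin <- c(
    "LOCUS       BADREC           12 bp    DNA     linear   SYN 01-JAN-2026",
    "DEFINITION  broken.",
    "ACCESSION   BADREC",
    "//")
  expect_error(parse_genbank(text = no_origin), "BADREC|LOCUS|ORIGIN")
  no_locus <- c("DEFINITION  orphan.", "ORIGIN",
                "        1 acgt", "//")
  expect_error(parse_genbank(text = no_locus), "LOCUS|ORIGIN")
})

test_that("author names are normalized to a canonical comparable form", {
  expect_identical(normalize_author(c("Smith, J.", " LEE,K. ")),
                   c("smith,j.", "lee,k."))
  expect_identical(normalize_author("O'Brien, P."), "obrien,p.")
})

test_that("an independent parser agrees on the generated flat file", {
  # Biopython reads the same file: accession, sequence and CDS count agree
  corp <- generate_corpus(synth_config(
    seed = 5L, n_pairs = c(ES = 2L, EF = 0L, NS = 0L, DI = 2L, DI_hard = 0L),
    length_range = c(300L, 400L)))
  gb <- tempfile(fileext = ".gb")
  write_genbank(unname(corp$records), gb)
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "for r in SeqIO.parse(sys.argv[1], 'genbank'):",
    "    n = sum(1 for f in r.features if f.type == 'CDS')",
    "    print(r.name, len(r.seq), n, str(r.seq[:25]))",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, gb), stdout = TRUE)
  expect_length(out, length(corp$records))
  parsed <- parse_genbank(gb)
  for (i in seq_along(parsed)) {
    parts <- strsplit(out[i], " ", fixed = TRUE)[[1]]
    r <- parsed[[i]]
    expect_identical(parts[1], r$accession)
    expect_identical(as.integer(parts[2]), nchar(r$sequence))
    expect_identical(as.integer(parts[3]), length(r$cds))
    expect_identical(parts[4], substr(r$sequence, 1, 25))
  }
})

test_that("pair-label files validate their schema", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("accession_a\taccession_b\tlabel\tsubtype",
               "A1\tA2\tDU\tES", "A3\tA4\tDI\tNA"), f)
  labs <- read_pair_labels(f)
  expect_identical(labs$label, c("DU", "DI"))
  writeLines(c("accession_a\taccession_b\tlabel", "A1\tA2\tMAYBE"), f)
  expect_error(read_pair_labels(f), "unknown pair labels")
})
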