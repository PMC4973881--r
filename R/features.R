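# ---------------------------------------------------------------------------
# The 22-feature pairwise representation of a record pair:
#   description, has_literature, literature, submitter,                (meta)
#   length, has_hits, identity, ap, expect_value, over_threshold,      (seq)
#   has_cds, cds_hits, cds_identity, cds_ap, cds_expect, cds_threshold,
#   has_trs, trs_hits, trs_identity, trs_ap, trs_expect, trs_threshold
# Missing-value semantics: when an alignment has no hits, its dependent
# numeric features are missing and the over-threshold flag is "Yes" (no
# significant similarity being the extreme of a non-significant alignment).
# ---------------------------------------------------------------------------

EVALUE_THRESHOLD <- 0.001

FEATURE_NAMES <- c(
  "description", "has_literature", "literature", "submitter",
  "length", "has_hits", "identity", "ap", "expect_value", "over_threshold",
  "has_cds", "cds_hits", "cds_identity", "cds_ap", "cds_expect",
  "cds_threshold",
  "has_trs", "trs_hits", "trs_identity", "trs_ap", "trs_expect",
  "trs_threshold")

CATEGORICAL_FEATURES <- c("has_literature", "submitter", "has_hits",
                          "over_threshold", "has_cds", "cds_hits",
                          "cds_threshold", "has_trs", "trs_hits",
                          "trs_threshold")

NUMERIC_FEATURES <- setdiff(FEATURE_NAMES, CATEGORICAL_FEATURES)

#' Stopword list used by the description tokenizer
#'
#' A fixed, versioned English stopword list shipped with the package, so
#' tokenization is reproducible across installations.
#'
#' @return Character vector of stopwords.
#' @export
gb_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "from",
    "has", "have", "in", "into", "is", "it", "its", "of", "on", "or",
    "that", "the", "this", "to", "was", "were", "which", "with")
}

# Deterministic rule-based lemmatizer. Crude by design: what matters for a
# set-overlap similarity is that inflected variants of the same word map to
# the same token (encoding/encode -> encode), not dictionary correctness.
lemmatize_token <- function(tok) {
  n <- nchar(tok)
  if (n >= 5L && endsWith(tok, "ies")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n >= 4L && endsWith(tok, "s") && !endsWith(tok, "ss") &&
      !endsWith(tok, "us") && !endsWith(tok, "is"))
    tok <- substr(tok, 1L, nchar(tok) - 1L)
  n <- nchar(tok)
  if (n >= 6L && endsWith(tok, "ing")) return(paste0(substr(tok, 1L, n - 3L), "e"))
  if (n >= 5L && endsWith(tok, "ed")) return(substr(tok, 1L, n - 1L))
  tok
}

#' Tokenize a record description
#'
#' Lowercases, splits on non-alphanumeric characters, removes stopwords,
#' lemmatizes each token with a deterministic rule set (e.g. "encoding" to
#' "encode"), and returns the unique token set.
#'
#' @param text Free text (the DEFINITION field).
#' @param stopwords Stopword list; defaults to [gb_stopwords()].
#' @return Character vector (a set) of tokens.
#' @export
#' @examples
#' tokenize_description("Encoding protein X")
tokenize_description <- function(text, stopwords = gb_stopwords()) {
  if (is.null(text) || !nzchar(trimws(text))) return(character())
  toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(text)), " ",
                   fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- setdiff(toks, stopwords)
  unique(vapply(toks, lemmatize_token, character(1L), USE.NAMES = FALSE))
}

#' Jaccard similarity of two sets
#'
#' Shared elements divided by total distinct elements. Two empty sets give
#' 0: empty fields share no evidence.
#'
#' @param set_a,set_b Character vectors treated as sets.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Description similarity of a record pair
#'
#' Jaccard similarity of the tokenized descriptions; order-insensitive.
#'
#' @param r1,r2 [gb_record()] objects.
#' @return Similarity in `[0, 1]`.
#' @export
description_similarity <- function(r1, r2) {
  jaccard(tokenize_description(r1$description),
          tokenize_description(r2$description))
}

#' Literature similarity of a record pair
#'
#' Rule cascade over the non-direct-submission references: (1) if both
#' records carry PubMed IDs, Boolean matching of the pooled ID sets; (2)
#' else if both carry a journal reference, token-Jaccard of that reference's
#' title; (3) else Jaccard of the pooled author-name sets. When either
#' record has no literature reference the similarity is missing.
#'
#' @param r1,r2 [gb_record()] objects.
#' @return List with `has_literature` (`"Yes"`/`"No"`) and `value`
#'   (numeric, `NA` when `has_literature` is `"No"`).
#' @export
literature_similarity <- function(r1, r2) {
  refs1 <- literature_refs(r1); refs2 <- literature_refs(r2)
  if (length(refs1) == 0L || length(refs2) == 0L)
    return(list(has_literature = "No", value = NA_real_))
  pm1 <- unlist(lapply(refs1, `[[`, "pubmed_id"))
  pm2 <- unlist(lapply(refs2, `[[`, "pubmed_id"))
  if (length(pm1) && length(pm2))
    return(list(has_literature = "Yes",
                value = as.numeric(length(intersect(pm1, pm2)) > 0L)))
  j1 <- Filter(function(r) !is.null(r$journal), refs1)
  j2 <- Filter(function(r) !is.null(r$journal), refs2)
  if (length(j1) && length(j2)) {
    t1 <- tokenize_description(j1[[1L]]$title %||% "")
    t2 <- tokenize_description(j2[[1L]]$title %||% "")
    return(list(has_literature = "Yes", value = jaccard(t1, t2)))
  }
  a1 <- unique(unlist(lapply(refs1, `[[`, "authors")))
  a2 <- unique(unlist(lapply(refs2, `[[`, "authors")))
  list(has_literature = "Yes", value = jaccard(a1, a2))
}

#' Submitter similarity of a record pair
#'
#' `"SAME"` when the records share at least one submitter, `"DIFFERENT"`
#' when they share none, `"NA"` when either record does not provide
#' submitter information (following the update policy that any one original
#' submitter can act on a record).
#'
#' @param r1,r2 [gb_record()] objects.
#' @return One of `"SAME"`, `"DIFFERENT"`, `"NA"`.
#' @export
submitter_similarity <- function(r1, r2) {
  s1 <- r1$submitters; s2 <- r2$submitters
  if (is.null(s1) || is.null(s2) || length(s1) == 0L || length(s2) == 0L)
    return("NA")
  if (length(intersect(s1, s2)) > 0L) "SAME" else "DIFFERENT"
}

#' Length ratio of two sequences
#'
#' Shorter length divided by longer length; symmetric.
#'
#' @param len_a,len_b Sequence lengths in bases (both positive).
#' @return Ratio in `(0, 1]`.
#' @export
length_ratio <- function(len_a, len_b) {
  if (len_a <= 0 || len_b <= 0)
    stop("length_ratio: lengths must be positive", call. = FALSE)
  min(len_a, len_b) / max(len_a, len_b)
}

#' Aligned proportion (AP)
#'
#' The number of locally aligned identical bases divided by the length of
#' the longer sequence — an estimate of global sequence identity without
#' performing global alignment. By default the identical-base count of the
#' single best HSP is used; `mode = "union"` sums the non-overlapping HSPs.
#'
#' @param outcome An `alignment_outcome` with hits.
#' @param len_d,len_r Lengths of the two sequences.
#' @param mode `"best"` (default) or `"union"`.
#' @return AP in `[0, 1]`.
#' @export
compute_ap <- function(outcome, len_d, len_r, mode = c("best", "union")) {
  mode <- match.arg(mode)
  if (!isTRUE(outcome$has_hits))
    stop("compute_ap: outcome has no hits; AP must be treated as missing",
         call. = FALSE)
  ni <- if (mode == "best") outcome$hsps[[1L]]$num_identical
        else sum(vapply(outcome$hsps, `[[`, integer(1L), "num_identical"))
  min(1, ni / max(len_d, len_r))
}

#' Alignment-derived features for one sequence pair
#'
#' Aligns the pair and derives the hit flag, best-HSP local identity, AP,
#' E-value, and the over-threshold flag (`"Yes"` iff there is no hit or the
#' E-value is strictly greater than 0.001).
#'
#' @param seq_a,seq_b Sequences.
#' @param params An [align_params()] object.
#' @param backend Alignment backend, see [align_pair()].
#' @param ap_mode AP aggregation mode, see [compute_ap()].
#' @param max_hsps HSP cap passed to the aligner.
#' @return List with `has_hits`, `identity`, `ap`, `expect_value`,
#'   `over_threshold`.
#' @export
alignment_features <- function(seq_a, seq_b, params = align_params(),
                               backend = "internal", ap_mode = "best",
                               max_hsps = 1L) {
  out <- align_pair(seq_a, seq_b, params, backend = backend,
                    max_hsps = if (ap_mode == "union") 5L else max_hsps)
  if (!out$has_hits)
    return(list(has_hits = "No", identity = NA_real_, ap = NA_real_,
                expect_value = NA_real_, over_threshold = "Yes"))
  best <- out$hsps[[1L]]
  list(has_hits = "Yes",
       identity = best$identity_fraction,
       ap = compute_ap(out, nchar(seq_a), nchar(seq_b), mode = ap_mode),
       expect_value = best$evalue,
       over_threshold = if (best$evalue > EVALUE_THRESHOLD) "Yes" else "No")
}

#' Compute the 22-feature representation of a record pair
#'
#' Whole sequences and first coding regions are compared in nucleotide
#' mode; first-CDS translations in protein mode. Degenerate inputs (absent
#' CDS or translation, no alignment hits) produce missing/`"No"` values,
#' never errors.
#'
#' @param rec_a,rec_b [gb_record()] objects.
#' @param backend Alignment backend, see [align_pair()].
#' @param ap_mode AP aggregation mode, see [compute_ap()].
#' @param nt_params,aa_params Alignment parameter overrides.
#' @return A named list of class `pair_features` with the 22 features.
#' @export
compute_pair_features <- function(rec_a, rec_b, backend = "internal",
                                  ap_mode = "best",
                                  nt_params = align_params("nucleotide"),
                                  aa_params = align_params("protein")) {
  lit <- literature_similarity(rec_a, rec_b)
  f <- list(
    description = description_similarity(rec_a, rec_b),
    has_literature = lit$has_literature,
    literature = lit$value,
    submitter = submitter_similarity(rec_a, rec_b),
    length = length_ratio(nchar(rec_a$sequence), nchar(rec_b$sequence)))
  f <- c(f, alignment_features(rec_a$sequence, rec_b$sequence, nt_params,
                               backend = backend, ap_mode = ap_mode))

  cds_a <- first_cds(rec_a); cds_b <- first_cds(rec_b)
  no_align <- list(hits = "No", identity = NA_real_, ap = NA_real_,
                   expect = NA_real_, threshold = "Yes")
  has_cds <- "No"; has_trs <- "No"; cdsf <- no_align; trsf <- no_align
  if (!is.null(cds_a) && !is.null(cds_b)) {
    has_cds <- "Yes"
    af <- alignment_features(cds_a$nucleotide_seq, cds_b$nucleotide_seq,
                             nt_params, backend = backend, ap_mode = ap_mode)
    cdsf <- list(hits = af$has_hits, identity = af$identity, ap = af$ap,
                 expect = af$expect_value, threshold = af$over_threshold)
    if (!is.null(cds_a$translation) && !is.null(cds_b$translation)) {
      has_trs <- "Yes"
      af <- alignment_features(cds_a$translation, cds_b$translation,
                               aa_params, backend = backend, ap_mode = ap_mode)
      trsf <- list(hits = af$has_hits, identity = af$identity, ap = af$ap,
                   expect = af$expect_value, threshold = af$over_threshold)
    }
  }
  f$has_cds <- has_cds
  f$cds_hits <- cdsf$hits; f$cds_identity <- cdsf$identity
  f$cds_ap <- cdsf$ap; f$cds_expect <- cdsf$expect
  f$cds_threshold <- cdsf$threshold
  f$has_trs <- has_trs
  f$trs_hits <- trsf$hits; f$trs_identity <- trsf$identity
  f$trs_ap <- trsf$ap; f$trs_expect <- trsf$expect
  f$trs_threshold <- trsf$threshold
  f <- f[FEATURE_NAMES]
  structure(f, class = "pair_features",
            accessions = c(rec_a$accession, rec_b$accession))
}

#' @export
print.pair_features <- function(x, ...) {
  acc <- attr(x, "accessions")
  cat("<pair_features>", acc[1L], "vs", acc[2L], "\n")
  df <- as.data.frame(lapply(unclass(x), function(v)
    if (is.numeric(v)) signif(v, 4) else v), stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compute the feature matrix for a set of labelled pairs
#'
#' @param pairs Tibble with `accession_a`, `accession_b` and optionally
#'   `label` (`DU`/`DI`) and `subtype` columns.
#' @param records Named list of [gb_record()] objects keyed by accession.
#' @param ... Passed to [compute_pair_features()].
#' @return Tibble with the accession columns, any label columns, and the 22
#'   feature columns.
#' @export
compute_feature_matrix <- function(pairs, records, ...) {
  stopifnot(all(c("accession_a", "accession_b") %in% names(pairs)))
  missing_acc <- setdiff(unique(c(pairs$accession_a, pairs$accession_b)),
                         names(records))
  if (length(missing_acc))
    stop("records missing for accessions: ",
         paste(utils::head(missing_acc, 5L), collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- compute_pair_features(records[[pairs$accession_a[i]]],
                               records[[pairs$accession_b[i]]], ...)
    tibble::as_tibble(unclass(f))
  })
  feats <- dplyr::bind_rows(rows)
  keep <- intersect(c("accession_a", "accession_b", "label", "subtype"),
                    names(pairs))
  dplyr::bind_cols(pairs[keep], feats)
}

#' Write / read a feature-matrix TSV
#'
#' One row per pair: accession pair, label columns when present, and the 22
#' named feature columns; missing values encoded as `NA`.
#'
#' @param features Feature tibble from [compute_feature_matrix()].
#' @param file Path.
#' @return `read_features_tsv` returns the tibble; `write_features_tsv`
#'   returns the path invisibly.
#' @export
write_features_tsv <- function(features, file) {
  utils::write.table(features, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  miss <- setdiff(FEATURE_NAMES, names(df))
  if (length(miss))
    stop("feature TSV is missing columns: ", paste(miss, collapse = ", "))
  for (cc in CATEGORICAL_FEATURES) df[[cc]] <- as.character(df[[cc]])
  # the submitter category "NA" is a level, not a missing value
  df$submitter[is.na(df$submitter)] <- "NA"
  tibble::as_tibble(df)
}
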