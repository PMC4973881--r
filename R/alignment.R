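# ---------------------------------------------------------------------------
# Local-alignment statistics behind one contract: hit flag, per-HSP identity,
# identical-base count and E-value, from either the internal Smith-Waterman
# engine (Biostrings dynamic programming + Karlin-Altschul statistics) or an
# external NCBI BLAST+ backend (bl2seq-style -subject calls).
#
# Scoring follows classic blastn/blastp defaults: nucleotide match +2 /
# mismatch -3, gap open 5 / extend 2; protein BLOSUM62, gap open 11 /
# extend 1. Gapped Karlin-Altschul parameters for these schemes:
# nucleotide lambda 0.625, K 0.410; protein lambda 0.267, K 0.041.
# ---------------------------------------------------------------------------

.nt_karlin <- list(lambda = 0.625, K = 0.410)
.aa_karlin <- list(lambda = 0.267, K = 0.041)

#' Alignment parameters
#'
#' Defaults follow the high-sensitivity pairwise settings: nucleotide word
#' size 4 and protein word size 2, with low-complexity masking (dust/seg)
#' disabled. Word size and masking only affect the external BLAST backend;
#' the internal engine is a full Smith-Waterman.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param word_size Seed word size for the external backend (default 4 for
#'   nucleotide, 2 for protein).
#' @param masking Enable low-complexity masking (default `FALSE`).
#' @param evalue_cutoff Report cutoff: alignments with E-value above this are
#'   not reported ("no hits"); default 10, the conventional BLAST default.
#'   The biological significance threshold of 0.001 is applied downstream as
#'   the `over_threshold` feature, not here.
#' @param max_dp_length Guard for the internal quadratic DP: sequences longer
#'   than this raise an error.
#' @return A list of class `align_params`.
#' @export
align_params <- function(mode = c("nucleotide", "protein"), word_size = NULL,
                         masking = FALSE, evalue_cutoff = 10,
                         max_dp_length = 20000L) {
  mode <- match.arg(mode)
  if (is.null(word_size)) word_size <- if (mode == "nucleotide") 4L else 2L
  structure(list(mode = mode, word_size = as.integer(word_size),
                 masking = isTRUE(masking),
                 evalue_cutoff = as.numeric(evalue_cutoff),
                 max_dp_length = as.integer(max_dp_length)),
            class = "align_params")
}

new_hsp <- function(score, num_identical, align_length, evalue,
                    start_a = NA_integer_, end_a = NA_integer_,
                    start_b = NA_integer_, end_b = NA_integer_) {
  list(score = score, num_identical = as.integer(num_identical),
       align_length = as.integer(align_length),
       identity_fraction = num_identical / align_length,
       evalue = evalue,
       start_a = start_a, end_a = end_a, start_b = start_b, end_b = end_b)
}

new_alignment_outcome <- function(hsps) {
  if (length(hsps) > 1L) {
    # ties broken by the leftmost start in either sequence, which keeps the
    # ordering invariant under swapping the pair
    ord <- order(vapply(hsps, `[[`, numeric(1L), "evalue"),
                 -vapply(hsps, `[[`, numeric(1L), "score"),
                 vapply(hsps, function(h)
                   min(h$start_a, h$start_b, na.rm = TRUE), numeric(1L)))
    hsps <- hsps[ord]
  }
  structure(list(has_hits = length(hsps) > 0L, hsps = hsps),
            class = "alignment_outcome")
}

#' @export
print.alignment_outcome <- function(x, ...) {
  if (!x$has_hits) {
    cat("<alignment_outcome> no hits\n")
  } else {
    cat("<alignment_outcome>", length(x$hsps), "HSP(s); best: identity",
        sprintf("%.3f", x$hsps[[1L]]$identity_fraction), "E-value",
        format(x$hsps[[1L]]$evalue, digits = 3), "\n")
  }
  invisible(x)
}

check_alphabet <- function(seq, mode, what) {
  if (!nzchar(seq)) stop(what, ": empty sequence", call. = FALSE)
  ok <- if (mode == "nucleotide") grepl("^[ACGTRYSWKMBDHVN]+$", seq)
        else grepl("^[A-Z*]+$", seq) && !grepl("[JOU]", seq)
  if (!ok) stop(what, ": sequence does not match ", mode, " alphabet",
                call. = FALSE)
  invisible(TRUE)
}

karlin_evalue <- function(score, m, n, mode) {
  p <- if (mode == "nucleotide") .nt_karlin else .aa_karlin
  p$K * m * n * exp(-p$lambda * score)
}

nt_matrix <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
      # masking character: "N" never aligns through a masked region
      m["N", ] <- -1000; m[, "N"] <- -1000
      cached <<- m
    }
    cached
  }
})

aa_matrix <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      m <- get_blosum62()
      m["X", ] <- -1000; m[, "X"] <- -1000
      cached <<- m
    }
    cached
  }
})

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Align a sequence pair
#'
#' Produces local-alignment statistics for a pair of nucleotide or protein
#' sequences. HSPs are ordered best-first (E-value ascending, score
#' descending, then leftmost start); `has_hits` is `FALSE` when no alignment
#' clears the report cutoff.
#'
#' @param seq_a,seq_b Sequences (character).
#' @param params An [align_params()] object.
#' @param backend `"internal"` (Smith-Waterman, default) or `"external"`
#'   (NCBI BLAST+ blastn/blastp on the PATH).
#' @param max_hsps Maximum number of HSPs to report (internal backend finds
#'   suboptimal HSPs by iterative masking).
#' @return An `alignment_outcome`: list with `has_hits` and `hsps`.
#' @export
#' @examples
#' out <- align_pair("ACGTACGTACGT", "ACGTACGTACGT", align_params())
#' out$hsps[[1]]$num_identical
align_pair <- function(seq_a, seq_b, params = align_params(),
                       backend = c("internal", "external"), max_hsps = 3L) {
  backend <- match.arg(backend)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  check_alphabet(seq_a, params$mode, "align_pair")
  check_alphabet(seq_b, params$mode, "align_pair")
  if (backend == "internal")
    internal_local_align(seq_a, seq_b, params, max_hsps = max_hsps)
  else
    external_local_align(seq_a, seq_b, params)
}

#' Internal Smith-Waterman local alignment
#'
#' Affine-gap local alignment with BLAST-compatible scoring (nucleotide:
#' match +2 / mismatch -3, gap open 5 / extend 2; protein: BLOSUM62, open
#' 11 / extend 1). E-values follow the Karlin-Altschul formula
#' \eqn{E = K m n e^{-\lambda S}} with the published gapped parameters for
#' these schemes. Suboptimal non-overlapping HSPs are found by iteratively
#' masking the best alignment's footprint in both sequences.
#'
#' @inheritParams align_pair
#' @return An `alignment_outcome`.
#' @export
internal_local_align <- function(seq_a, seq_b, params = align_params(),
                                 max_hsps = 3L) {
  if (nchar(seq_a) > params$max_dp_length || nchar(seq_b) > params$max_dp_length)
    stop("internal_local_align: sequence exceeds max_dp_length (",
         params$max_dp_length, ")", call. = FALSE)
  nt <- params$mode == "nucleotide"
  mat <- if (nt) nt_matrix() else aa_matrix()
  go <- if (nt) 5 else 11
  ge <- if (nt) 2 else 1
  mask_char <- if (nt) "N" else "X"
  # canonical argument order: the traceback among co-optimal alignments is
  # otherwise not guaranteed symmetric in (a, b)
  swapped <- seq_a > seq_b
  if (swapped) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  m <- nchar(seq_a); n <- nchar(seq_b)
  a <- seq_a; b <- seq_b
  hsps <- list()
  for (k in seq_len(max(1L, max_hsps))) {
    al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = go, gapExtension = ge)
    s <- Biostrings::score(al)
    if (s <= 0) break
    ev <- karlin_evalue(s, m, n, params$mode)
    if (ev > params$evalue_cutoff) break
    pat <- Biostrings::pattern(al)
    len <- nchar(as.character(Biostrings::alignedPattern(al)))
    hsps <- c(hsps, list(new_hsp(
      score = s, num_identical = Biostrings::nmatch(al), align_length = len,
      evalue = ev,
      start_a = Biostrings::start(pat), end_a = Biostrings::end(pat),
      start_b = Biostrings::start(Biostrings::subject(al)),
      end_b = Biostrings::end(Biostrings::subject(al)))))
    if (k == max_hsps) break
    sub <- Biostrings::subject(al)
    a <- mask_region(a, Biostrings::start(pat), Biostrings::end(pat), mask_char)
    b <- mask_region(b, Biostrings::start(sub), Biostrings::end(sub), mask_char)
  }
  if (swapped) {
    hsps <- lapply(hsps, function(h) {
      h[c("start_a", "end_a", "start_b", "end_b")] <-
        h[c("start_b", "end_b", "start_a", "end_a")]
      h
    })
  }
  new_alignment_outcome(hsps)
}

mask_region <- function(seq, from, to, char) {
  paste0(substr(seq, 1L, from - 1L), strrep(char, to - from + 1L),
         substr(seq, to + 1L, nchar(seq)))
}

# ----------------------------- external backend ----------------------------

#' External BLAST+ pairwise alignment
#'
#' Calls `blastn`/`blastp` with a `-subject` file (the bl2seq idiom), dust or
#' seg masking disabled unless requested, and the configured word size,
#' requesting tabular output which is parsed with [parse_blast_tabular()].
#'
#' @inheritParams align_pair
#' @return An `alignment_outcome`.
#' @export
external_local_align <- function(seq_a, seq_b, params = align_params()) {
  nt <- params$mode == "nucleotide"
  exe <- if (nt) "blastn" else "blastp"
  if (!nzchar(Sys.which(exe)))
    stop("external alignment backend unavailable: '", exe,
         "' not found on PATH", call. = FALSE)
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  writeLines(c(">q", seq_a), qf)
  writeLines(c(">s", seq_b), sf)
  args <- c("-query", qf, "-subject", sf,
            "-word_size", params$word_size,
            "-evalue", format(params$evalue_cutoff),
            "-outfmt", shQuote("6 nident length pident evalue score qstart qend sstart send"))
  if (nt) {
    args <- c(args, "-reward", "2", "-penalty", "-3",
              "-gapopen", "5", "-gapextend", "2",
              "-dust", if (params$masking) "yes" else "no")
  } else {
    args <- c(args, "-seg", if (params$masking) "yes" else "no")
  }
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("external alignment backend failed (", exe, " exit ", status, ")",
         call. = FALSE)
  parse_blast_tabular(out)
}

#' Parse tabular BLAST output
#'
#' Parses tabular (`-outfmt 6`) pairwise alignment reports with columns
#' `nident length pident evalue score qstart qend sstart send` (the format
#' requested by [external_local_align()]). An empty body means no hits.
#'
#' @param text Character vector of tabular lines.
#' @param columns Column names, in file order.
#' @return An `alignment_outcome`.
#' @export
parse_blast_tabular <- function(text,
                                columns = c("nident", "length", "pident",
                                            "evalue", "score", "qstart",
                                            "qend", "sstart", "send")) {
  text <- text[nzchar(trimws(text)) & !startsWith(trimws(text), "#")]
  if (length(text) == 0L) return(new_alignment_outcome(list()))
  hsps <- vector("list", length(text))
  for (i in seq_along(text)) {
    parts <- strsplit(trimws(text[i]), "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- strsplit(trimws(text[i]), "\\s+")[[1L]]
    if (length(parts) < length(columns))
      stop("parse_blast_tabular: unparseable line ", i, ": '",
           text[i], "'", call. = FALSE)
    v <- suppressWarnings(as.numeric(parts[seq_along(columns)]))
    if (anyNA(v))
      stop("parse_blast_tabular: non-numeric field on line ", i, call. = FALSE)
    names(v) <- columns
    hsps[[i]] <- new_hsp(score = v[["score"]],
                         num_identical = v[["nident"]],
                         align_length = v[["length"]],
                         evalue = v[["evalue"]],
                         start_a = v[["qstart"]], end_a = v[["qend"]],
                         start_b = v[["sstart"]], end_b = v[["send"]])
  }
  new_alignment_outcome(hsps)
}
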