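# ---------------------------------------------------------------------------
# Record model: a nucleotide database record as consumed by the feature
# extractor. Coordinates are 0-based half-open internally; the GenBank
# 1-based inclusive convention is converted at the parser/writer boundary.
# ---------------------------------------------------------------------------

#' Normalize an author name
#'
#' Lowercases, strips whitespace and punctuation other than the
#' `surname,i.` separator characters, yielding a canonical form suitable
#' for set comparison of author names.
#'
#' @param x Character vector of author names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_author(c("Smith, J.", "LEE,K."))
normalize_author <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", "", x)
  gsub("[^a-z0-9,.-]", "", x)
}

#' Construct a literature reference
#'
#' One REFERENCE entry of a record. Direct-submission entries (the special
#' "Direct Submission" label) carry the submitters of the record and are
#' excluded from literature comparison.
#'
#' @param authors Character vector of author names (normalized on
#'   construction).
#' @param title Reference title, or `NULL`.
#' @param journal Journal line, or `NULL`.
#' @param pubmed_id PubMed identifier as a string, or `NULL`.
#' @param direct_submission Logical; is this a direct-submission entry?
#' @return An object of class `gb_reference`.
#' @export
gb_reference <- function(authors = character(), title = NULL, journal = NULL,
                         pubmed_id = NULL, direct_submission = FALSE) {
  authors <- normalize_author(as.character(authors))
  authors <- authors[nzchar(authors)]
  if (!direct_submission &&
      is.null(pubmed_id) && is.null(journal) && is.null(title) &&
      length(authors) == 0L) {
    stop("gb_reference: at least one of pubmed_id, journal, title, authors ",
         "must be populated", call. = FALSE)
  }
  structure(
    list(authors = authors, title = title, journal = journal,
         pubmed_id = if (is.null(pubmed_id)) NULL else as.character(pubmed_id),
         direct_submission = isTRUE(direct_submission)),
    class = "gb_reference"
  )
}

#' Construct a coding-sequence region
#'
#' @param start,end 0-based half-open coordinates on the record sequence.
#' @param nucleotide_seq Nucleotide sequence of the region. When `NULL` it is
#'   sliced from `sequence`.
#' @param translation Amino-acid translation, or `NULL` when the record does
#'   not carry one.
#' @param sequence Full record sequence used to slice/validate simple spans.
#' @param location Original GenBank location string (kept for joined or
#'   complement locations whose extracted sequence is not the raw slice).
#' @return An object of class `gb_cds`.
#' @export
gb_cds <- function(start, end, nucleotide_seq = NULL, translation = NULL,
                   sequence = NULL, location = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("gb_cds: need 0 <= start < end", call. = FALSE)
  if (!is.null(sequence) && end > nchar(sequence))
    stop("gb_cds: end beyond record length", call. = FALSE)
  if (is.null(nucleotide_seq)) {
    if (is.null(sequence)) stop("gb_cds: need nucleotide_seq or sequence")
    nucleotide_seq <- substr(sequence, start + 1L, end)
  }
  structure(
    list(start = start, end = end,
         nucleotide_seq = toupper(nucleotide_seq),
         translation = if (is.null(translation)) NULL else toupper(translation),
         location = location),
    class = "gb_cds"
  )
}

#' Construct a sequence record
#'
#' The in-memory model of one nucleotide database record: description
#' (DEFINITION), literature references and submitters (REFERENCE), sequence
#' (ORIGIN), and coding regions with translations (CDS features).
#'
#' @param accession Accession string (non-empty).
#' @param sequence Nucleotide sequence (non-empty; uppercased).
#' @param organism Organism name.
#' @param description Free-text description (DEFINITION field).
#' @param references List of [gb_reference()] objects, in record order.
#' @param submitters Character vector of submitter names, or `NULL` when the
#'   record provides none (direct-submission reference absent).
#' @param cds List of [gb_cds()] objects, in record order.
#' @return An object of class `gb_record`.
#' @export
gb_record <- function(accession, sequence, organism = "synthetic construct",
                      description = "", references = list(),
                      submitters = NULL, cds = list()) {
  accession <- as.character(accession)
  if (!nzchar(accession)) stop("gb_record: accession must be non-empty")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("gb_record: sequence must be non-empty")
  if (!is.null(submitters)) {
    submitters <- normalize_author(submitters)
    submitters <- submitters[nzchar(submitters)]
  }
  structure(
    list(accession = accession, organism = as.character(organism),
         description = as.character(description),
         references = references, submitters = submitters,
         sequence = sequence, cds = cds),
    class = "gb_record"
  )
}

#' @export
print.gb_record <- function(x, ...) {
  cat("<gb_record>", x$accession, "|", x$organism, "\n")
  cat("  ", substr(x$description, 1, 60), "\n")
  cat("  ", nchar(x$sequence), "bp;", length(x$cds), "CDS;",
      length(x$references), "reference(s);",
      if (is.null(x$submitters)) "submitters n/a"
      else paste(length(x$submitters), "submitter(s)"), "\n")
  invisible(x)
}

#' First coding region of a record
#'
#' Records may carry several CDS features; only the first one (and its
#' translation) enters the pairwise feature representation.
#'
#' @param record A [gb_record()].
#' @return `NULL` when the record has no CDS, otherwise a list with
#'   `nucleotide_seq` and `translation` (`NULL` when absent).
#' @export
first_cds <- function(record) {
  if (length(record$cds) == 0L) return(NULL)
  x <- record$cds[[1L]]
  list(nucleotide_seq = x$nucleotide_seq, translation = x$translation)
}

#' Literature (non-direct-submission) references of a record
#'
#' @param record A [gb_record()].
#' @return List of `gb_reference` objects excluding direct-submission
#'   entries.
#' @export
literature_refs <- function(record) {
  Filter(function(r) !isTRUE(r$direct_submission), record$references)
}

# --------------------------- location handling -----------------------------

reverse_complement <- function(seq) {
  x <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Parse a GenBank location string: simple spans, join(), order(), and an
# outer complement(). Returns 1-based inclusive interval matrix plus strand.
parse_location <- function(loc) {
  loc <- gsub("[ <>]", "", loc)
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else {
      ab <- rep(as.integer(p), 2L)
    }
    if (anyNA(ab) || ab[1L] > ab[2L])
      stop("unparseable location segment: ", p, call. = FALSE)
    ab
  }, integer(2L)))
  list(intervals = unname(iv), complement = complement)
}

extract_location_seq <- function(sequence, loc) {
  pieces <- apply(loc$intervals, 1L, function(ab)
    substr(sequence, ab[1L], ab[2L]))
  out <- paste(pieces, collapse = "")
  if (loc$complement) out <- reverse_complement(out)
  out
}

# ------------------------------- parsing -----------------------------------

#' Parse GenBank flat-file records
#'
#' Reads the GenBank flat-file dialect (`LOCUS` ... `//` blocks) into
#' [gb_record()] objects. DEFINITION, ACCESSION, SOURCE/ORGANISM, REFERENCE
#' (with AUTHORS/TITLE/JOURNAL/PUBMED), CDS features with `/translation`,
#' and the ORIGIN sequence are retained; submitters are taken from
#' references labelled "Direct Submission". Records without an ORIGIN
#' sequence are rejected.
#'
#' @param file Path to a GenBank flat file, or `NULL` when `text` is given.
#' @param text Character vector of lines (alternative to `file`).
#' @return List of [gb_record()] objects (empty list for empty input).
#' @export
parse_genbank <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("parse_genbank: give file or text")
    text <- readLines(file, warn = FALSE)
  }
  text <- text[!(seq_along(text) == length(text) & text == "")]
  if (length(text) == 0L || all(!nzchar(trimws(text)))) return(list())
  ends <- grep("^//", text)
  if (length(ends) == 0L)
    stop("malformed GenBank input: no record terminator '//'", call. = FALSE)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    block <- text[starts[i]:(ends[i] - 1L)]
    block <- block[nzchar(trimws(block)) | grepl("^ORIGIN", block)]
    if (length(block)) records[[i]] <- parse_genbank_block(block)
  }
  Filter(Negate(is.null), records)
}

is_toplevel <- function(line) nzchar(line) && substr(line, 1L, 1L) != " "

field_text <- function(lines) {
  trimws(paste(trimws(substring(lines, 13L)), collapse = " "))
}

parse_genbank_block <- function(lines) {
  kw_idx <- which(vapply(lines, is_toplevel, logical(1L)))
  kws <- vapply(kw_idx, function(i)
    trimws(substr(lines[i], 1L, 12L)), character(1L))
  ident <- if (length(kw_idx)) sub("^LOCUS\\s+(\\S+).*", "\\1", lines[1L])
           else "<unnamed>"
  if (!("LOCUS" %in% kws) || !("ORIGIN" %in% kws))
    stop("malformed GenBank block (missing LOCUS or ORIGIN) near '",
         substr(lines[1L], 1L, 40L), "'", call. = FALSE)

  span <- function(j) {           # lines of the j-th top-level field
    from <- kw_idx[j]
    to <- if (j < length(kw_idx)) kw_idx[j + 1L] - 1L else length(lines)
    lines[from:to]
  }

  accession <- NULL; description <- ""; organism <- ""
  references <- list(); cds <- list(); sequence <- NULL
  for (j in seq_along(kw_idx)) {
    kw <- kws[j]
    fl <- span(j)
    if (kw == "DEFINITION") {
      description <- sub("\\.$", "", field_text(fl))
    } else if (kw == "ACCESSION") {
      accession <- strsplit(field_text(fl), "\\s+")[[1L]][1L]
    } else if (kw == "SOURCE") {
      org <- grep("^  ORGANISM", fl)
      if (length(org))
        organism <- trimws(substring(fl[org[1L]], 13L))
    } else if (kw == "REFERENCE") {
      references <- c(references, list(parse_reference(fl)))
    } else if (kw == "FEATURES") {
      cds <- parse_cds_features(fl)
    } else if (kw == "ORIGIN") {
      seqlines <- fl[-1L]
      sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    }
  }
  if (is.null(accession)) accession <- ident
  if (is.null(sequence) || !nzchar(sequence))
    stop("malformed GenBank block (empty ORIGIN) in record '", accession, "'",
         call. = FALSE)

  submitters <- NULL
  for (r in references) {
    if (isTRUE(r$direct_submission))
      submitters <- union(submitters, r$authors)
  }
  cds_objs <- lapply(cds, function(x) {
    loc <- parse_location(x$location)
    start0 <- min(loc$intervals[, 1L]) - 1L
    end0 <- max(loc$intervals[, 2L])
    simple <- nrow(loc$intervals) == 1L && !loc$complement
    gb_cds(start = start0, end = end0,
           nucleotide_seq = extract_location_seq(sequence, loc),
           translation = x$translation,
           location = if (simple) NULL else x$location)
  })
  gb_record(accession = accession, sequence = sequence, organism = organism,
            description = description, references = references,
            submitters = submitters, cds = cds_objs)
}

parse_reference <- function(fl) {
  sub_idx <- which(grepl("^\\s{1,4}\\S", fl))
  sub_kws <- trimws(substr(fl[sub_idx], 1L, 12L))
  get <- function(kw) {
    j <- which(sub_kws == kw)
    if (!length(j)) return(NULL)
    from <- sub_idx[j[1L]]
    nxt <- sub_idx[sub_idx > from]
    to <- if (length(nxt)) nxt[1L] - 1L else length(fl)
    field_text(fl[from:to])
  }
  authors_raw <- get("AUTHORS")
  authors <- character()
  if (!is.null(authors_raw)) {
    a <- gsub(" and ", ", ", authors_raw, fixed = TRUE)
    authors <- trimws(strsplit(a, ",\\s+")[[1L]])
  }
  title <- get("TITLE"); journal <- get("JOURNAL"); pubmed <- get("PUBMED")
  direct <- identical(title, "Direct Submission") ||
    (!is.null(journal) && startsWith(journal, "Submitted"))
  gb_reference(authors = authors, title = title, journal = journal,
               pubmed_id = pubmed, direct_submission = direct)
}

parse_cds_features <- function(fl) {
  out <- list()
  i <- 2L
  n <- length(fl)
  while (i <= n) {
    key <- trimws(substr(fl[i], 1L, 20L))
    if (key == "CDS") {
      loc <- trimws(substring(fl[i], 21L))
      i <- i + 1L
      # location may continue across lines until the first qualifier
      while (i <= n && !grepl("^\\s{21}/", fl[i]) &&
             !nzchar(trimws(substr(fl[i], 1L, 20L)))) {
        loc <- paste0(loc, trimws(fl[i]))
        i <- i + 1L
      }
      translation <- NULL
      while (i <= n && !nzchar(trimws(substr(fl[i], 1L, 20L)))) {
        q <- trimws(fl[i])
        if (startsWith(q, "/translation=")) {
          tr <- sub("^/translation=\"", "", q)
          while (!grepl("\"$", tr) && i < n) {
            i <- i + 1L
            tr <- paste0(tr, trimws(fl[i]))
          }
          translation <- sub("\"$", "", tr)
        }
        i <- i + 1L
      }
      out <- c(out, list(list(location = loc, translation = translation)))
    } else {
      i <- i + 1L
    }
  }
  out
}

# ------------------------------- writing -----------------------------------

wrap_field <- function(keyword, value, width = 79L) {
  body <- strwrap(value, width = width - 12L)
  if (length(body) == 0L) body <- ""
  first <- sprintf("%-12s%s", keyword, body[1L])
  rest <- if (length(body) > 1L) paste0(strrep(" ", 12L), body[-1L])
  c(first, rest)
}

format_authors <- function(authors) paste(authors, collapse = ", ")

#' Write records as a GenBank flat file
#'
#' Inverse of [parse_genbank()] for the fields the record model retains;
#' `parse_genbank(write_genbank(x))` round-trips all modelled fields.
#'
#' @param records A `gb_record` or list of them.
#' @param file Output path, or `NULL` to return the lines invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_genbank <- function(records, file = NULL) {
  if (inherits(records, "gb_record")) records <- list(records)
  lines <- as.character(unlist(lapply(records, format_genbank_record),
                               use.names = FALSE))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

format_genbank_record <- function(r) {
  out <- character()
  out <- c(out, sprintf("LOCUS       %-16s%12d bp    DNA     linear   SYN 01-JAN-2026",
                        r$accession, nchar(r$sequence)))
  out <- c(out, wrap_field("DEFINITION", paste0(r$description, ".")))
  out <- c(out, sprintf("%-12s%s", "ACCESSION", r$accession))
  out <- c(out, sprintf("%-12s%s", "SOURCE", r$organism))
  out <- c(out, sprintf("  %-10s%s", "ORGANISM", r$organism))
  for (k in seq_along(r$references)) {
    ref <- r$references[[k]]
    out <- c(out, sprintf("%-12s%d", "REFERENCE", k))
    if (length(ref$authors))
      out <- c(out, wrap_field("  AUTHORS", format_authors(ref$authors)))
    if (!is.null(ref$title))
      out <- c(out, wrap_field("  TITLE", ref$title))
    if (!is.null(ref$journal))
      out <- c(out, wrap_field("  JOURNAL", ref$journal))
    if (!is.null(ref$pubmed_id))
      out <- c(out, sprintf("   %-9s%s", "PUBMED", ref$pubmed_id))
  }
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     %-16s%s", "source",
                        paste0("1..", nchar(r$sequence))))
  out <- c(out, sprintf("%s/organism=\"%s\"", strrep(" ", 21L), r$organism))
  for (x in r$cds) {
    loc <- if (!is.null(x$location)) x$location
           else paste0(x$start + 1L, "..", x$end)
    out <- c(out, sprintf("     %-16s%s", "CDS", loc))
    if (!is.null(x$translation)) {
      tr <- paste0("/translation=\"", x$translation, "\"")
      chunks <- substring(tr, seq(1L, nchar(tr), 58L),
                          pmin(seq(1L, nchar(tr), 58L) + 57L, nchar(tr)))
      out <- c(out, paste0(strrep(" ", 21L), chunks))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(r$sequence)
  pos <- seq(1L, nchar(s), 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  c(out, "//")
}

#' Read a pair-label file
#'
#' Tab-separated file with columns `accession_a`, `accession_b`,
#' `label` (`DU`/`DI`) and optional `subtype` (`ES`/`EF`/`NS`).
#'
#' @param file Path to the TSV.
#' @return Tibble of pair labels.
#' @export
read_pair_labels <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  need <- c("accession_a", "accession_b", "label")
  if (!all(need %in% names(df)))
    stop("pair-label file must have columns accession_a, accession_b, label")
  bad <- setdiff(unique(df$label), c("DU", "DI"))
  if (length(bad)) stop("unknown pair labels: ", paste(bad, collapse = ", "))
  tibble::as_tibble(df)
}
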