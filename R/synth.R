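# ---------------------------------------------------------------------------
# Seeded generator of GenBank-format record pairs with known binary and
# subtype labels. Pair classes:
#   ES      copy + point substitutions, metadata highly shared
#   EF      one record is a contiguous fragment of the other
#   NS      independent sequences, metadata highly shared (duplicates
#           detectable only through metadata)
#   DI      two independent records
#   DI_hard near-identical sequences with disjoint metadata (the
#           "similar coding sequences but different proteins" phenomenon)
# ---------------------------------------------------------------------------

#' Synthetic corpus configuration
#'
#' Defaults describe a realistic mixed corpus: sequences of a few hundred
#' to ~1.5 kb, ES duplicates at 0.5% substitutions/site, EF fragments
#' covering 30-70% of the parent, and metadata sharing probabilities high
#' for duplicates. `DU` and `DI` counts are balanced when
#' `ES + EF + NS == DI + DI_hard`.
#'
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration.
#' @param n_pairs Named integer vector with entries `ES`, `EF`, `NS`, `DI`,
#'   `DI_hard`.
#' @param length_range Sequence length bounds (bases).
#' @param es_mutation_rate Substitutions/site for ES (and NS-metadata)
#'   copies.
#' @param ef_fragment_range Fragment fraction bounds for EF, in (0, 1).
#' @param ef_mutation_rate Substitutions/site applied to EF fragments.
#' @param di_hard_mutation_rate Substitutions/site for DI_hard sequence
#'   copies.
#' @param p_shared_pmid Probability a duplicate pair shares its literature
#'   reference (same PubMed ID).
#' @param p_shared_submitter Probability a duplicate pair shares its
#'   submitter set.
#' @param desc_keep Per-token retention probability when deriving a
#'   duplicate's description from its partner.
#' @param p_cds Probability a record carries a CDS.
#' @param p_translation Probability a CDS carries a translation.
#' @param p_literature Probability a record has a literature reference.
#' @param p_direct_submission Probability a record has a direct-submission
#'   reference (and therefore submitter information).
#' @param vocab_size Description vocabulary size.
#' @param di_max_length_ratio When set (in (0, 1)), `DI` pairs are redrawn
#'   until their length ratio is at most this value — used by the separable
#'   fixture so distinct pairs are separable in every feature view.
#' @param organism Organism name written into the records.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_pairs = c(ES = 50L, EF = 50L, NS = 25L,
                                     DI = 100L, DI_hard = 25L),
                         length_range = c(300L, 1500L),
                         es_mutation_rate = 0.005,
                         ef_fragment_range = c(0.3, 0.7),
                         ef_mutation_rate = 0.005,
                         di_hard_mutation_rate = 0.002,
                         p_shared_pmid = 0.8,
                         p_shared_submitter = 0.85,
                         desc_keep = 0.85,
                         p_cds = 0.85,
                         p_translation = 0.9,
                         p_literature = 0.85,
                         p_direct_submission = 0.9,
                         vocab_size = 120L,
                         di_max_length_ratio = NULL,
                         organism = "synthetic construct") {
  full <- c(ES = 0L, EF = 0L, NS = 0L, DI = 0L, DI_hard = 0L)
  n_pairs <- as.integer(n_pairs)[match(names(full), names(n_pairs))]
  n_pairs[is.na(n_pairs)] <- 0L
  names(n_pairs) <- names(full)
  probs <- c(p_shared_pmid, p_shared_submitter, desc_keep, p_cds,
             p_translation, p_literature, p_direct_submission)
  if (any(probs < 0 | probs > 1))
    stop("synth_config: probabilities must be in [0, 1]", call. = FALSE)
  if (any(n_pairs < 0)) stop("synth_config: n_pairs must be >= 0")
  if (ef_fragment_range[1] <= 0 || ef_fragment_range[2] >= 1 ||
      ef_fragment_range[1] > ef_fragment_range[2])
    stop("synth_config: ef_fragment_range must lie inside (0, 1)")
  if (length_range[1] < 150L || length_range[1] > length_range[2])
    stop("synth_config: length_range must be increasing and >= 150")
  structure(list(seed = as.integer(seed), n_pairs = n_pairs,
                 length_range = as.integer(length_range),
                 es_mutation_rate = es_mutation_rate,
                 ef_fragment_range = ef_fragment_range,
                 ef_mutation_rate = ef_mutation_rate,
                 di_hard_mutation_rate = di_hard_mutation_rate,
                 p_shared_pmid = p_shared_pmid,
                 p_shared_submitter = p_shared_submitter,
                 desc_keep = desc_keep, p_cds = p_cds,
                 p_translation = p_translation,
                 p_literature = p_literature,
                 p_direct_submission = p_direct_submission,
                 vocab_size = as.integer(vocab_size),
                 di_max_length_ratio = di_max_length_ratio,
                 organism = organism),
            class = "synth_config")
}

rand_word <- function(min_len = 3L, max_len = 8L) {
  n <- sample(min_len:max_len, 1L)
  cons <- c("b","c","d","f","g","h","k","l","m","n","p","r","s","t","v","z")
  vow <- c("a","e","i","o","u")
  paste0(vapply(seq_len(n), function(i)
    if (i %% 2L == 1L) sample(cons, 1L) else sample(vow, 1L),
    character(1L)), collapse = "")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

non_stop_codons <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      all <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                               c("A","C","G","T")), 1L, paste, collapse = "")
      cached <<- setdiff(all, c("TAA", "TAG", "TGA"))
    }
    cached
  }
})

translate_cds <- function(cds_seq) {
  # translation excludes the stop codon, per the flat-file convention
  body <- substr(cds_seq, 1L, nchar(cds_seq) - 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(body)))
}

# environment holding the generator state while a corpus is built
synth_env <- function(cfg) {
  e <- new.env()
  e$cfg <- cfg
  e$vocab <- replicate(cfg$vocab_size, rand_word())
  e$authors <- replicate(60L, paste0(rand_word(4L, 8L), ",",
                                     sample(letters, 1L), "."))
  e$journals <- replicate(12L, paste0("j. ", rand_word(), " ", rand_word()))
  e$acc_counter <- 0L
  e
}

next_accession <- function(e) {
  # seed-prefixed so corpora generated with different seeds never share
  # accessions (e.g. in generalisation sweeps)
  e$acc_counter <- e$acc_counter + 1L
  sprintf("S%03d%06d", e$cfg$seed %% 1000L, e$acc_counter)
}

make_literature_ref <- function(e) {
  authors <- sample(e$authors, sample(2:4, 1L))
  has_pmid <- runif(1L) < 0.7
  gb_reference(
    authors = authors,
    title = paste(replicate(sample(4:7, 1L), sample(e$vocab, 1L)),
                  collapse = " "),
    journal = paste0(sample(e$journals, 1L), " ", sample(1:40, 1L), " (",
                     sample(1:12, 1L), "), ", sample(1:800, 1L), " (",
                     sample(1995:2015, 1L), ")"),
    pubmed_id = if (has_pmid) as.character(1000000L + sample.int(8999999L, 1L))
                else NULL)
}

make_submission_ref <- function(e, authors = NULL) {
  if (is.null(authors)) authors <- sample(e$authors, sample(1:3, 1L))
  gb_reference(authors = authors, title = "Direct Submission",
               journal = "Submitted (01-JAN-2015) Synthetic Institute",
               direct_submission = TRUE)
}

place_cds <- function(sequence, e) {
  len <- nchar(sequence)
  n_codons <- sample(40:90, 1L)
  cds_len <- 3L * (n_codons + 2L)
  if (cds_len + 6L >= len) {
    n_codons <- max(10L, (len - 12L) %/% 3L - 2L)
    cds_len <- 3L * (n_codons + 2L)
  }
  start0 <- sample(0:(len - cds_len), 1L)
  orf <- paste0("ATG",
                paste(sample(non_stop_codons(), n_codons, TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  sequence <- paste0(substr(sequence, 1L, start0),
                     orf,
                     substr(sequence, start0 + cds_len + 1L, len))
  list(sequence = sequence, start = start0, end = start0 + cds_len)
}

make_base_record <- function(e) {
  cfg <- e$cfg
  len <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
  sequence <- rand_seq(len)
  cds <- list()
  if (runif(1L) < cfg$p_cds) {
    placed <- place_cds(sequence, e)
    sequence <- placed$sequence
    cds_seq <- substr(sequence, placed$start + 1L, placed$end)
    translation <- if (runif(1L) < cfg$p_translation) translate_cds(cds_seq)
                   else NULL
    cds <- list(gb_cds(placed$start, placed$end, sequence = sequence,
                       translation = translation))
  }
  refs <- list()
  if (runif(1L) < cfg$p_literature)
    refs <- c(refs, list(make_literature_ref(e)))
  submitters <- NULL
  if (runif(1L) < cfg$p_direct_submission) {
    sub_ref <- make_submission_ref(e)
    refs <- c(refs, list(sub_ref))
    submitters <- sub_ref$authors
  }
  gb_record(accession = next_accession(e), sequence = sequence,
            organism = cfg$organism,
            description = paste(sample(e$vocab, sample(4:8, 1L)),
                                collapse = " "),
            references = refs, submitters = submitters, cds = cds)
}

# rebuild CDS annotation after sequence editing: coordinates kept, slice
# and translation recomputed from the edited sequence
refresh_cds <- function(cds, sequence) {
  lapply(cds, function(x) {
    gb_cds(x$start, x$end, sequence = sequence,
           translation = if (is.null(x$translation)) NULL else
             translate_cds(substr(sequence, x$start + 1L, x$end)))
  })
}

# derive a duplicate partner's metadata from the source record
shared_metadata <- function(rec, e) {
  cfg <- e$cfg
  toks <- strsplit(rec$description, " ", fixed = TRUE)[[1L]]
  keep <- toks[runif(length(toks)) < cfg$desc_keep]
  extra <- sample(e$vocab, sample(0:2, 1L))
  desc <- paste(unique(c(keep, extra)), collapse = " ")
  if (!nzchar(desc)) desc <- paste(sample(e$vocab, 3L), collapse = " ")
  lit <- Filter(function(r) !isTRUE(r$direct_submission), rec$references)
  refs <- list()
  if (length(lit)) {
    refs <- if (runif(1L) < cfg$p_shared_pmid) lit[1L]
            else list(make_literature_ref(e))
  } else if (runif(1L) < cfg$p_literature) {
    refs <- list(make_literature_ref(e))
  }
  submitters <- NULL
  if (!is.null(rec$submitters) && runif(1L) < cfg$p_shared_submitter) {
    sub_ref <- make_submission_ref(e, authors = rec$submitters)
    refs <- c(refs, list(sub_ref)); submitters <- sub_ref$authors
  } else if (runif(1L) < cfg$p_direct_submission) {
    sub_ref <- make_submission_ref(e)
    refs <- c(refs, list(sub_ref)); submitters <- sub_ref$authors
  }
  list(description = desc, references = refs, submitters = submitters)
}

make_pair <- function(class, e) {
  cfg <- e$cfg
  a <- make_base_record(e)
  if (class == "ES") {
    meta <- shared_metadata(a, e)
    seq_b <- mutate_seq(a$sequence, cfg$es_mutation_rate)
    b <- gb_record(next_accession(e), seq_b, organism = cfg$organism,
                   description = meta$description,
                   references = meta$references,
                   submitters = meta$submitters,
                   cds = refresh_cds(a$cds, seq_b))
  } else if (class == "EF") {
    meta <- shared_metadata(a, e)
    frac <- runif(1L, cfg$ef_fragment_range[1L], cfg$ef_fragment_range[2L])
    len <- nchar(a$sequence)
    flen <- max(100L, round(frac * len))
    # keep the first CDS inside the fragment when it fits
    lo <- 0L; hi <- len - flen
    if (length(a$cds)) {
      x <- a$cds[[1L]]
      if (x$end - x$start <= flen) {
        lo <- max(0L, x$end - flen); hi <- min(hi, x$start)
        if (lo > hi) { lo <- 0L; hi <- len - flen }
      }
    }
    off <- if (hi > lo) sample(lo:hi, 1L) else lo
    seq_b <- mutate_seq(substr(a$sequence, off + 1L, off + flen),
                        cfg$ef_mutation_rate)
    cds_b <- list()
    if (length(a$cds)) {
      x <- a$cds[[1L]]
      if (x$start >= off && x$end <= off + flen) {
        cds_b <- refresh_cds(list(gb_cds(x$start - off, x$end - off,
                                         sequence = seq_b,
                                         translation = x$translation)),
                             seq_b)
      }
    }
    b <- gb_record(next_accession(e), seq_b, organism = cfg$organism,
                   description = meta$description,
                   references = meta$references,
                   submitters = meta$submitters, cds = cds_b)
  } else if (class == "NS") {
    meta <- shared_metadata(a, e)
    tmp <- make_base_record(e)   # independent sequence and CDS
    b <- gb_record(tmp$accession, tmp$sequence, organism = cfg$organism,
                   description = meta$description,
                   references = meta$references,
                   submitters = meta$submitters, cds = tmp$cds)
  } else if (class == "DI") {
    b <- make_base_record(e)
    if (!is.null(cfg$di_max_length_ratio)) {
      for (try in 1:50) {
        if (length_ratio(nchar(a$sequence), nchar(b$sequence)) <=
            cfg$di_max_length_ratio) break
        b <- make_base_record(e)
      }
    }
  } else {  # DI_hard: near-identical sequence, disjoint metadata
    seq_b <- mutate_seq(a$sequence, cfg$di_hard_mutation_rate)
    tmp <- make_base_record(e)   # donor of independent metadata
    b <- gb_record(tmp$accession, seq_b, organism = cfg$organism,
                   description = tmp$description,
                   references = tmp$references,
                   submitters = tmp$submitters,
                   cds = refresh_cds(a$cds, seq_b))
  }
  list(a = a, b = b)
}

#' Generate a labelled synthetic corpus
#'
#' Produces GenBank-style records and labelled pairs for the configured
#' class counts. The corpus is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return List of class `synth_corpus`: `records` (named list of
#'   [gb_record()]), `pairs` (tibble: accession_a, accession_b, label,
#'   subtype, class), `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  e <- synth_env(config)
  classes <- rep(names(config$n_pairs), config$n_pairs)
  records <- list()
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    pr <- make_pair(cl, e)
    records[[pr$a$accession]] <- pr$a
    records[[pr$b$accession]] <- pr$b
    rows[[i]] <- tibble::tibble(
      accession_a = pr$a$accession, accession_b = pr$b$accession,
      label = if (cl %in% c("DI", "DI_hard")) "DI" else "DU",
      subtype = if (cl %in% c("DI", "DI_hard")) NA_character_ else cl,
      class = cl)
  }
  structure(list(records = records, pairs = dplyr::bind_rows(rows),
                 config = config),
            class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus>", length(x$records), "records,", nrow(x$pairs),
      "pairs (seed", x$config$seed, ")\n")
  print(table(x$pairs$class))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes `records.gb` (GenBank flat file), `labels.tsv` (pair-label file),
#' `ground_truth.tsv` (labels plus generator class) and `config.json`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(unname(corpus$records), file.path(dir, "records.gb"))
  labs <- corpus$pairs[c("accession_a", "accession_b", "label", "subtype")]
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(corpus$pairs, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  cfg <- corpus$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a cleanly separable labelled corpus
#'
#' Sanity fixture for classifiers: half `ES` duplicates generated at zero
#' mutation rate with fully shared metadata, half `DI` pairs with
#' independent sequences and metadata. The classes are separable in
#' feature space by construction.
#'
#' @param n Total number of pairs (>= 100; split evenly).
#' @param seed Seed.
#' @param length_range Sequence length bounds.
#' @return A `synth_corpus`.
#' @export
generate_separable_set <- function(n = 200L, seed = 1L,
                                   length_range = c(300L, 600L)) {
  if (n < 100L) stop("generate_separable_set: n must be >= 100")
  half <- n %/% 2L
  cfg <- synth_config(seed = seed,
                      n_pairs = c(ES = half, EF = 0L, NS = 0L,
                                  DI = n - half, DI_hard = 0L),
                      length_range = length_range,
                      es_mutation_rate = 0,
                      p_shared_pmid = 1, p_shared_submitter = 1,
                      desc_keep = 1, di_max_length_ratio = 0.8)
  generate_corpus(cfg)
}
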