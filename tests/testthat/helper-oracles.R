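# Independent oracles used across the suite. These re-derive expected
# values by brute force and must stay independent of the package internals
# they check.

# Naive affine-gap Smith-Waterman: O(mn) dynamic programme with explicit
# traceback. Gap of length g costs open + g * ext.
sw_naive <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)   # gap in A (consume B)
  F <- matrix(NEG, m + 1, n + 1)   # gap in B (consume A)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  best <- max(H)
  idx <- which(H == best, arr.ind = TRUE)[1, ]
  # traceback counting identities, preferring the diagonal on ties
  i <- idx[1]; j <- idx[2]
  ident <- 0L; len <- 0L
  state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      if (H[i, j] == H[i - 1, j - 1] + s) {
        if (A[i - 1] == B[j - 1]) ident <- ident + 1L
        len <- len + 1L
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      len <- len + 1L
      if (E[i, j] == H[i, j - 1] - open - ext) state <- "H"
      j <- j - 1
    } else {
      len <- len + 1L
      if (F[i, j] == H[i - 1, j] - open - ext) state <- "H"
      i <- i - 1
    }
  }
  list(score = best, num_identical = ident, align_length = len)
}

# AUROC by exhaustive enumeration of positive/negative pairs (ties 0.5)
auroc_naive <- function(truth01, score) {
  pos <- score[truth01 == 1]; neg <- score[truth01 == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Shared fixture cache: expensive corpora are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_mixed_corpus <- function() {
  fixture("small_mixed", function() {
    corp <- generate_corpus(synth_config(
      seed = 42L, n_pairs = c(ES = 10L, EF = 10L, NS = 5L, DI = 15L,
                              DI_hard = 5L),
      length_range = c(300L, 600L)))
    feats <- compute_feature_matrix(corp$pairs, corp$records)
    feats$class <- corp$pairs$class
    list(corpus = corp, features = label_subtypes(feats))
  })
}

separable_200 <- function() {
  fixture("separable_200", function() {
    corp <- generate_separable_set(200L, seed = 7L)
    list(corpus = corp,
         features = compute_feature_matrix(corp$pairs, corp$records))
  })
}
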