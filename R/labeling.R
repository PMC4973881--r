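# ---------------------------------------------------------------------------
# Duplicate subtypes and the Seq90 baseline.
#
# Subtype precedence is NS -> ES -> EF: a non-significant alignment (no hit,
# or E-value strictly over 0.001) invalidates the identity evidence that the
# ES/EF distinction relies on, so NS is carved out first; among significant
# alignments, pairs with both local identity and AP at or above 0.9 are ES
# (near-exact sequences) and the remainder are EF (near-exact fragments).
# ---------------------------------------------------------------------------

#' Assign a duplicate subtype from pair features
#'
#' For a pair known to be a duplicate, classifies it as `NS` (non-significant
#' alignment: over-threshold E-value or no hits), `ES` (both identity and AP
#' >= 0.9, inclusive) or `EF` (significant hit below the ES criteria). The
#' E-value boundary is strict: exactly 0.001 is not over the threshold.
#'
#' @param features A `pair_features` object, a one-row data frame, or a
#'   feature tibble (vectorized).
#' @return Character vector of subtypes in `{ES, EF, NS}`.
#' @export
#' @examples
#' f <- list(over_threshold = "No", identity = 0.95, ap = 0.93)
#' assign_subtype(f)
assign_subtype <- function(features) {
  ot <- as.character(features[["over_threshold"]])
  id <- as.numeric(features[["identity"]])
  ap <- as.numeric(features[["ap"]])
  n <- length(ot)
  out <- character(n)
  ns <- ot == "Yes"
  es <- !ns & !is.na(id) & !is.na(ap) & id >= 0.9 & ap >= 0.9
  out[ns] <- "NS"
  out[es] <- "ES"
  out[!ns & !es] <- "EF"
  out
}

#' Seq90 baseline classifier
#'
#' Declares a pair a duplicate when both the local sequence identity and the
#' length ratio are at least 0.9 (inclusive). Pairs without an alignment hit
#' (missing identity) are classified distinct: the baseline cannot claim
#' duplication without an alignment.
#'
#' @param features A `pair_features` object or a feature tibble (vectorized).
#' @return Character vector in `{DU, DI}`.
#' @export
seq90_classify <- function(features) {
  id <- as.numeric(features[["identity"]])
  len <- as.numeric(features[["length"]])
  ifelse(!is.na(id) & id >= 0.9 & len >= 0.9, "DU", "DI")
}

#' Append ground-truth subtype labels to a feature matrix
#'
#' Applies [assign_subtype()] to the rows labelled `DU`; `DI` rows get `NA`.
#' When the tibble already has a `subtype` column it is replaced.
#'
#' @param features Feature tibble with a `label` column.
#' @return The tibble with a `subtype` column.
#' @export
label_subtypes <- function(features) {
  if (!"label" %in% names(features))
    stop("label_subtypes: features must have a 'label' column")
  sub <- rep(NA_character_, nrow(features))
  du <- features$label == "DU"
  sub[du] <- assign_subtype(features[du, , drop = FALSE])
  features$subtype <- sub
  features
}
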