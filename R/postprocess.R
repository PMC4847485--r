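# Task-specific post-processing: phenotype candidate scoring/ranking from
# per-mention predictions, and stage-ethnicity tuple assembly.

#' Aggregate per-mention predictions into candidate scores
#'
#' For each (document, canonical phenotype) the classifier's hard
#' predictions over that phenotype's mentions are counted as positive
#' (`V_p`) and negative (`V_n`) votes, then converted into
#' `P_TF = V_p / (V_p + V_n)` and `P_IDF = V_p / sum(V_p over the
#' document's candidates)`. A document with zero positive votes has all
#' `P_IDF` defined as 0.
#'
#' @param predictions data frame with columns `doc_id`, `canonical`,
#'   `label` (0/1 per mention).
#' @return data frame with columns `doc_id`, `canonical`, `V_p`, `V_n`,
#'   `P_TF`, `P_IDF`.
#' @export
score_candidates <- function(predictions) {
  stopifnot(all(c("doc_id", "canonical", "label") %in% names(predictions)))
  if (nrow(predictions) == 0L) {
    return(data.frame(doc_id = character(), canonical = character(),
                      V_p = integer(), V_n = integer(),
                      P_TF = numeric(), P_IDF = numeric()))
  }
  agg <- stats::aggregate(
    cbind(V_p = predictions$label == 1L, V_n = predictions$label == 0L),
    by = list(doc_id = predictions$doc_id, canonical = predictions$canonical),
    FUN = sum
  )
  agg$V_p <- as.integer(agg$V_p); agg$V_n <- as.integer(agg$V_n)
  tot <- agg$V_p + agg$V_n
  agg$P_TF <- ifelse(tot > 0, agg$V_p / tot, 0)
  doc_tot <- stats::ave(agg$V_p, agg$doc_id, FUN = sum)
  agg$P_IDF <- ifelse(doc_tot > 0, agg$V_p / doc_tot, 0)
  agg <- agg[order(agg$doc_id, agg$canonical), ]
  rownames(agg) <- NULL
  agg
}

#' Combine P_TF and P_IDF into a single ranking score
#'
#' Arithmetic mean `(P_TF + P_IDF)/2` or harmonic mean
#' `2 P_TF P_IDF / (P_TF + P_IDF)`, the latter defined as 0 when both
#' inputs are 0. The harmonic mean penalizes candidates that are strong on
#' one component only, which suits the typically small, outlier-prone vote
#' ratios.
#'
#' @param scores data frame from [score_candidates()] (or any frame with
#'   `P_TF`, `P_IDF`).
#' @param method `"harmonic"` (default) or `"arithmetic"`.
#' @return numeric vector of combined scores, one per row.
#' @export
combine_scores <- function(scores, method = c("harmonic", "arithmetic")) {
  method <- match.arg(method)
  a <- scores$P_TF; b <- scores$P_IDF
  if (method == "arithmetic") (a + b) / 2 else ifelse(a + b > 0, 2 * a * b / (a + b), 0)
}

#' Rank a document's candidates and keep the top k
#'
#' Descending by combined score; ties broken by higher `V_p`, then
#' lexicographically by canonical name, so the ordering is deterministic.
#'
#' @param scores data frame from [score_candidates()] restricted to a
#'   single document.
#' @param k number of candidates to keep (>= 1).
#' @param method passed to [combine_scores()].
#' @return character vector of canonicals, best first, length `<= k`.
#' @export
rank_top_k <- function(scores, k, method = c("harmonic", "arithmetic")) {
  stopifnot(k >= 1L)
  if (nrow(scores) == 0L) return(character())
  if (length(unique(scores$doc_id)) > 1L) {
    stop("rank_top_k expects candidates of a single document", call. = FALSE)
  }
  s <- combine_scores(scores, method)
  o <- order(-s, -scores$V_p, scores$canonical)
  utils::head(scores$canonical[o], k)
}

#' Assemble deduplicated stage-ethnicity tuples
#'
#' Groups positive passages by their stage classification into
#' `(stage, ethnicity)` tuples with set semantics per document.
#'
#' @param classified data frame with columns `doc_id`, `ethnicity`,
#'   `stage`.
#' @return data frame of unique tuples, sorted for determinism.
#' @export
assemble_tuples <- function(classified) {
  cols <- c("doc_id", "stage", "ethnicity")
  if (nrow(classified) == 0L) {
    return(data.frame(doc_id = character(), stage = character(),
                      ethnicity = character()))
  }
  stopifnot(all(cols %in% names(classified)))
  out <- unique(classified[, cols])
  out <- out[order(out$doc_id, out$stage, out$ethnicity), ]
  rownames(out) <- NULL
  out
}

#' Assign-all-ethnicities baseline for stage-ethnicity extraction
#'
#' Every ethnicity the dictionary tags in an article is assigned to both
#' stages. Its recall is 1 whenever the dictionary covers every curated
#' ethnicity; its precision is what the learned pipeline must beat.
#'
#' @param articles list of [article()]s.
#' @param dict ethnicity [term_dictionary()].
#' @return tuple data frame as from [assemble_tuples()].
#' @export
baseline_assign_all <- function(articles, dict) {
  rows <- do.call(rbind, lapply(articles, function(a) {
    m <- match_mentions(a, dict)
    if (nrow(m) == 0L) return(NULL)
    eth <- unique(m$canonical)
    data.frame(doc_id = a$doc_id,
               stage = rep(c("initial", "replication"), each = length(eth)),
               ethnicity = rep(eth, 2L), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(doc_id = character(), stage = character(),
                      ethnicity = character()))
  }
  assemble_tuples(rows)
}
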