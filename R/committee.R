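# The committee of weak classifiers. Each member gives a hard 0/1 vote on a
# (passage, curated-record) pair; all votes together form the I x J binary
# committee matrix that the EM label estimator consumes.

.norm_match <- function(x) normalize_ws(matching_form(normalize_typography(x)))

# term contained in text (or vice versa) as a substring, on normalized forms
.substr_either <- function(a, b) {
  grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)
}

# whole-term occurrence of a lexicon term inside a token-joined context string
.lexicon_hit <- function(terms, context_string) {
  any(vapply(terms, function(t) {
    grepl(paste0("(?<![[:alnum:]])", rx_escape(.norm_match(t)), "(?![[:alnum:]])"),
          context_string, perl = TRUE)
  }, logical(1)))
}

.ctx_string <- function(p) {
  .norm_match(paste(c(p$left_context, p$right_context), collapse = " "))
}

#' Phenotype-task committee votes for one passage
#'
#' Five rule-based members, in fixed order:
#' \enumerate{
#'   \item `title_abstract` -- the mention occurs in the title or abstract;
#'   \item `exact_match` -- the mention equals a curated term
#'     (case-insensitive, hyphen/space-insensitive);
#'   \item `substring` -- the mention is a substring of a curated term or
#'     contains one ("Diabetes" vs curated "Type-2 Diabetes");
#'   \item `synonym` -- the mention exactly or partially matches a
#'     preferred term of a curated term's concept, i.e. any surface term
#'     sharing the curated term's canonical entity in the synonym
#'     dictionary;
#'   \item `compound` -- the mention has multiple tokens separated by a
#'     space or hyphen ("Parkinson's disease").
#' }
#'
#' @param passage a `curex_passage`.
#' @param record the document's [curated_record()] (phenotype task).
#' @param synonyms optional [term_dictionary()] grouping synonymous surface
#'   terms under one canonical entity.
#' @return named integer vector of 5 votes in \{0, 1\}.
#' @export
vote_task1 <- function(passage, record, synonyms = NULL) {
  stopifnot(record$task == "phenotype", passage$doc_id == record$doc_id)
  mention <- .norm_match(passage$surface)
  terms <- .norm_match(record$phenotype_terms)
  v1 <- passage$location %in% c("title", "abstract")
  v2 <- mention %in% terms
  v3 <- any(vapply(terms, .substr_either, logical(1), b = mention))
  v4 <- FALSE
  if (!is.null(synonyms)) {
    dict_terms <- names(synonyms$entries)
    for (term in terms) {
      ent <- synonyms$entries[match(term, .norm_match(dict_terms))]
      if (is.na(ent)) next
      # all preferred terms of the curated concept, the curated surface
      # included (concept synonym lists carry the term's own atoms)
      syns <- .norm_match(dict_terms[synonyms$entries == ent])
      if (any(vapply(syns, .substr_either, logical(1), b = mention))) {
        v4 <- TRUE
        break
      }
    }
  }
  toks <- tokens_of(chartr("-", " ", passage$surface), fold = FALSE)
  v5 <- length(toks) >= 2L && grepl("[ -]", trimws(passage$surface))
  stats::setNames(as.integer(c(v1, v2, v3, v4, v5)),
                  c("title_abstract", "exact_match", "substring", "synonym",
                    "compound"))
}

#' Stage-ethnicity positive/negative committee votes for one passage
#'
#' Three members, in fixed order: the learned base classifier's prediction;
#' a rule that fires when any sample-description lexicon term ("stage",
#' "cohort", ...) appears in the context window; and the weak label from
#' curated data -- 1 iff the passage's canonical ethnicity appears in the
#' record's tuples for either stage.
#'
#' @param passage a `curex_passage`.
#' @param record the document's [curated_record()] (stage-ethnicity task).
#' @param lexicon a sample-description [rule_lexicon()].
#' @param base_vote the trained base scorer's 0/1 prediction for this
#'   passage (or a function of the passage returning one).
#' @return named integer vector of 3 votes.
#' @export
vote_task2_posneg <- function(passage, record, lexicon, base_vote) {
  stopifnot(record$task == "stage_ethnicity", passage$doc_id == record$doc_id)
  if (is.function(base_vote)) base_vote <- base_vote(passage)
  if (is.null(base_vote) || is.na(base_vote)) {
    stop("base committee member is untrained (no vote available)", call. = FALSE)
  }
  v2 <- .lexicon_hit(lexicon$terms, .ctx_string(passage))
  eth <- .norm_match(record$tuples$ethnicity)
  v3 <- .norm_match(passage$canonical) %in% eth
  stats::setNames(as.integer(c(base_vote, v2, v3)),
                  c("base_classifier", "sample_lexicon", "weak_label"))
}

#' Stage-ethnicity initial/replication committee votes for one passage
#'
#' Applied to passages judged positive upstream. Binary convention:
#' 1 = initial, 0 = replication. Members, in fixed order: the learned
#' initial-vs-replication classifier; a stage-cue rule (initial cue present
#' and no replication cue -> 1; replication cue present and no initial cue
#' -> 0; no cue or both -> 1, the default-initial tie-break, since the
#' initial stage is obligatory in a GWAS); and the weak label from curated
#' tuples (ethnicity listed under initial -> 1; only under replication ->
#' 0; under both or neither -> 1).
#'
#' @param passage a `curex_passage`.
#' @param record the document's [curated_record()].
#' @param initial_cues,replication_cues stage-cue [rule_lexicon()]s.
#' @param base_vote the trained stage scorer's 0/1 prediction.
#' @return named integer vector of 3 votes.
#' @export
vote_task2_stage <- function(passage, record, initial_cues, replication_cues,
                             base_vote) {
  stopifnot(record$task == "stage_ethnicity", passage$doc_id == record$doc_id)
  if (is.function(base_vote)) base_vote <- base_vote(passage)
  if (is.null(base_vote) || is.na(base_vote)) {
    stop("base committee member is untrained (no vote available)", call. = FALSE)
  }
  ctx <- .ctx_string(passage)
  ini <- .lexicon_hit(initial_cues$terms, ctx)
  rep_ <- .lexicon_hit(replication_cues$terms, ctx)
  v2 <- if (rep_ && !ini) 0L else 1L
  eth <- .norm_match(passage$canonical)
  stages <- record$tuples$stage[.norm_match(record$tuples$ethnicity) == eth]
  v3 <- if (length(stages) && all(stages == "replication")) 0L else 1L
  stats::setNames(as.integer(c(base_vote, v2, v3)),
                  c("base_classifier", "stage_cue", "weak_label"))
}

#' Build the committee matrix from long-form votes
#'
#' @param votes data frame with columns `passage_id`, `classifier_id`,
#'   `vote` (0/1). Every (passage, classifier) pair must appear exactly
#'   once; rows and columns keep first-appearance order.
#' @return an object of class `committee_matrix` with elements `M`
#'   (integer I x J matrix), `passage_ids`, `classifier_ids`.
#' @export
build_matrix <- function(votes) {
  stopifnot(is.data.frame(votes),
            all(c("passage_id", "classifier_id", "vote") %in% names(votes)))
  if (!all(votes$vote %in% c(0L, 1L))) {
    stop("votes must be binary 0/1", call. = FALSE)
  }
  pids <- unique(votes$passage_id)
  cids <- unique(votes$classifier_id)
  key <- paste(votes$passage_id, votes$classifier_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- votes[which(dup)[1], ]
    stop(sprintf("duplicate vote for passage '%s' / classifier '%s'",
                 d$passage_id, d$classifier_id), call. = FALSE)
  }
  if (nrow(votes) != length(pids) * length(cids)) {
    full <- expand.grid(passage_id = pids, classifier_id = cids,
                        stringsAsFactors = FALSE)
    fkey <- paste(full$passage_id, full$classifier_id, sep = "\r")
    miss <- full[!(fkey %in% key), ][1, ]
    stop(sprintf("missing vote for passage '%s' / classifier '%s'",
                 miss$passage_id, miss$classifier_id), call. = FALSE)
  }
  M <- matrix(0L, length(pids), length(cids),
              dimnames = list(pids, cids))
  M[cbind(match(votes$passage_id, pids), match(votes$classifier_id, cids))] <-
    as.integer(votes$vote)
  structure(list(M = M, passage_ids = pids, classifier_ids = cids),
            class = "committee_matrix")
}

#' @exportS3Method base::print
print.committee_matrix <- function(x, ...) {
  cat(sprintf("<committee_matrix %d passages x %d classifiers, %.1f%% positive votes>\n",
              nrow(x$M), ncol(x$M), 100 * mean(x$M)))
  invisible(x)
}

# Wrap a plain binary matrix (used by the simulator and the EM front door).
as_committee_matrix <- function(M, passage_ids = NULL, classifier_ids = NULL) {
  if (inherits(M, "committee_matrix")) return(M)
  M <- as.matrix(M)
  if (!all(M %in% c(0, 1))) stop("committee matrix entries must be 0/1", call. = FALSE)
  storage.mode(M) <- "integer"
  passage_ids <- passage_ids %||% rownames(M) %||% paste0("p", seq_len(nrow(M)))
  classifier_ids <- classifier_ids %||% colnames(M) %||% paste0("c", seq_len(ncol(M)))
  dimnames(M) <- list(passage_ids, classifier_ids)
  structure(list(M = M, passage_ids = passage_ids, classifier_ids = classifier_ids),
            class = "committee_matrix")
}

# Collect a committee matrix from per-passage vote vectors (list of equal-
# length named integer vectors, one per passage).
votes_to_matrix <- function(vote_list, passage_ids = NULL) {
  stopifnot(length(vote_list) >= 1L)
  passage_ids <- passage_ids %||% paste0("p", seq_along(vote_list))
  cids <- names(vote_list[[1]])
  long <- do.call(rbind, lapply(seq_along(vote_list), function(i) {
    data.frame(passage_id = passage_ids[i], classifier_id = cids,
               vote = as.integer(vote_list[[i]]), stringsAsFactors = FALSE)
  }))
  build_matrix(long)
}

#' Write a committee matrix as TSV
#' @param cm a `committee_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_committee_matrix <- function(cm, path) {
  df <- data.frame(passage_id = cm$passage_ids, cm$M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
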