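# Evaluation: precision-at-k for ranked phenotype extraction and
# micro/macro precision/recall/F1 for stage-ethnicity tuple sets, plus the
# article-based cross-validation harness.

.harmonic <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

#' Precision at k for ranked phenotype predictions
#'
#' The fraction of documents for which at least one of the top-k ranked
#' canonicals matches a gold term (case-insensitive). Documents with an
#' empty gold set are excluded from the denominator; documents with gold
#' terms but no predictions count as misses.
#'
#' @param ranked named list: `doc_id` -> character vector of ranked
#'   canonicals.
#' @param gold named list: `doc_id` -> character vector of gold terms, or a
#'   named list of phenotype [curated_record()]s.
#' @param k rank cutoff (>= 1).
#' @return an `evaluation_report` with `metric = "p_at_k"`.
#' @export
precision_at_k <- function(ranked, gold, k = 2L) {
  stopifnot(k >= 1L)
  gold <- lapply(gold, function(g) if (inherits(g, "curex_record")) g$phenotype_terms else g)
  docs <- names(gold)[lengths(gold) > 0L]
  hits <- vapply(docs, function(d) {
    top <- utils::head(ranked[[d]] %||% character(), k)
    any(tolower(top) %in% tolower(gold[[d]]))
  }, logical(1))
  structure(list(metric = "p_at_k", k = as.integer(k),
                 precision = if (length(docs)) mean(hits) else NA_real_,
                 recall = NA_real_, f1 = NA_real_,
                 n_docs = length(docs), n_tuples = NA_integer_),
            class = "evaluation_report")
}

.tuple_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  tolower(paste(df$stage, df$ethnicity, sep = "\r"))
}

#' Tuple-level precision, recall and F1
#'
#' A predicted tuple present in the document's gold set is a true positive,
#' otherwise a false positive; a gold tuple with no predicted counterpart
#' is a false negative. `micro` pools TP/FP/FN over all documents. `macro`
#' computes per-document precision and recall, averages each, and reports
#' F1 as the harmonic mean of the two macro averages. Macro conventions:
#' a document with empty gold and empty prediction contributes
#' precision = recall = 1; empty prediction with non-empty gold gives
#' precision 0; empty gold with non-empty prediction gives recall 1.
#'
#' @param predicted,gold tuple data frames with columns `doc_id`, `stage`,
#'   `ethnicity` (matching is case-insensitive).
#' @param averaging `"micro"` or `"macro"`.
#' @return an `evaluation_report`.
#' @export
tuple_prf <- function(predicted, gold, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  docs <- union(unique(gold$doc_id), unique(predicted$doc_id))
  per_doc <- lapply(docs, function(d) {
    pk <- unique(.tuple_key(predicted[predicted$doc_id == d, , drop = FALSE]))
    gk <- unique(.tuple_key(gold[gold$doc_id == d, , drop = FALSE]))
    tp <- sum(pk %in% gk)
    list(tp = tp, fp = length(pk) - tp, fn = sum(!(gk %in% pk)),
         n_pred = length(pk), n_gold = length(gk))
  })
  n_tuples <- sum(vapply(per_doc, `[[`, numeric(1), "n_gold"))
  counts <- c(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_)
  if (averaging == "micro") {
    tp <- sum(vapply(per_doc, `[[`, numeric(1), "tp"))
    fp <- sum(vapply(per_doc, `[[`, numeric(1), "fp"))
    fn <- sum(vapply(per_doc, `[[`, numeric(1), "fn"))
    counts <- c(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- .harmonic(p, r)
  } else {
    pr <- vapply(per_doc, function(x) {
      if (x$n_pred == 0L && x$n_gold == 0L) return(c(1, 1))
      p <- if (x$n_pred > 0L) x$tp / x$n_pred else 0
      r <- if (x$n_gold > 0L) x$tp / x$n_gold else 1
      c(p, r)
    }, numeric(2))
    p <- mean(pr[1, ]); r <- mean(pr[2, ])
    f1 <- .harmonic(p, r)
  }
  structure(list(metric = paste0(averaging, "_prf"), k = NA_integer_,
                 precision = p, recall = r, f1 = f1,
                 n_docs = length(docs), n_tuples = as.integer(n_tuples),
                 tp = counts[["tp"]], fp = counts[["fp"]], fn = counts[["fn"]]),
            class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s: P=%.4f R=%.4f F1=%.4f (%d docs)>\n",
              x$metric, x$precision, x$recall, x$f1, x$n_docs))
  invisible(x)
}

#' Article-based k-fold cross-validation
#'
#' Articles are shuffled with the seed and split at article granularity:
#' each fold trains the configured pipeline on the other folds' articles
#' (with their curated records) and predicts the held-out articles.
#' Predictions are pooled across folds before the final metrics are
#' computed.
#'
#' @param articles named list of [article()]s (names = doc ids).
#' @param curated named list of [curated_record()]s for the same ids.
#' @param config pipeline configuration, see [pipeline_config()].
#' @param folds number of folds (default 5); must not exceed the number of
#'   articles.
#' @param seed integer seed controlling the shuffle and all downstream
#'   randomness.
#' @param gold optional evaluation gold standard: for the stage-ethnicity
#'   task a tuple data frame, for the phenotype task a named list of term
#'   vectors; defaults to the curated records themselves.
#' @return list with `assignments` (doc -> fold), `per_fold` reports, and
#'   pooled reports (`micro`/`macro` for tuples, `p_at_k` for phenotypes),
#'   plus the pooled predictions.
#' @export
cross_validate <- function(articles, curated, config = pipeline_config(),
                           folds = 5L, seed = 0L, gold = NULL) {
  ids <- names(articles)
  stopifnot(!is.null(ids), all(ids %in% names(curated)))
  if (length(ids) < folds) {
    stop("fewer documents than folds", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(ids))
  fold_id <- stats::setNames(rep_len(seq_len(folds), length(ids)), shuffled)
  fold_id <- fold_id[ids]
  task <- config$task
  if (is.null(gold)) {
    gold <- if (task == "stage_ethnicity") records_to_tuples(curated) else curated
  }
  pooled_tuples <- NULL
  pooled_ranked <- list()
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_ids <- ids[fold_id == f]
    train_ids <- setdiff(ids, test_ids)
    fold_seed <- (seed + f) %% .Machine$integer.max
    if (task == "stage_ethnicity") {
      res <- run_task2_pipeline(
        train = list(articles = articles[train_ids], curated = curated[train_ids]),
        test = list(articles = articles[test_ids]),
        dict = config$dict, lexicons = config$lexicons,
        config = utils::modifyList(config, list(seed = fold_seed)))
      pooled_tuples <- rbind(pooled_tuples, res$tuples)
      fold_gold <- gold[gold$doc_id %in% test_ids, , drop = FALSE]
      per_fold[[f]] <- tuple_prf(res$tuples, fold_gold, "micro")
    } else {
      res <- run_task1_pipeline(
        train = list(articles = articles[train_ids], curated = curated[train_ids]),
        test = list(articles = articles[test_ids]),
        dict = config$dict, synonyms = config$synonyms,
        config = utils::modifyList(config, list(seed = fold_seed)))
      pooled_ranked <- c(pooled_ranked, res$rankings)
      per_fold[[f]] <- precision_at_k(res$rankings, gold[test_ids], k = 2L)
    }
  }
  out <- list(assignments = fold_id, per_fold = per_fold, seed = seed,
              folds = folds)
  if (task == "stage_ethnicity") {
    if (is.null(pooled_tuples)) {
      pooled_tuples <- data.frame(doc_id = character(), stage = character(),
                                  ethnicity = character())
    }
    out$predictions <- pooled_tuples
    out$micro <- tuple_prf(pooled_tuples, gold, "micro")
    out$macro <- tuple_prf(pooled_tuples, gold, "macro")
  } else {
    out$predictions <- pooled_ranked
    out$p_at_k <- precision_at_k(pooled_ranked, gold, k = 2L)
  }
  out
}

#' Flatten stage-ethnicity records to a tuple data frame
#' @param records named list of stage-ethnicity [curated_record()]s.
#' @return data frame with columns `doc_id`, `stage`, `ethnicity`.
#' @export
records_to_tuples <- function(records) {
  rows <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$tuples) == 0L) return(NULL)
    data.frame(doc_id = r$doc_id, stage = r$tuples$stage,
               ethnicity = r$tuples$ethnicity, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(doc_id = character(), stage = character(),
                      ethnicity = character()))
  }
  rownames(rows) <- NULL
  rows
}
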