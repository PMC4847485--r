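# End-to-end pipelines: passage extraction (A), feature creation (B),
# committee voting (C), EM label estimation (D), cost-sensitive learning
# (E), then task-specific post-processing. The cost-insensitive variants
# skip (C)/(D) and train directly on the weak curated labels with unit
# costs, which is the comparison baseline.

#' Pipeline configuration
#'
#' @param task `"stage_ethnicity"` or `"phenotype"`.
#' @param em_variant `"disagreement"` or `"paper_literal"`, see
#'   [em_estimate()].
#' @param cost_variant `"lemma_consistent"` or `"paper_literal"`, see
#'   [assign_costs()].
#' @param priors EM [em_priors()].
#' @param tol,max_iter EM convergence settings.
#' @param reg SVM regularization strength.
#' @param ranking `"harmonic"` or `"arithmetic"` score combination for
#'   phenotype ranking.
#' @param top_k ranked list length kept per document.
#' @param cost_sensitive `FALSE` trains the cost-insensitive baseline.
#' @param min_df minimum document frequency for feature vocabularies.
#' @param seed root seed for all randomness in the run.
#' @param dict,lexicons,synonyms optional resources consumed by
#'   [cross_validate()] (the `run_*` functions take them as arguments).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = c("stage_ethnicity", "phenotype"),
                            em_variant = "disagreement",
                            cost_variant = "lemma_consistent",
                            priors = em_priors(), tol = 1e-6, max_iter = 100L,
                            reg = 1.0,
                            ranking = "harmonic", top_k = 5L,
                            cost_sensitive = TRUE, min_df = 1L, seed = 0L,
                            dict = NULL, lexicons = NULL, synonyms = NULL) {
  task <- match.arg(task)
  em_variant <- match.arg(em_variant, c("disagreement", "paper_literal"))
  cost_variant <- match.arg(cost_variant, c("lemma_consistent", "paper_literal"))
  ranking <- match.arg(ranking, c("harmonic", "arithmetic"))
  structure(list(task = task, em_variant = em_variant,
                 cost_variant = cost_variant, priors = priors, tol = tol,
                 max_iter = as.integer(max_iter), reg = reg, ranking = ranking,
                 top_k = as.integer(top_k), cost_sensitive = cost_sensitive,
                 min_df = as.integer(min_df), seed = as.integer(seed),
                 dict = dict, lexicons = lexicons, synonyms = synonyms),
            class = c("pipeline_config", "list"))
}

.collect_passages <- function(articles, dict, policy) {
  out <- list()
  for (a in articles) {
    m <- match_mentions(a, dict)
    out <- c(out, extract_passages(m, a, policy))
  }
  out
}

.config_manifest <- function(config, extra = list()) {
  keep <- c("task", "em_variant", "cost_variant", "tol", "max_iter", "reg",
            "ranking", "top_k", "cost_sensitive", "min_df", "seed")
  c(config[keep],
    list(priors = unclass(config$priors),
         package = "curex",
         version = as.character(utils::packageVersion("curex"))),
    extra)
}

#' Run the phenotype-ranking pipeline
#'
#' Trains on articles with curated phenotype records, then ranks candidate
#' phenotypes for each test article from the cost-sensitive classifier's
#' per-mention predictions.
#'
#' @param train list with `articles` (named list) and `curated` (named
#'   record list).
#' @param test list with `articles` (named list).
#' @param dict phenotype [term_dictionary()].
#' @param synonyms synonym [term_dictionary()] for the committee's synonym
#'   rule (may be `NULL`).
#' @param config a [pipeline_config()] with `task = "phenotype"`.
#' @return list with `rankings` (named list doc_id -> ranked canonicals),
#'   `scores` (candidate score frame), `model`, `schema`, `estimate` (the
#'   EM label estimate, `NULL` for the cost-insensitive variant) and
#'   `manifest`.
#' @export
run_task1_pipeline <- function(train, test, dict, synonyms = NULL,
                               config = pipeline_config(task = "phenotype")) {
  stopifnot(config$task == "phenotype")
  train_articles <- train$articles[names(train$articles) %in% names(train$curated)]
  passages <- .collect_passages(train_articles, dict, "cross_sentence")
  if (length(passages) == 0L) stop("no training passages extracted", call. = FALSE)
  schema <- fit_feature_schema(passages, "phenotype", min_df = config$min_df)
  x <- featurize(passages, schema)
  votes <- lapply(passages, function(p)
    vote_task1(p, train$curated[[p$doc_id]], synonyms))
  estimate <- NULL
  if (config$cost_sensitive) {
    cm <- votes_to_matrix(votes)
    estimate <- em_estimate(cm, config$priors, config$tol, config$max_iter,
                            config$em_variant)
    costs <- assign_costs(estimate, config$cost_variant)
  } else {
    y <- vapply(votes, `[[`, integer(1), "substring")
    costs <- list(y = y, c = rep.int(1, length(y)))
  }
  model <- train_weighted(x, costs, reg = config$reg)
  # apply to test articles
  preds <- list()
  for (a in test$articles) {
    tp <- .collect_passages(list(a), dict, "cross_sentence")
    if (length(tp) == 0L) next
    xt <- featurize(tp, schema)
    pr <- predict(model, xt)
    preds[[a$doc_id]] <- data.frame(
      doc_id = a$doc_id,
      canonical = vapply(tp, `[[`, character(1), "canonical"),
      label = pr$label, stringsAsFactors = FALSE)
  }
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(doc_id = character(), canonical = character(), label = integer())
  scores <- score_candidates(preds)
  rankings <- lapply(split(scores, scores$doc_id), rank_top_k,
                     k = config$top_k, method = config$ranking)
  list(rankings = rankings, scores = scores, model = model, schema = schema,
       estimate = estimate,
       manifest = .config_manifest(config, list(
         n_train_docs = length(train_articles),
         n_train_passages = length(passages),
         n_test_docs = length(test$articles))))
}

.stage_weak_label <- function(p, record) {
  eth <- .norm_match(record$tuples$ethnicity)
  stages <- record$tuples$stage[eth == .norm_match(p$canonical)]
  if (length(stages) && all(stages == "replication")) 0L else 1L
}

#' Run the stage-ethnicity tuple-extraction pipeline
#'
#' Chains two committees: the positive/negative committee decides whether
#' an ethnicity mention describes a study sample at all; mentions
#' classified positive are then classified into the initial or replication
#' stage by the second committee, and assembled into deduplicated
#' `(stage, ethnicity)` tuples per document.
#'
#' @param train list with `articles` and `curated`.
#' @param test list with `articles`.
#' @param dict ethnicity [term_dictionary()].
#' @param lexicons list with `sample` (sample-description lexicon),
#'   `initial` and `replication` (stage-cue lexicons); defaults to the
#'   bundled lexicons.
#' @param config a [pipeline_config()] with `task = "stage_ethnicity"`.
#' @return list with `tuples` (data frame `doc_id`, `stage`, `ethnicity`),
#'   the two models, `schema`, the two EM estimates and `manifest`.
#' @export
run_task2_pipeline <- function(train, test, dict, lexicons = NULL,
                               config = pipeline_config(task = "stage_ethnicity")) {
  stopifnot(config$task == "stage_ethnicity")
  if (is.null(lexicons)) {
    cues <- default_stage_lexicons()
    lexicons <- list(sample = default_sample_lexicon(),
                     initial = cues$initial, replication = cues$replication)
  }
  train_articles <- train$articles[names(train$articles) %in% names(train$curated)]
  passages <- .collect_passages(train_articles, dict, "within_sentence")
  if (length(passages) == 0L) stop("no training passages extracted", call. = FALSE)
  entities <- sort(unique(unname(dict$entries)))
  schema <- fit_feature_schema(passages, "stage_ethnicity", entities = entities,
                               min_df = config$min_df)
  x <- featurize(passages, schema)
  y_weak <- vapply(passages, function(p) {
    rec <- train$curated[[p$doc_id]]
    as.integer(.norm_match(p$canonical) %in% .norm_match(rec$tuples$ethnicity))
  }, integer(1))

  est_pos <- NULL; est_stage <- NULL
  if (config$cost_sensitive) {
    base <- oof_base_votes(x, y_weak, folds = 5L, seed = config$seed)
    votes <- lapply(seq_along(passages), function(i)
      vote_task2_posneg(passages[[i]], train$curated[[passages[[i]]$doc_id]],
                        lexicons$sample, base[i]))
    est_pos <- em_estimate(votes_to_matrix(votes), config$priors, config$tol,
                           config$max_iter, config$em_variant)
    costs_pos <- assign_costs(est_pos, config$cost_variant)
  } else {
    costs_pos <- list(y = y_weak, c = rep.int(1, length(y_weak)))
  }
  model_pos <- train_weighted(x, costs_pos, reg = config$reg)

  # stage committee operates on (weakly) positive training passages
  pos_idx <- which(if (config$cost_sensitive) costs_pos$y == 1L else y_weak == 1L)
  xp <- x[pos_idx, , drop = FALSE]
  s_weak <- vapply(passages[pos_idx], function(p)
    .stage_weak_label(p, train$curated[[p$doc_id]]), integer(1))
  stage_constant <- NULL
  model_stage <- NULL
  if (length(unique(s_weak)) < 2L) {
    stage_constant <- if (length(s_weak)) as.integer(s_weak[1]) else 1L
  } else if (config$cost_sensitive) {
    base_s <- oof_base_votes(xp, s_weak, folds = 5L, seed = config$seed + 1L)
    votes_s <- lapply(seq_along(pos_idx), function(i)
      vote_task2_stage(passages[[pos_idx[i]]],
                       train$curated[[passages[[pos_idx[i]]]$doc_id]],
                       lexicons$initial, lexicons$replication, base_s[i]))
    est_stage <- em_estimate(votes_to_matrix(votes_s), config$priors,
                             config$tol, config$max_iter, config$em_variant)
    costs_stage <- assign_costs(est_stage, config$cost_variant)
    if (length(unique(costs_stage$y)) < 2L) {
      stage_constant <- costs_stage$y[1]
    } else {
      model_stage <- train_weighted(xp, costs_stage, reg = config$reg)
    }
  } else {
    model_stage <- train_weighted(
      xp, list(y = s_weak, c = rep.int(1, length(s_weak))), reg = config$reg)
  }

  # apply to test articles
  rows <- list()
  for (a in test$articles) {
    tp <- .collect_passages(list(a), dict, "within_sentence")
    if (length(tp) == 0L) next
    xt <- featurize(tp, schema)
    pos <- predict(model_pos, xt)$label == 1L
    if (!any(pos)) next
    xt_pos <- xt[pos, , drop = FALSE]
    stage_lab <- if (!is.null(stage_constant)) {
      rep.int(stage_constant, sum(pos))
    } else {
      predict(model_stage, xt_pos)$label
    }
    rows[[a$doc_id]] <- data.frame(
      doc_id = a$doc_id,
      ethnicity = vapply(tp[pos], `[[`, character(1), "canonical"),
      stage = ifelse(stage_lab == 1L, "initial", "replication"),
      stringsAsFactors = FALSE)
  }
  tuples <- if (length(rows)) assemble_tuples(do.call(rbind, rows)) else
    data.frame(doc_id = character(), stage = character(), ethnicity = character())
  list(tuples = tuples, model_pos = model_pos, model_stage = model_stage,
       stage_constant = stage_constant, schema = schema,
       estimate_pos = est_pos, estimate_stage = est_stage,
       manifest = .config_manifest(config, list(
         n_train_docs = length(train_articles),
         n_train_passages = length(passages),
         n_test_docs = length(test$articles))))
}
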