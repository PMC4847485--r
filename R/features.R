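# Feature creation. Each task has a fixed sequence of feature blocks;
# blocks occupy disjoint index ranges in the final vector. Term-count
# blocks are TF-IDF weighted with the smoothed inverse document frequency
# log((1 + N) / (1 + df)) + 1 and L2-normalized per block. The
# stage-ethnicity vectors are additionally standardized to zero mean and
# unit variance per dimension using training-set statistics.

char_ngrams <- function(x, nmin = 2L, nmax = 4L) {
  x <- tolower(x)
  n <- nchar(x)
  if (n < nmin) return(character())
  out <- character()
  for (k in nmin:min(nmax, n)) {
    out <- c(out, substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  out
}

word_ngrams <- function(tokens, nmin = 1L, nmax = 2L) {
  m <- length(tokens)
  out <- character()
  for (k in nmin:nmax) {
    if (m < k) break
    if (k == 1L) {
      out <- c(out, tokens)
    } else {
      idx <- seq_len(m - k + 1L)
      grams <- tokens[idx]
      for (j in 2:k) grams <- paste(grams, tokens[idx + j - 1L], sep = "_")
      out <- c(out, grams)
    }
  }
  out
}

# Fit a TF-IDF block over a list of token multisets.
fit_tfidf_block <- function(doclists, min_df = 1L) {
  n <- length(doclists)
  df_counts <- table(unlist(lapply(doclists, unique), use.names = FALSE))
  keep <- df_counts >= min_df
  vocab <- sort(names(df_counts)[keep])
  dfv <- as.numeric(df_counts[vocab])
  list(vocab = vocab,
       idf = log((1 + n) / (1 + dfv)) + 1,
       n_docs = n)
}

# Transform token multisets into a sparse TF-IDF matrix (rows L2-normalized).
transform_tfidf_block <- function(doclists, block) {
  n <- length(doclists)
  d <- length(block$vocab)
  if (d == 0L) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(n, d)))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_len(n)) {
    idx <- match(doclists[[r]], block$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tab <- table(idx)
    j <- as.integer(names(tab))
    x <- as.numeric(tab) * block$idf[j]
    nrm <- sqrt(sum(x^2))
    if (nrm > 0) x <- x / nrm
    ii <- c(ii, rep.int(r, length(j))); jj <- c(jj, j); xx <- c(xx, x)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, d))
}

# Binary indicator block over a fixed level set.
transform_onehot <- function(values, levels) {
  n <- length(values)
  j <- match(values, levels)
  ok <- !is.na(j)
  Matrix::sparseMatrix(i = which(ok), j = j[ok], x = rep.int(1, sum(ok)),
                       dims = c(n, length(levels)))
}

# Binary bag block (1 if the token occurs at least once).
transform_bag <- function(doclists, vocab) {
  n <- length(doclists)
  ii <- integer(); jj <- integer()
  for (r in seq_len(n)) {
    idx <- unique(match(doclists[[r]], vocab))
    idx <- idx[!is.na(idx)]
    ii <- c(ii, rep.int(r, length(idx))); jj <- c(jj, idx)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = rep.int(1, length(ii)),
                       dims = c(n, length(vocab)))
}

.p_ctx_tokens <- function(p, stem = FALSE) {
  tk <- tolower(c(p$left_context, p$right_context))
  tk[grepl("^[0-9]+$", tk)] <- "#num"
  tk <- gsub("'", "", tk, fixed = TRUE)
  if (stem) tk <- porter_stem(tk)
  tk
}

.p_title_tokens <- function(p) tokens_of(p$section_title, collapse_digits = TRUE)

#' Fit a feature schema on training passages
#'
#' Phenotype-task blocks: character 2--4-grams of the mention; word
#' (1,2)-grams of the context window; character 2--4-grams of the context;
#' binary positional flags (in-title, in-abstract) plus a binary bag over
#' section-title tokens. Stage-ethnicity-task blocks: one-hot canonical
#' entity indicator; Porter-stemmed context (1,2)-grams (TF-IDF);
#' section-title unigrams (TF-IDF); normalized distance from article start
#' and from section start; same-article mention count of the entity. Digit
#' tokens are collapsed to a single placeholder in all word-level blocks.
#'
#' @param passages list of training passages from [extract_passages()].
#' @param task `"phenotype"` or `"stage_ethnicity"`.
#' @param entities canonical entity levels for the one-hot block
#'   (stage-ethnicity task); defaults to those observed in `passages`.
#' @param min_df minimum document frequency for term blocks.
#' @return an object of class `curex_schema`.
#' @export
fit_feature_schema <- function(passages, task = c("phenotype", "stage_ethnicity"),
                               entities = NULL, min_df = 1L) {
  task <- match.arg(task)
  if (length(passages) == 0L) stop("cannot fit a schema on zero passages", call. = FALSE)
  if (task == "phenotype") {
    blocks <- list(
      mention_char = fit_tfidf_block(lapply(passages, function(p)
        char_ngrams(p$surface)), min_df),
      ctx_word = fit_tfidf_block(lapply(passages, function(p)
        word_ngrams(.p_ctx_tokens(p))), min_df),
      ctx_char = fit_tfidf_block(lapply(passages, function(p)
        char_ngrams(paste(c(p$left_context, p$right_context), collapse = " "))),
        min_df),
      position = list(vocab = c("in_title", "in_abstract"), idf = NULL),
      sec_bag = list(vocab = sort(unique(unlist(lapply(passages, .p_title_tokens)))),
                     idf = NULL)
    )
    scaler <- NULL
  } else {
    entities <- entities %||% sort(unique(vapply(passages, `[[`, character(1),
                                                 "canonical")))
    blocks <- list(
      entity = list(vocab = entities, idf = NULL),
      ctx_word = fit_tfidf_block(lapply(passages, function(p)
        word_ngrams(.p_ctx_tokens(p, stem = TRUE))), min_df),
      sec_title = fit_tfidf_block(lapply(passages, .p_title_tokens), min_df),
      numeric = list(vocab = c("frac_doc", "frac_section", "n_entity_in_doc"),
                     idf = NULL)
    )
    scaler <- NULL  # filled below once the raw matrix exists
  }
  dims <- vapply(blocks, function(b) length(b$vocab), integer(1))
  offsets <- stats::setNames(cumsum(c(0L, utils::head(unname(dims), -1L))),
                             names(dims))
  schema <- structure(
    list(task = task, blocks = blocks, dims = dims, offsets = offsets,
         schema_id = sprintf("curex-%s-%d", task, sum(dims)),
         scaler = NULL),
    class = "curex_schema"
  )
  if (task == "stage_ethnicity") {
    x <- .featurize_raw(passages, schema)
    mu <- Matrix::colMeans(x)
    # population variance, consistent with standard feature scalers
    sq <- Matrix::colMeans(x^2) - mu^2
    sdv <- sqrt(pmax(sq, 0))
    sdv[sdv < 1e-12] <- 1
    schema$scaler <- list(mean = as.numeric(mu), sd = as.numeric(sdv))
  }
  schema
}

#' @exportS3Method base::print
print.curex_schema <- function(x, ...) {
  cat(sprintf("<curex_schema %s: %d dims (%s)%s>\n", x$task, sum(x$dims),
              paste(sprintf("%s=%d", names(x$dims), x$dims), collapse = ", "),
              if (is.null(x$scaler)) "" else ", standardized"))
  invisible(x)
}

.featurize_raw <- function(passages, schema) {
  b <- schema$blocks
  if (schema$task == "phenotype") {
    parts <- list(
      transform_tfidf_block(lapply(passages, function(p)
        char_ngrams(p$surface)), b$mention_char),
      transform_tfidf_block(lapply(passages, function(p)
        word_ngrams(.p_ctx_tokens(p))), b$ctx_word),
      transform_tfidf_block(lapply(passages, function(p)
        char_ngrams(paste(c(p$left_context, p$right_context), collapse = " "))),
        b$ctx_char),
      local({
        loc <- vapply(passages, `[[`, character(1), "location")
        Matrix::sparseMatrix(
          i = c(which(loc == "title"), which(loc == "abstract")),
          j = c(rep.int(1L, sum(loc == "title")),
                rep.int(2L, sum(loc == "abstract"))),
          x = rep.int(1, sum(loc %in% c("title", "abstract"))),
          dims = c(length(passages), 2L))
      }),
      transform_bag(lapply(passages, .p_title_tokens), b$sec_bag$vocab)
    )
  } else {
    num <- do.call(rbind, lapply(passages, function(p)
      c(p$frac_doc, p$frac_section, p$n_entity_in_doc)))
    parts <- list(
      transform_onehot(vapply(passages, `[[`, character(1), "canonical"),
                       b$entity$vocab),
      transform_tfidf_block(lapply(passages, function(p)
        word_ngrams(.p_ctx_tokens(p, stem = TRUE))), b$ctx_word),
      transform_tfidf_block(lapply(passages, .p_title_tokens), b$sec_title),
      Matrix::Matrix(num, sparse = TRUE)
    )
  }
  do.call(cbind, parts)
}

#' Featurize passages under a fitted schema
#'
#' @param passages list of passages (or a single passage).
#' @param schema a fitted [fit_feature_schema()] object.
#' @return a sparse (phenotype task) or dense (stage-ethnicity task, because
#'   of standardization) numeric matrix, one row per passage.
#' @export
featurize <- function(passages, schema) {
  if (!inherits(schema, "curex_schema")) {
    stop("schema must be fitted with fit_feature_schema()", call. = FALSE)
  }
  if (inherits(passages, "curex_passage")) passages <- list(passages)
  x <- .featurize_raw(passages, schema)
  if (!is.null(schema$scaler)) {
    x <- as.matrix(x)
    x <- sweep(x, 2L, schema$scaler$mean, "-")
    x <- sweep(x, 2L, schema$scaler$sd, "/")
  }
  colnames(x) <- feature_names(schema)
  x
}

#' Persist a fitted feature schema as JSON
#' @param schema a `curex_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "curex_schema"))
  jsonlite::write_json(
    list(task = schema$task, schema_id = schema$schema_id,
         blocks = lapply(schema$blocks, function(b)
           list(vocab = b$vocab, idf = b$idf, n_docs = b$n_docs)),
         scaler = schema$scaler),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a persisted feature schema
#' @param path JSON path written by [write_schema()].
#' @return a `curex_schema`.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(obj$blocks, function(b) {
    list(vocab = as.character(b$vocab %||% character()),
         idf = if (is.null(b$idf)) NULL else as.numeric(b$idf),
         n_docs = b$n_docs)
  })
  dims <- vapply(blocks, function(b) length(b$vocab), integer(1))
  scaler <- if (is.null(obj$scaler) || length(obj$scaler) == 0L) NULL else
    list(mean = as.numeric(obj$scaler$mean), sd = as.numeric(obj$scaler$sd))
  offsets <- stats::setNames(cumsum(c(0L, utils::head(unname(dims), -1L))),
                             names(dims))
  structure(list(task = obj$task, blocks = blocks, dims = dims,
                 offsets = offsets,
                 schema_id = obj$schema_id, scaler = scaler),
            class = "curex_schema")
}

#' Feature names of a schema (block-prefixed, disjoint ranges)
#' @param schema a `curex_schema`.
#' @return character vector of length `sum(schema$dims)`.
#' @export
feature_names <- function(schema) {
  unlist(lapply(names(schema$blocks), function(nm)
    paste(nm, schema$blocks[[nm]]$vocab, sep = ":")), use.names = FALSE)
}
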