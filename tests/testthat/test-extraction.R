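test_that("longest match wins over embedded shorter terms", {
  a <- article("d", title = "", abstract = "",
               sections = list(list(title = "", paragraphs =
                 list("patients with type 2 diabetes"))))
  d <- term_dictionary(c("type 2 diabetes" = "Type 2 diabetes",
                         "diabetes" = "Type 2 diabetes"))
  m <- match_mentions(a, d)
  expect_equal(nrow(m), 1L)
  expect_identical(m$surface, "type 2 diabetes")
})

test_that("adjectivals and demonyms both resolve to the canonical group", {
  a <- article("d", sections = list(list(title = "", paragraphs =
    list("German and Germans were enrolled."))))
  d <- term_dictionary(c("German" = "European", "Germans" = "European"))
  m <- match_mentions(a, d)
  expect_equal(nrow(m), 2L)
  expect_identical(unique(m$canonical), "European")
})

test_that("text without dictionary terms yields an empty mention frame", {
  a <- article("d", sections = list(list(title = "", paragraphs = list("no hits here"))))
  d <- term_dictionary(c("diabetes" = "Diabetes"))
  expect_equal(nrow(match_mentions(a, d)), 0L)
})

test_that("hyphen and space are interchangeable in matching", {
  a <- article("d", sections = list(list(title = "", paragraphs =
    list("African-American participants and African American controls"))))
  d <- term_dictionary(c("African American" = "African American"))
  m <- match_mentions(a, d)
  expect_equal(nrow(m), 2L)
  expect_setequal(m$surface, c("African-American", "African American"))
})

test_that("mention surfaces equal the text slice and matches never overlap", {
  vocab <- c("han", "han chinese", "european", "east asian", "asian",
             "type 2 diabetes", "diabetes")
  set.seed(42)
  for (rep in 1:20) {
    words <- sample(c("han", "chinese", "european", "east", "asian", "type",
                      "2", "diabetes", "study", "cohort"), 12, replace = TRUE)
    text <- paste(words, collapse = " ")
    a <- article("d", sections = list(list(title = "", paragraphs = list(text))))
    d <- term_dictionary(stats::setNames(tools::toTitleCase(vocab), vocab))
    m <- match_mentions(a, d)
    dmtext <- paste(text)
    if (nrow(m)) {
      expect_identical(tolower(m$surface),
                       tolower(substring(dmtext, m$start + 1L, m$end)))
      if (nrow(m) > 1L) {
        o <- order(m$start)
        expect_true(all(m$start[o][-1] >= m$end[o][-nrow(m)]))
      }
    }
    # every brute-force occurrence is covered by at least one emitted mention
    occ <- brute_force_occurrences(text, vocab)
    if (nrow(occ)) {
      covered <- vapply(seq_len(nrow(occ)), function(i)
        any(m$start < occ$end[i] & m$end > occ$start[i]), logical(1))
      expect_true(all(covered))
    }
  }
})

test_that("context windows respect the 10-token cap and sentence boundaries", {
  words <- paste0("w", 1:25)
  words[13] <- "diabetes"
  a <- article("d", sections = list(list(title = "", paragraphs =
    list(paste(words, collapse = " ")))))
  d <- term_dictionary(c("diabetes" = "Diabetes"))
  m <- match_mentions(a, d)
  p <- extract_passages(m, a, "within_sentence")[[1]]
  expect_length(p$left_context, 10L)
  expect_length(p$right_context, 10L)
  expect_identical(p$left_context, paste0("w", 3:12))
  expect_identical(p$right_context, paste0("w", 14:23))
})

test_that("a mention at document start has empty left context", {
  a <- article("d", sections = list(list(title = "", paragraphs =
    list("Diabetes was studied."))))
  d <- term_dictionary(c("diabetes" = "Diabetes"))
  p <- extract_passages(match_mentions(a, d), a, "cross_sentence")[[1]]
  expect_length(p$left_context, 0L)
})

test_that("within-sentence windows truncate at the sentence start", {
  a <- article("d", sections = list(list(title = "", paragraphs = list(
    "Some earlier sentence ends here. Only three words before diabetes appears in this sentence."))))
  d <- term_dictionary(c("diabetes" = "Diabetes"))
  m <- match_mentions(a, d)
  p_in <- extract_passages(m, a, "within_sentence")[[1]]
  expect_identical(p_in$left_context, c("Only", "three", "words", "before"))
  p_cross <- extract_passages(m, a, "cross_sentence")[[1]]
  expect_gt(length(p_cross$left_context), length(p_in$left_context))
})

test_that("featurization is deterministic and blocks occupy disjoint ranges", {
  sim <- small_task2_corpus(n_docs = 6L, seed = 3L)
  ps <- list()
  for (a in sim$articles) {
    ps <- c(ps, extract_passages(match_mentions(a, sim$dictionary), a,
                                 "within_sentence"))
  }
  schema <- fit_feature_schema(ps, "stage_ethnicity",
                               entities = sort(unique(unname(sim$dictionary$entries))))
  x1 <- featurize(ps, schema)
  x2 <- featurize(ps, schema)
  expect_identical(x1, x2)
  expect_equal(ncol(x1), sum(schema$dims))
  nms <- feature_names(schema)
  expect_identical(colnames(x1), nms)
  # block prefixes partition the columns contiguously
  prefixes <- sub(":.*", "", nms)
  expect_identical(rle(prefixes)$values, names(schema$blocks))
})

test_that("the entity one-hot indicator marks exactly the passage's entity", {
  sim <- small_task2_corpus(n_docs = 4L, seed = 5L)
  a <- sim$articles[[1]]
  ps <- extract_passages(match_mentions(a, sim$dictionary), a, "within_sentence")
  entities <- sort(unique(unname(sim$dictionary$entries)))
  schema <- fit_feature_schema(ps, "stage_ethnicity", entities = entities)
  x <- curex:::.featurize_raw(ps, schema)
  ent_block <- as.matrix(x[, seq_along(entities), drop = FALSE])
  for (i in seq_along(ps)) {
    expect_equal(sum(ent_block[i, ]), 1)
    expect_equal(which(ent_block[i, ] == 1), match(ps[[i]]$canonical, entities))
  }
})

test_that("distance features are monotone in character offset", {
  sim <- small_task2_corpus(n_docs = 5L, seed = 7L)
  a <- sim$articles[[1]]
  ps <- extract_passages(match_mentions(a, sim$dictionary), a, "within_sentence")
  starts <- vapply(ps, `[[`, numeric(1), "start")
  fracs <- vapply(ps, `[[`, numeric(1), "frac_doc")
  expect_identical(order(starts), order(fracs))
  expect_true(all(fracs >= 0 & fracs <= 1))
})

test_that("featurize rejects an unfitted schema and TF-IDF rows are unit norm", {
  sim <- small_task2_corpus(n_docs = 4L, seed = 9L)
  a <- sim$articles[[1]]
  ps <- extract_passages(match_mentions(a, sim$dictionary), a, "within_sentence")
  expect_error(featurize(ps, list(task = "stage_ethnicity")), "fitted")
  schema <- fit_feature_schema(ps, "stage_ethnicity")
  raw <- curex:::.featurize_raw(ps, schema)
  ctx_cols <- schema$offsets[["ctx_word"]] + seq_len(schema$dims[["ctx_word"]])
  norms <- sqrt(Matrix::rowSums(raw[, ctx_cols, drop = FALSE]^2))
  expect_true(all(abs(norms[norms > 1e-9] - 1) < 1e-9))
})

test_that("passages serialize to JSON-lines", {
  a <- tiny_article()
  d <- term_dictionary(c("diabetes" = "Diabetes"))
  ps <- extract_passages(match_mentions(a, d), a, "cross_sentence")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_passages(ps, path)
  lines <- readLines(path)
  expect_length(lines, length(ps))
  obj <- jsonlite::fromJSON(lines[1])
  expect_identical(obj$doc_id, "d1")
})
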