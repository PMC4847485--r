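mk_passage <- function(doc_id = "doc1", surface = "Diabetes",
                       canonical = surface, location = "body",
                       left = character(), right = character()) {
  structure(list(doc_id = doc_id, surface = surface, canonical = canonical,
                 start = 0L, end = nchar(surface), location = location,
                 section_title = "", sentence_index = 1L,
                 left_context = left, right_context = right,
                 window_policy = "within_sentence", frac_doc = 0,
                 frac_section = 0, n_entity_in_doc = 1L),
            class = "curex_passage")
}

test_that("a mention that substring-matches the curated term votes (0,0,1,0,0)", {
  p <- mk_passage(surface = "Diabetes")
  rec <- curated_record("doc1", "phenotype", phenotype_terms = "Type-2 Diabetes")
  v <- vote_task1(p, rec)
  expect_identical(unname(v), c(0L, 0L, 1L, 0L, 0L))
})

test_that("compound mentions fire the compound-token rule", {
  rec <- curated_record("doc1", "phenotype", phenotype_terms = "X")
  v <- vote_task1(mk_passage(surface = "Parkinson's disease"), rec)
  expect_identical(v[["compound"]], 1L)
  expect_identical(vote_task1(mk_passage(surface = "Waist-hip"), rec)[["compound"]], 1L)
  expect_identical(vote_task1(mk_passage(surface = "Asthma"), rec)[["compound"]], 0L)
})

test_that("an exact title match fires title, exact and substring rules", {
  p <- mk_passage(surface = "Obesity", location = "title")
  rec <- curated_record("doc1", "phenotype", phenotype_terms = "Obesity")
  v <- vote_task1(p, rec)
  expect_identical(unname(v[1:3]), c(1L, 1L, 1L))
})

test_that("the synonym rule matches via the shared canonical entity", {
  syn <- term_dictionary(c("T2D" = "Type 2 diabetes",
                           "type 2 diabetes" = "Type 2 diabetes"))
  p <- mk_passage(surface = "type 2 diabetes")
  rec <- curated_record("doc1", "phenotype", phenotype_terms = "T2D")
  v <- vote_task1(p, rec, synonyms = syn)
  expect_identical(v[["synonym"]], 1L)
  expect_identical(v[["exact_match"]], 0L)
})

test_that("exact match implies substring match over random surfaces", {
  set.seed(1)
  terms <- c("obesity", "type 2 diabetes", "asthma", "height", "eye color")
  for (i in 1:50) {
    surface <- sample(terms, 1)
    curated <- sample(terms, sample(1:2, 1))
    p <- mk_passage(surface = surface)
    rec <- curated_record("doc1", "phenotype", phenotype_terms = curated)
    v <- vote_task1(p, rec)
    expect_lte(v[["exact_match"]], v[["substring"]])
    # determinism
    expect_identical(v, vote_task1(p, rec))
  }
})

test_that("positive/negative committee combines lexicon rule and weak label", {
  lex <- default_sample_lexicon()
  rec <- curated_record("doc1", "stage_ethnicity",
                        tuples = data.frame(stage = "initial",
                                            ethnicity = "European"))
  p_hit <- mk_passage(surface = "German", canonical = "European",
                      right = c("cohort", "was", "genotyped"))
  v <- vote_task2_posneg(p_hit, rec, lex, base_vote = 1L)
  expect_identical(unname(v[2:3]), c(1L, 1L))
  p_miss <- mk_passage(surface = "Han", canonical = "East Asian",
                       right = c("art", "was", "discussed"))
  v2 <- vote_task2_posneg(p_miss, rec, lex, base_vote = 0L)
  expect_identical(unname(v2[2:3]), c(0L, 0L))
  expect_error(vote_task2_posneg(p_hit, rec, lex, base_vote = NA),
               "untrained")
})

test_that("stage-cue votes follow the cue words with default-initial tie-break", {
  cues <- default_stage_lexicons()
  rec <- curated_record("doc1", "stage_ethnicity",
                        tuples = data.frame(stage = c("initial", "replication"),
                                            ethnicity = c("European", "East Asian")))
  p_rep <- mk_passage(canonical = "East Asian", surface = "Han",
                      left = c("in", "the", "follow-up", "cohort"))
  v <- vote_task2_stage(p_rep, rec, cues$initial, cues$replication, 0L)
  expect_identical(v[["stage_cue"]], 0L)
  expect_identical(v[["weak_label"]], 0L)
  p_ini <- mk_passage(canonical = "European", surface = "German",
                      left = c("in", "the", "discovery", "stage"))
  v2 <- vote_task2_stage(p_ini, rec, cues$initial, cues$replication, 1L)
  expect_identical(v2[["stage_cue"]], 1L)
  expect_identical(v2[["weak_label"]], 1L)
  # ethnicity curated under both stages: weak label defaults to initial
  rec_both <- curated_record("doc1", "stage_ethnicity",
                             tuples = data.frame(stage = c("initial", "replication"),
                                                 ethnicity = c("European", "European")))
  v3 <- vote_task2_stage(p_ini, rec_both, cues$initial, cues$replication, 1L)
  expect_identical(v3[["weak_label"]], 1L)
  # no cue at all: default initial
  p_none <- mk_passage(canonical = "European", surface = "German",
                       left = c("a", "total", "of"))
  v4 <- vote_task2_stage(p_none, rec, cues$initial, cues$replication, 1L)
  expect_identical(v4[["stage_cue"]], 1L)
})

test_that("build_matrix assembles votes and enforces completeness", {
  votes <- data.frame(
    passage_id = rep(c("p1", "p2"), each = 5),
    classifier_id = rep(paste0("c", 1:5), 2),
    vote = c(1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L))
  cm <- build_matrix(votes)
  expect_equal(dim(cm$M), c(2L, 5L))
  # each column reconstructs its classifier's vote sequence
  for (j in 1:5) {
    expect_identical(unname(cm$M[, j]),
                     votes$vote[votes$classifier_id == paste0("c", j)])
  }
  expect_error(build_matrix(rbind(votes, votes[1, ])), "duplicate")
  expect_error(build_matrix(votes[-1, ]), "missing")
  bad <- votes; bad$vote[1] <- 2L
  expect_error(build_matrix(bad), "binary")
})

test_that("permuting passages permutes matrix rows identically", {
  set.seed(2)
  vote_list <- lapply(1:6, function(i)
    stats::setNames(sample(0:1, 3, replace = TRUE), c("a", "b", "c")))
  ids <- paste0("p", 1:6)
  cm <- votes_to_matrix(vote_list, ids)
  perm <- sample(6)
  cm_p <- votes_to_matrix(vote_list[perm], ids[perm])
  expect_identical(cm_p$M, cm$M[perm, ])
})
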