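test_that("article XML round-trip preserves all fields and section order", {
  a <- article("pmid1", title = "Title X", abstract = "An abstract.",
               sections = list(
                 list(title = "Intro", paragraphs = list("First paragraph.", "Second one.")),
                 list(title = "Methods", paragraphs = list("Methods text.")),
                 list(title = "Results", paragraphs = list("Results text."))
               ))
  path <- withr::local_tempfile(fileext = ".xml")
  write_article(a, path)
  b <- read_article(path)
  expect_identical(b$doc_id, "pmid1")
  expect_identical(b$title, a$title)
  expect_identical(b$abstract, a$abstract)
  expect_length(b$sections, 3L)
  expect_identical(vapply(b$sections, `[[`, character(1), "title"),
                   c("Intro", "Methods", "Results"))
  expect_identical(b$sections[[1]]$paragraphs, a$sections[[1]]$paragraphs)
})

test_that("plain-text articles become a single untitled section", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("abc def", path)
  a <- read_article(path)
  expect_identical(a$title, "")
  expect_identical(a$abstract, "")
  expect_length(a$sections, 1L)
  expect_identical(a$sections[[1]]$title, "")
  expect_identical(a$sections[[1]]$paragraphs, "abc def")
  expect_identical(a$source_format, "plain_text")
})

test_that("malformed XML and empty files are rejected with clear errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><sec></article>", bad)
  expect_error(read_article(bad), "malformed")
  empty <- withr::local_tempfile(fileext = ".txt")
  file.create(empty)
  expect_error(read_article(empty), "empty")
})

test_that("whitespace runs are collapsed on read", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0("<article doc-id='x'><article-title>A   title\n here",
                    "</article-title><abstract>ok</abstract>",
                    "<sec><title>S</title><p>p   q</p></sec></article>"), path)
  a <- read_article(path)
  expect_identical(a$title, "A title here")
  expect_identical(a$sections[[1]]$paragraphs, "p q")
})

test_that("curated phenotype rows merge per document", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tDISEASETRAIT",
               "doc1\tObesity",
               "doc1\tBody mass index",
               "doc2\tAsthma"), path)
  recs <- read_curated_table(path, "phenotype")
  expect_length(recs, 2L)
  expect_setequal(recs[["doc1"]]$phenotype_terms, c("Obesity", "Body mass index"))
  expect_identical(recs[["doc2"]]$phenotype_terms, "Asthma")
})

test_that("curated stage values are normalized and tuples merged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tSTAGE\tETHNICITY",
               "doc1\tinitial\tEuropean",
               "doc1\tReplication \tEast Asian",
               "doc1\tinitial\tEuropean"), path)
  recs <- read_curated_table(path, "stage_ethnicity")
  expect_length(recs, 1L)
  tu <- recs[["doc1"]]$tuples
  expect_equal(nrow(tu), 2L)
  expect_setequal(tu$stage, c("initial", "replication"))
})

test_that("curated tables are insensitive to row order", {
  lines <- c("doc1\tinitial\tEuropean", "doc2\treplication\tHan",
             "doc1\treplication\tEast Asian")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tSTAGE\tETHNICITY", lines), p1)
  writeLines(c("DOC_ID\tSTAGE\tETHNICITY", rev(lines)), p2)
  r1 <- read_curated_table(p1, "stage_ethnicity")
  r2 <- read_curated_table(p2, "stage_ethnicity")
  for (id in names(r1)) {
    t1 <- r1[[id]]$tuples; t2 <- r2[[id]]$tuples
    expect_setequal(paste(t1$stage, t1$ethnicity), paste(t2$stage, t2$ethnicity))
  }
})

test_that("schema errors and blank cells are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tTRAIT", "doc1\tX"), path)
  expect_error(read_curated_table(path, "phenotype"), "DISEASETRAIT")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tDISEASETRAIT", "doc1\t", "doc2\tAsthma"), path2)
  expect_warning(recs <- read_curated_table(path2, "phenotype"), "skipped")
  expect_identical(names(recs), "doc2")
})

test_that("ethnicity aliases rewrite curated spellings", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("DOC_ID\tSTAGE\tETHNICITY",
               "doc1\tinitial\tNorth African/Middle East"), path)
  recs <- read_curated_table(path, "stage_ethnicity",
                             aliases = default_ethnicity_aliases())
  expect_identical(recs[["doc1"]]$tuples$ethnicity, "Middle East/North African")
})

test_that("dictionary loading case-folds, collapses duplicates, rejects conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("German\tEuropean", "Germans\tEuropean",
               "han\tEast Asian", "Han\tEast Asian"), path)
  d <- load_dictionary(path)
  expect_length(d$entries, 3L)  # han/Han collapse after case-folding
  expect_setequal(unique(unname(d$entries)), c("European", "East Asian"))

  conflict <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("han\tEast Asian", "Han\tChinese"), conflict)
  expect_error(load_dictionary(conflict), "conflicting.*han")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_dictionary(empty), "empty")
})

test_that("dictionary load -> dump -> load is a fixed point", {
  d <- default_ethnicity_dictionary()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  dump_dictionary(d, p1)
  d2 <- load_dictionary(p1)
  expect_identical(d2$entries, d$entries)
})

test_that("gzip-compressed inputs are accepted", {
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  writeLines(c("DOC_ID\tDISEASETRAIT", "doc1\tObesity"), con)
  close(con)
  recs <- read_curated_table(path, "phenotype")
  expect_identical(recs[["doc1"]]$phenotype_terms, "Obesity")
})

test_that("curly typography is normalized to ASCII", {
  expect_identical(normalize_typography("“Parkinson’s” – x"),
                   "\"Parkinson's\" - x")
})
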