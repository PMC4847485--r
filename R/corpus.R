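# Domain types and readers/writers for articles, curated tables, term
# dictionaries and rule lexicons.
#
# Articles travel in a deliberately minimal XML dialect:
#   <article doc-id="..."><article-title/><abstract/>
#     <sec><title/><p/>...</sec>...</article>
# Real full-text formats (JATS/NXML, transcribed PDF) are converted to this
# dialect upstream; parsing them is out of scope here.

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Construct an article
#'
#' @param doc_id non-empty document identifier.
#' @param title,abstract plain text (may be empty).
#' @param sections list of `list(title =, paragraphs = character())`.
#' @param source_format `"structured_xml"` or `"plain_text"`.
#' @return an object of class `curex_article`.
#' @export
article <- function(doc_id, title = "", abstract = "", sections = list(),
                    source_format = c("structured_xml", "plain_text")) {
  source_format <- match.arg(source_format)
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string", call. = FALSE)
  }
  norm <- function(x) normalize_ws(normalize_typography(x))
  sections <- lapply(sections, function(s) {
    list(title = norm(s$title %||% ""),
         paragraphs = vapply(s$paragraphs, norm, character(1), USE.NAMES = FALSE))
  })
  structure(
    list(doc_id = doc_id, title = norm(title), abstract = norm(abstract),
         sections = sections, source_format = source_format),
    class = "curex_article"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.curex_article <- function(x, ...) {
  cat(sprintf("<curex_article %s: %d section(s), title %s>\n",
              x$doc_id, length(x$sections),
              if (nzchar(x$title)) shQuote(x$title) else "(none)"))
  invisible(x)
}

#' Read an article file
#'
#' Structured-XML files must follow the minimal dialect above; plain-text
#' files become a single untitled section with empty title and abstract,
#' paragraphs split at blank lines. Gzip-compressed variants (`.gz`) are
#' accepted. Whitespace runs are collapsed to single spaces on read.
#'
#' @param path path to the file.
#' @param format `"structured_xml"` or `"plain_text"`; by default inferred
#'   from the extension (`.xml` vs anything else).
#' @param doc_id identifier to use; defaults to the `doc-id` attribute
#'   (XML) or the file base name.
#' @return a [article()] object.
#' @export
read_article <- function(path, format = NULL, doc_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  base <- sub("\\.gz$", "", basename(path))
  if (is.null(format)) {
    format <- if (grepl("\\.xml$", base, ignore.case = TRUE)) "structured_xml" else "plain_text"
  }
  format <- match.arg(format, c("structured_xml", "plain_text"))
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("empty input file: ", path, call. = FALSE)
  }
  if (format == "structured_xml") {
    doc <- tryCatch(
      xml2::read_xml(paste(lines, collapse = "\n")),
      error = function(e) stop("malformed article XML in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (xml2::xml_name(doc) != "article") {
      stop("malformed article XML in ", path, ": root element must be <article>",
           call. = FALSE)
    }
    id <- doc_id %||% xml2::xml_attr(doc, "doc-id")
    if (is.na(id) || is.null(id) || !nzchar(id)) id <- tools::file_path_sans_ext(base)
    title <- xml2::xml_text(xml2::xml_find_first(doc, "./article-title"))
    abstract <- xml2::xml_text(xml2::xml_find_first(doc, "./abstract"))
    secs <- lapply(xml2::xml_find_all(doc, "./sec"), function(s) {
      list(title = xml2::xml_text(xml2::xml_find_first(s, "./title")),
           paragraphs = xml2::xml_text(xml2::xml_find_all(s, "./p")))
    })
    secs <- lapply(secs, function(s) {
      s$title <- if (is.na(s$title)) "" else s$title
      s
    })
    article(id, title = ifelse(is.na(title), "", title),
            abstract = ifelse(is.na(abstract), "", abstract),
            sections = secs, source_format = "structured_xml")
  } else {
    id <- doc_id %||% tools::file_path_sans_ext(base)
    text <- paste(lines, collapse = "\n")
    paras <- strsplit(text, "\n[ \t]*\n+")[[1]]
    paras <- paras[nzchar(trimws(paras))]
    article(id, title = "", abstract = "",
            sections = list(list(title = "", paragraphs = paras)),
            source_format = "plain_text")
  }
}

#' Write an article in the minimal XML dialect
#'
#' @param a a [article()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_article <- function(a, path) {
  stopifnot(inherits(a, "curex_article"))
  doc <- xml2::xml_new_root("article", "doc-id" = a$doc_id)
  xml2::xml_add_child(doc, "article-title", a$title)
  xml2::xml_add_child(doc, "abstract", a$abstract)
  for (s in a$sections) {
    sec <- xml2::xml_add_child(doc, "sec")
    xml2::xml_add_child(sec, "title", s$title)
    for (p in s$paragraphs) xml2::xml_add_child(sec, "p", p)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- curated records ------------------------------------------------------

#' Construct a curated record
#'
#' A curated record holds what a database curator recorded for one article:
#' for the phenotype task a set of disease/trait terms; for the
#' stage-ethnicity task a set of `(stage, ethnicity)` tuples, with stage
#' restricted to `"initial"` and `"replication"`.
#'
#' @param doc_id document identifier.
#' @param task `"phenotype"` or `"stage_ethnicity"`.
#' @param phenotype_terms character vector of curated phenotype terms.
#' @param tuples data frame with columns `stage`, `ethnicity`.
#' @return an object of class `curex_record`.
#' @export
curated_record <- function(doc_id, task = c("phenotype", "stage_ethnicity"),
                           phenotype_terms = character(),
                           tuples = data.frame(stage = character(),
                                               ethnicity = character())) {
  task <- match.arg(task)
  if (task == "phenotype") {
    phenotype_terms <- unique(normalize_ws(normalize_typography(phenotype_terms)))
    if (length(phenotype_terms) == 0L) {
      stop("curated phenotype record needs at least one term", call. = FALSE)
    }
  } else {
    tuples$stage <- tolower(trimws(tuples$stage))
    bad <- setdiff(unique(tuples$stage), c("initial", "replication"))
    if (length(bad)) stop("invalid stage value(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    tuples$ethnicity <- normalize_ws(normalize_typography(tuples$ethnicity))
    tuples <- unique(tuples[, c("stage", "ethnicity")])
    rownames(tuples) <- NULL
    if (nrow(tuples) == 0L) {
      stop("curated stage-ethnicity record needs at least one tuple", call. = FALSE)
    }
  }
  structure(list(doc_id = doc_id, task = task,
                 phenotype_terms = phenotype_terms, tuples = tuples),
            class = "curex_record")
}

#' Read a curated table
#'
#' Tab-separated with a header. Required columns: `DOC_ID`, `DISEASETRAIT`
#' for the phenotype task; `DOC_ID`, `STAGE`, `ETHNICITY` for the
#' stage-ethnicity task. Multiple rows for a document are merged into one
#' record; duplicate rows collapse silently; rows with a blank required cell
#' are skipped with a warning. Values are trimmed and typography-normalized;
#' stages are case-folded to the `initial`/`replication` enum. An optional
#' alias table (named character vector, alias -> canonical, matched
#' case-insensitively) rewrites ethnicity spellings before merging.
#'
#' @param path TSV path (`.gz` accepted).
#' @param task `"phenotype"` or `"stage_ethnicity"`.
#' @param aliases named character vector of ethnicity aliases.
#' @return named list of [curated_record()]s, keyed by `doc_id`.
#' @export
read_curated_table <- function(path, task = c("phenotype", "stage_ethnicity"),
                               aliases = character()) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .open_text(path)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  required <- if (task == "phenotype") c("DOC_ID", "DISEASETRAIT") else
    c("DOC_ID", "STAGE", "ETHNICITY")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("curated table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in required) df[[col]] <- normalize_ws(normalize_typography(df[[col]]))
  blank <- Reduce(`|`, lapply(required, function(col) !nzchar(df[[col]])))
  if (any(blank)) {
    warning(sum(blank), " row(s) with blank required cells skipped", call. = FALSE)
    df <- df[!blank, , drop = FALSE]
  }
  if (task == "stage_ethnicity" && length(aliases)) {
    hit <- match(tolower(df$ETHNICITY), tolower(names(aliases)))
    df$ETHNICITY[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out <- list()
  for (id in unique(df$DOC_ID)) {
    rows <- df[df$DOC_ID == id, , drop = FALSE]
    if (task == "phenotype") {
      # case-insensitive dedup, original casing of first occurrence retained
      terms <- rows$DISEASETRAIT[!duplicated(tolower(rows$DISEASETRAIT))]
      out[[id]] <- curated_record(id, "phenotype", phenotype_terms = terms)
    } else {
      out[[id]] <- curated_record(
        id, "stage_ethnicity",
        tuples = data.frame(stage = tolower(rows$STAGE),
                            ethnicity = rows$ETHNICITY,
                            stringsAsFactors = FALSE)
      )
    }
  }
  out
}

#' Write a curated table
#' @param records named list of [curated_record()]s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curated_table <- function(records, path) {
  task <- records[[1]]$task
  rows <- do.call(rbind, lapply(records, function(r) {
    if (task == "phenotype") {
      data.frame(DOC_ID = r$doc_id, DISEASETRAIT = r$phenotype_terms,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(DOC_ID = r$doc_id, STAGE = r$tuples$stage,
                 ETHNICITY = r$tuples$ethnicity, stringsAsFactors = FALSE)
    }
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- term dictionaries and rule lexicons ----------------------------------

#' Construct a term dictionary
#'
#' Maps case-folded surface terms to canonical entity strings (many-to-one),
#' e.g. demonyms and adjectivals to top-level ethnicity groups.
#'
#' @param entries named character vector: `names()` are surface terms,
#'   values are canonical entities.
#' @param name dictionary label.
#' @return an object of class `curex_dictionary`.
#' @export
term_dictionary <- function(entries, name = "dictionary") {
  if (length(entries) == 0L) stop("empty dictionary: ", name, call. = FALSE)
  terms <- case_fold(names(entries))
  if (any(!nzchar(terms))) stop("dictionary contains empty terms", call. = FALSE)
  vals <- normalize_ws(normalize_typography(unname(entries)))
  keep <- !duplicated(paste(terms, vals, sep = "\r"))
  terms <- terms[keep]; vals <- vals[keep]
  dup <- terms[duplicated(terms)]
  if (length(dup)) {
    stop("conflicting dictionary entries for term(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  o <- order(terms)
  structure(list(entries = stats::setNames(vals[o], terms[o]), name = name),
            class = "curex_dictionary")
}

#' @exportS3Method base::print
print.curex_dictionary <- function(x, ...) {
  cat(sprintf("<curex_dictionary %s: %d terms -> %d entities>\n",
              x$name, length(x$entries), length(unique(x$entries))))
  invisible(x)
}

#' Load a term dictionary from a two-column TSV
#'
#' Column 1 is the surface term, column 2 the canonical entity; no header.
#' Terms are case-folded; identical duplicate rows collapse; a term mapped
#' to two different entities is a hard error (a silently resolved conflict
#' would corrupt the weak labels downstream).
#'
#' @param path TSV path (`.gz` accepted).
#' @param name dictionary label, defaults to the file base name.
#' @return a [term_dictionary()].
#' @export
load_dictionary <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  name <- name %||% tools::file_path_sans_ext(sub("\\.gz$", "", basename(path)))
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty dictionary file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("dictionary rows must have two tab-separated columns: ", path, call. = FALSE)
  }
  term_dictionary(
    stats::setNames(vapply(parts, `[[`, character(1), 2L),
                    vapply(parts, `[[`, character(1), 1L)),
    name = name
  )
}

#' Write a term dictionary as two-column TSV
#' @param dict a [term_dictionary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "curex_dictionary"))
  writeLines(paste(names(dict$entries), dict$entries, sep = "\t"), path)
  invisible(path)
}

#' Construct a rule lexicon
#'
#' A flat set of case-folded cue terms used by the rule-based committee
#' members (sample-description words, stage cues).
#'
#' @param terms character vector of terms.
#' @param purpose `"sample_description"`, `"initial_cue"` or `"replication_cue"`.
#' @return an object of class `curex_lexicon`.
#' @export
rule_lexicon <- function(terms,
                         purpose = c("sample_description", "initial_cue",
                                     "replication_cue")) {
  purpose <- match.arg(purpose)
  terms <- sort(unique(case_fold(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("empty rule lexicon", call. = FALSE)
  structure(list(terms = terms, purpose = purpose), class = "curex_lexicon")
}

#' Load a rule lexicon (one term per line)
#' @param path path (`.gz` accepted).
#' @param purpose lexicon purpose, see [rule_lexicon()].
#' @return a [rule_lexicon()].
#' @export
load_lexicon <- function(path, purpose = "sample_description") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .open_text(path)
  on.exit(close(con))
  rule_lexicon(readLines(con, warn = FALSE, encoding = "UTF-8"), purpose = purpose)
}
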