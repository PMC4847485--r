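# Passage extraction: dictionary-based mention matching and context-window
# construction around each mention. Char spans are 0-based half-open into the
# concatenated document text.

# Flatten an article into one text with a segment table (title, abstract,
# one segment per body paragraph) and a global sentence table. Segments are
# joined by a single space; sentences never cross a segment boundary.
doc_model <- function(a) {
  stopifnot(inherits(a, "curex_article"))
  parts <- list(list(part = "title", section_title = "", text = a$title,
                     section_index = 0L))
  parts <- c(parts, list(list(part = "abstract", section_title = "",
                              text = a$abstract, section_index = 0L)))
  si <- 0L
  for (s in a$sections) {
    si <- si + 1L
    for (p in s$paragraphs) {
      parts <- c(parts, list(list(part = "body", section_title = s$title,
                                  text = p, section_index = si)))
    }
  }
  parts <- Filter(function(x) nzchar(x$text), parts)
  if (length(parts) == 0L) {
    return(list(doc_id = a$doc_id, text = "",
                segments = data.frame(part = character(), section_title = character(),
                                      section_index = integer(), start = integer(),
                                      end = integer()),
                sentences = data.frame(start = integer(), end = integer())))
  }
  texts <- vapply(parts, `[[`, character(1), "text")
  lens <- nchar(texts)
  starts <- cumsum(c(0L, head(lens + 1L, -1L)))  # +1 for the joining space
  segments <- data.frame(
    part = vapply(parts, `[[`, character(1), "part"),
    section_title = vapply(parts, `[[`, character(1), "section_title"),
    section_index = vapply(parts, `[[`, integer(1), "section_index"),
    start = starts, end = starts + lens,
    stringsAsFactors = FALSE
  )
  sentences <- do.call(rbind, lapply(seq_along(texts), function(i) {
    s <- split_sentences(texts[i])
    if (nrow(s) == 0L) return(NULL)
    data.frame(start = s$start + starts[i], end = s$end + starts[i])
  }))
  if (is.null(sentences)) sentences <- data.frame(start = integer(), end = integer())
  list(doc_id = a$doc_id, text = paste(texts, collapse = " "),
       segments = segments, sentences = sentences)
}

.empty_mentions <- function() {
  data.frame(doc_id = character(), surface = character(), canonical = character(),
             start = integer(), end = integer(), location = character(),
             section_title = character(), section_index = integer(),
             sentence_index = integer(), stringsAsFactors = FALSE)
}

#' Match dictionary terms in an article
#'
#' Case-insensitive, word-boundary-anchored exact string matching of every
#' dictionary surface term against the article text. A hyphen inside a term
#' or the text is treated as a space, so "African-American" and "African
#' American" are interchangeable. Overlapping candidates are resolved
#' longest-match-first, then leftmost (so "type 2 diabetes" suppresses the
#' embedded "diabetes").
#'
#' @param a a [article()] object.
#' @param dict a [term_dictionary()].
#' @return data frame of mentions: `doc_id`, `surface`, `canonical`,
#'   `start`, `end` (0-based half-open into the concatenated text),
#'   `location` (`title`/`abstract`/`body`), `section_title`,
#'   `section_index`, `sentence_index`.
#' @export
match_mentions <- function(a, dict) {
  stopifnot(inherits(dict, "curex_dictionary"))
  dm <- doc_model(a)
  if (!nzchar(dm$text)) return(.empty_mentions())
  norm <- matching_form(dm$text)
  cand <- list()
  for (i in seq_along(dict$entries)) {
    term <- matching_form(names(dict$entries)[i])
    if (nchar(term) > nchar(norm)) next
    rx <- paste0("(?<![[:alnum:]])", rx_escape(term), "(?![[:alnum:]])")
    m <- gregexpr(rx, norm, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = as.integer(m) - 1L,
      len = attr(m, "match.length"),
      canonical = unname(dict$entries[i]),
      stringsAsFactors = FALSE
    )
  }
  if (length(cand) == 0L) return(.empty_mentions())
  cand <- do.call(rbind, cand)
  cand$end <- cand$start + cand$len
  # a match must lie inside a single segment (joining spaces are not text)
  seg_idx <- findInterval(cand$start, dm$segments$start)
  inside <- cand$end <= dm$segments$end[seg_idx]
  cand <- cand[inside, , drop = FALSE]
  seg_idx <- seg_idx[inside]
  if (nrow(cand) == 0L) return(.empty_mentions())
  o <- order(-cand$len, cand$start, cand$canonical)
  cand <- cand[o, , drop = FALSE]
  seg_idx <- seg_idx[o]
  occupied <- logical(nchar(norm))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  seg_idx <- seg_idx[keep]
  o <- order(cand$start)
  cand <- cand[o, , drop = FALSE]
  seg_idx <- seg_idx[o]
  sent_idx <- if (nrow(dm$sentences)) {
    findInterval(cand$start, dm$sentences$start)
  } else {
    rep.int(1L, nrow(cand))
  }
  out <- data.frame(
    doc_id = dm$doc_id,
    surface = substring(dm$text, cand$start + 1L, cand$end),
    canonical = cand$canonical,
    start = cand$start, end = cand$end,
    location = dm$segments$part[seg_idx],
    section_title = dm$segments$section_title[seg_idx],
    section_index = dm$segments$section_index[seg_idx],
    sentence_index = as.integer(sent_idx),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract context-window passages around mentions
#'
#' Takes up to 10 tokens on either side of each mention. Under the
#' `within_sentence` policy the window is clipped at the mention's sentence
#' boundaries (the convention for stage-ethnicity extraction); under
#' `cross_sentence` it is not (the convention for phenotype extraction).
#'
#' Each passage also carries the positional quantities used later as
#' features: the mention's normalized offset from the article start and
#' from its section start, and how often its canonical entity is mentioned
#' in the same article.
#'
#' @param mentions data frame from [match_mentions()].
#' @param a the same [article()] the mentions came from.
#' @param policy `"cross_sentence"` or `"within_sentence"`.
#' @param window tokens per side (default 10).
#' @return list of `curex_passage` objects.
#' @export
extract_passages <- function(mentions, a,
                             policy = c("cross_sentence", "within_sentence"),
                             window = 10L) {
  policy <- match.arg(policy)
  dm <- doc_model(a)
  if (nrow(mentions) == 0L) return(list())
  stopifnot(all(mentions$doc_id == dm$doc_id))
  toks <- tokenize_spans(dm$text)
  doc_len <- max(1L, nchar(dm$text))
  counts <- table(mentions$canonical)
  lapply(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, ]
    lo <- m$start; hi <- m$end
    if (policy == "within_sentence" && nrow(dm$sentences) >= m$sentence_index &&
        m$sentence_index >= 1L) {
      s <- dm$sentences[m$sentence_index, ]
      lo_bound <- s$start; hi_bound <- s$end
    } else {
      lo_bound <- 0L; hi_bound <- nchar(dm$text)
    }
    left <- toks$token[toks$end <= lo & toks$start >= lo_bound]
    right <- toks$token[toks$start >= hi & toks$end <= hi_bound]
    if (length(left) > window) left <- utils::tail(left, window)
    if (length(right) > window) right <- utils::head(right, window)
    seg <- dm$segments[dm$segments$start <= m$start &
                         dm$segments$end >= m$end, , drop = FALSE][1, ]
    sec_len <- max(1L, seg$end - seg$start)
    structure(
      list(doc_id = m$doc_id, surface = m$surface, canonical = m$canonical,
           start = m$start, end = m$end, location = m$location,
           section_title = m$section_title, sentence_index = m$sentence_index,
           left_context = left, right_context = right, window_policy = policy,
           frac_doc = m$start / doc_len,
           frac_section = (m$start - seg$start) / sec_len,
           n_entity_in_doc = as.integer(counts[[m$canonical]])),
      class = "curex_passage"
    )
  })
}

#' @exportS3Method base::print
print.curex_passage <- function(x, ...) {
  cat(sprintf("<curex_passage %s [%d,%d) %s -> %s | %d+%d context tokens>\n",
              x$doc_id, x$start, x$end, shQuote(x$surface), x$canonical,
              length(x$left_context), length(x$right_context)))
  invisible(x)
}

# Serialize passages to JSON-lines (one object per line).
#' Write passages as JSON-lines
#' @param passages list of passages from [extract_passages()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_passages <- function(passages, path) {
  lines <- vapply(passages, function(p) {
    jsonlite::toJSON(unclass(p), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
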