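# Low-level text utilities shared by the readers, the matcher and the
# featurizer. All coordinates are 0-based, half-open character spans.

#' Normalize typography to ASCII
#'
#' Curated tables and transcribed article text mix curly quotes, long dashes
#' and non-breaking spaces with their ASCII counterparts; mapping them to
#' ASCII keeps string matching honest. The mapping is length-preserving so
#' character offsets computed on normalized text remain valid on the input.
#'
#' @param x character vector.
#' @return character vector with typographic characters replaced by ASCII.
#' @export
normalize_typography <- function(x) {
  from <- c("‘", "’", "“", "”", "–", "—", " ")
  to <- c("'", "'", "\"", "\"", "-", "-", " ")
  for (i in seq_along(from)) x <- gsub(from[i], to[i], x, fixed = TRUE)
  x
}

#' Collapse runs of whitespace to single spaces and trim
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_ws <- function(x) {
  trimws(gsub("[ \t\r\n]+", " ", x))
}

# Case-fold for matching keys. Display strings keep their original casing.
case_fold <- function(x) tolower(normalize_ws(normalize_typography(x)))

# Length-preserving matching form of running text: lower case, hyphens
# treated as spaces so "African-American" matches "African American".
matching_form <- function(x) chartr("-", " ", tolower(x))

rx_escape <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)

#' Tokenize text, keeping character spans
#'
#' Tokens are maximal alphanumeric runs, with internal apostrophes allowed
#' ("Parkinson's" is one token). Spans are 0-based half-open.
#'
#' @param text a single string.
#' @return data frame with columns `token`, `start`, `end`.
#' @export
tokenize_spans <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+(?:'[[:alnum:]]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(
    token = substring(text, m, m + len - 1L),
    start = start,
    end = start + len,
    stringsAsFactors = FALSE
  )
}

# Plain token vector (lower-cased), digits collapsed to a placeholder so
# arbitrary sample sizes do not inflate the feature vocabulary.
tokens_of <- function(text, fold = TRUE, collapse_digits = FALSE) {
  tk <- tokenize_spans(text)$token
  if (fold) tk <- tolower(tk)
  if (collapse_digits) tk[grepl("^[0-9]+$", tk)] <- "#num"
  tk
}

#' Split text into sentences
#'
#' Rule-based splitter: a sentence ends at a run of `.`, `!` or `?` followed
#' by whitespace and an upper-case letter or digit. Abbreviation handling is
#' deliberately minimal. Spans are 0-based half-open into `text`.
#'
#' @param text a single string.
#' @return data frame with columns `start`, `end`, one row per sentence.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- gregexpr("[.!?]+(?=[ \t]+[A-Z0-9])", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1L) integer() else as.integer(m) + attr(m, "match.length") - 1L
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  out <- data.frame(start = starts - 1L, end = ends)
  out[out$end > out$start, , drop = FALSE]
}

## ---- Porter stemmer -------------------------------------------------------
## The classic (1980) suffix-stripping algorithm, used for the stage-ethnicity
## context features. Operates on lower-case ASCII words; anything else is
## returned unchanged.

ps_is_cons <- function(chs, i) {
  ch <- chs[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!ps_is_cons(chs, i - 1L))
  }
  TRUE
}

ps_measure <- function(chs) {
  n <- length(chs)
  if (n == 0L) return(0L)
  cats <- vapply(seq_len(n), function(i) ps_is_cons(chs, i), logical(1))
  r <- rle(cats)$values
  if (length(r) < 2L) return(0L)
  sum(!r[-length(r)] & r[-1L])
}

ps_has_vowel <- function(chs) {
  n <- length(chs)
  n > 0L && any(!vapply(seq_len(n), function(i) ps_is_cons(chs, i), logical(1)))
}

ps_double_cons <- function(chs) {
  n <- length(chs)
  n >= 2L && chs[n] == chs[n - 1L] && ps_is_cons(chs, n)
}

ps_cvc <- function(chs) {
  n <- length(chs)
  n >= 3L && ps_is_cons(chs, n) && !ps_is_cons(chs, n - 1L) &&
    ps_is_cons(chs, n - 2L) && !(chs[n] %in% c("w", "x", "y"))
}

ps_ends <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw > ns && substring(w, nw - ns + 1L, nw) == suf
}

ps_stem_part <- function(w, suf) substring(w, 1L, nchar(w) - nchar(suf))

ps_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

porter_stem_word <- function(w) {
  if (nchar(w) <= 2L || !grepl("^[a-z]+$", w)) return(w)

  # step 1a
  if (ps_ends(w, "sses")) {
    w <- ps_stem_part(w, "es")
  } else if (ps_ends(w, "ies")) {
    w <- paste0(ps_stem_part(w, "ies"), "i")
  } else if (!ps_ends(w, "ss") && ps_ends(w, "s")) {
    w <- ps_stem_part(w, "s")
  }

  # step 1b
  adjust <- FALSE
  if (ps_ends(w, "eed")) {
    if (ps_measure(ps_chars(ps_stem_part(w, "eed"))) > 0L) w <- ps_stem_part(w, "d")
  } else if (ps_ends(w, "ed") && ps_has_vowel(ps_chars(ps_stem_part(w, "ed")))) {
    w <- ps_stem_part(w, "ed")
    adjust <- TRUE
  } else if (ps_ends(w, "ing") && ps_has_vowel(ps_chars(ps_stem_part(w, "ing")))) {
    w <- ps_stem_part(w, "ing")
    adjust <- TRUE
  }
  if (adjust) {
    chs <- ps_chars(w)
    if (ps_ends(w, "at") || ps_ends(w, "bl") || ps_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (ps_double_cons(chs) && !(chs[length(chs)] %in% c("l", "s", "z"))) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (ps_measure(chs) == 1L && ps_cvc(chs)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (ps_ends(w, "y") && ps_has_vowel(ps_chars(ps_stem_part(w, "y")))) {
    w <- paste0(ps_stem_part(w, "y"), "i")
  }

  apply_rules <- function(w, rules, cond) {
    for (i in seq_len(nrow(rules))) {
      suf <- rules$suf[i]
      if (ps_ends(w, suf)) {
        stem <- ps_stem_part(w, suf)
        if (cond(stem)) w <- paste0(stem, rules$rep[i])
        return(w)
      }
    }
    w
  }

  # step 2
  rules2 <- data.frame(
    suf = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
            "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
            "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
    rep = c("ate", "tion", "ence", "ance", "ize", "able", "al",
            "ent", "e", "ous", "ize", "ate", "ate", "al",
            "ive", "ful", "ous", "al", "ive", "ble"),
    stringsAsFactors = FALSE
  )
  w <- apply_rules(w, rules2, function(stem) ps_measure(ps_chars(stem)) > 0L)

  # step 3
  rules3 <- data.frame(
    suf = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    rep = c("ic", "", "al", "ic", "ic", "", ""),
    stringsAsFactors = FALSE
  )
  w <- apply_rules(w, rules3, function(stem) ps_measure(ps_chars(stem)) > 0L)

  # step 4
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (ps_ends(w, suf)) {
      stem <- ps_stem_part(w, suf)
      ok <- ps_measure(ps_chars(stem)) > 1L
      if (suf == "ion") {
        ok <- ok && nchar(stem) > 0L &&
          substring(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (ps_ends(w, "e")) {
    stem <- ps_stem_part(w, "e")
    m <- ps_measure(ps_chars(stem))
    if (m > 1L || (m == 1L && !ps_cvc(ps_chars(stem)))) w <- stem
  }

  # step 5b
  chs <- ps_chars(w)
  if (ps_measure(chs) > 1L && ps_double_cons(chs) && chs[length(chs)] == "l") {
    w <- substring(w, 1L, nchar(w) - 1L)
  }

  w
}

#' Porter-stem a vector of words
#'
#' @param words character vector of (ideally lower-case ASCII) words.
#' @return character vector of stems, same length.
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}

# Seeded RNG scope: every source of randomness in the package flows through
# this helper so one root seed reproduces a run exactly.
with_seed <- function(seed, code) withr::with_seed(seed, code)
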