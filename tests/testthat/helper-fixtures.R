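# Shared fixtures and independent brute-force oracles used across tests.

tiny_article <- function(doc_id = "d1",
                         title = "Study of type 2 diabetes",
                         abstract = "Patients with type 2 diabetes were enrolled.",
                         body = "German and Germans with African-American ancestry. Diabetes was frequent.") {
  article(doc_id, title = title, abstract = abstract,
          sections = list(list(title = "Methods", paragraphs = list(body))))
}

# quadratic-time dictionary matcher: every word-boundary occurrence of every
# term (hyphen == space, case-insensitive), no overlap resolution
brute_force_occurrences <- function(text, terms) {
  norm <- chartr("-", " ", tolower(text))
  is_alnum <- function(ch) grepl("[[:alnum:]]", ch)
  out <- list()
  for (term in terms) {
    t <- chartr("-", " ", tolower(term))
    nt <- nchar(t)
    if (nt > nchar(norm)) next
    for (s in seq_len(nchar(norm) - nt + 1L)) {
      if (substring(norm, s, s + nt - 1L) != t) next
      before <- if (s > 1L) substring(norm, s - 1L, s - 1L) else ""
      after <- if (s + nt <= nchar(norm)) substring(norm, s + nt, s + nt) else ""
      if ((before == "" || !is_alnum(before)) && (after == "" || !is_alnum(after))) {
        out[[length(out) + 1L]] <- data.frame(term = term, start = s - 1L,
                                              end = s - 1L + nt)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(term = character(), start = integer(), end = integer())
}

# scalar-loop re-implementation of the EM update recurrences
brute_force_em <- function(M, k = 1, K = 2, kp = 1, Kp = 2, tol = 1e-6,
                           max_iter = 100L, variant = "disagreement") {
  I <- nrow(M); J <- ncol(M)
  e <- rep(0, J)
  p_old <- rep(NA_real_, I)
  for (t in seq_len(max_iter)) {
    p <- numeric(I)
    for (i in seq_len(I)) {
      acc <- 0
      for (j in seq_len(J)) acc <- acc + (1 - e[j]) * M[i, j]
      p[i] <- (acc + k) / (J + K)
    }
    for (j in seq_len(J)) {
      acc <- 0
      for (i in seq_len(I)) {
        acc <- acc + if (variant == "disagreement") {
          p[i] * (1 - M[i, j]) + (1 - p[i]) * M[i, j]
        } else {
          p[i] * M[i, j]
        }
      }
      e[j] <- (acc + kp) / (I + Kp)
    }
    if (t > 1L && max(abs(p - p_old)) < tol) {
      return(list(p = p, e = e, iterations = t, converged = TRUE))
    }
    p_old <- p
  }
  list(p = p_old, e = e, iterations = max_iter, converged = FALSE)
}

# brute-force tuple metrics from explicit set comparison
brute_force_micro <- function(pred, gold) {
  docs <- union(pred$doc_id, gold$doc_id)
  tp <- fp <- fn <- 0L
  for (d in docs) {
    pk <- unique(tolower(paste(pred$stage[pred$doc_id == d],
                               pred$ethnicity[pred$doc_id == d])))
    gk <- unique(tolower(paste(gold$stage[gold$doc_id == d],
                               gold$ethnicity[gold$doc_id == d])))
    tp <- tp + length(intersect(pk, gk))
    fp <- fp + length(setdiff(pk, gk))
    fn <- fn + length(setdiff(gk, pk))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

random_tuple_frame <- function(n_docs, max_tuples = 3L) {
  groups <- c("European", "East Asian", "South Asian", "African American")
  rows <- list()
  for (d in seq_len(n_docs)) {
    k <- sample(0:max_tuples, 1L)
    if (k == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = sprintf("doc%02d", d),
      stage = sample(c("initial", "replication"), k, replace = TRUE),
      ethnicity = sample(groups, k, replace = TRUE))
  }
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(doc_id = character(), stage = character(), ethnicity = character())
}

small_task2_corpus <- function(n_docs = 24L, seed = 11L, label_noise = 0.3) {
  gen_task2_corpus(corpus_sim_config(n_docs = n_docs, label_noise = label_noise,
                                     seed = seed))
}
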