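# Synthetic-data generators. Two kinds of objects are produced: committee
# matrices with known ground truth (to exercise the EM label estimator in
# isolation) and miniature corpora with planted mentions, distractors and
# noisy curated records (to exercise the whole pipeline end to end without
# any external download). Everything is deterministic under its seed.

#' Simulate a committee matrix from known ground truth
#'
#' True labels are drawn with prior `prior_pos`; classifier `j` flips each
#' true label independently with probability `error_rates[j]`
#' (conditionally independent votes, all rates below chance level 0.5).
#'
#' @param I number of passages (rows).
#' @param J number of classifiers (columns).
#' @param prior_pos probability that a passage is truly positive.
#' @param error_rates length-J vector in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `matrix` (a `committee_matrix`), `true_labels`,
#'   `error_rates`.
#' @export
gen_committee_matrix <- function(I, J, prior_pos, error_rates, seed = 0L) {
  stopifnot(I >= 1L, J >= 1L, prior_pos > 0, prior_pos < 1,
            length(error_rates) == J)
  if (any(error_rates < 0 | error_rates >= 0.5)) {
    stop("error rates must lie in [0, 0.5): weak classifiers must beat chance",
         call. = FALSE)
  }
  with_seed(seed, {
    z <- stats::rbinom(I, 1L, prior_pos)
    M <- vapply(seq_len(J), function(j) {
      flip <- stats::rbinom(I, 1L, error_rates[j])
      as.integer(ifelse(flip == 1L, 1L - z, z))
    }, integer(I))
    list(matrix = as_committee_matrix(M), true_labels = z,
         error_rates = error_rates)
  })
}

#' Corpus simulation settings
#'
#' The defaults describe the study conditions the generated corpora
#' emulate: one or two target phenotypes per article (two with probability
#' 0.51, giving 1.51 on average), targets usually visible in the title and
#' abstract, curated terms that frequently diverge from the text (synonym
#' swaps, occasional typos), ethnicity mentions mostly but not always
#' linked to a stage cue in the same sentence, and a substantial fraction
#' of curated records perturbed relative to the textual truth.
#'
#' @param n_docs number of articles.
#' @param n_entities entity vocabulary size cap (defaults to the bundled
#'   vocabulary size).
#' @param mentions_per_doc integer range (length 2) of planted mentions per
#'   target entity.
#' @param target_in_title_prob probability a target is planted in title and
#'   abstract.
#' @param synonym_swap_prob probability the curated term is a synonym of
#'   the planted term rather than the term itself.
#' @param typo_prob probability the curated term carries a one-character
#'   typo.
#' @param label_noise probability a document's curated record is perturbed
#'   (stage flip or ethnicity substitution) relative to the textual truth.
#' @param stage_cue_prob probability a planted tuple gets a sentence that
#'   links the ethnicity to a stage cue.
#' @param seed integer seed.
#' @return an object of class `corpus_sim_config`.
#' @export
corpus_sim_config <- function(n_docs = 100L, n_entities = NULL,
                              mentions_per_doc = c(1L, 3L),
                              target_in_title_prob = 0.9,
                              synonym_swap_prob = 0.3, typo_prob = 0.1,
                              label_noise = 0.3, stage_cue_prob = 0.8,
                              seed = 1L) {
  probs <- c(target_in_title_prob, synonym_swap_prob, typo_prob, label_noise,
             stage_cue_prob)
  stopifnot(n_docs >= 1L, all(probs >= 0 & probs <= 1),
            length(mentions_per_doc) == 2L,
            mentions_per_doc[1] >= 1L,
             mentions_per_doc[2] >= mentions_per_doc[1])
  structure(list(n_docs = as.integer(n_docs), n_entities = n_entities,
                 mentions_per_doc = as.integer(mentions_per_doc),
                 target_in_title_prob = target_in_title_prob,
                 synonym_swap_prob = synonym_swap_prob, typo_prob = typo_prob,
                 label_noise = label_noise, stage_cue_prob = stage_cue_prob,
                 seed = as.integer(seed)),
            class = "corpus_sim_config")
}

# one-character substitution or deletion
.typo <- function(term) {
  n <- nchar(term)
  pos <- sample.int(n, 1L)
  if (stats::runif(1) < 0.5 && n > 3L) {
    paste0(substring(term, 1L, pos - 1L), substring(term, pos + 1L, n))
  } else {
    letter <- sample(letters, 1L)
    paste0(substring(term, 1L, pos - 1L), letter, substring(term, pos + 1L, n))
  }
}

.rint <- function(range) if (range[1] == range[2]) range[1] else
  sample(seq(range[1], range[2]), 1L)

#' Generate a synthetic phenotype-task corpus
#'
#' Each document receives one or two gold phenotypes, planted in the title
#' and abstract with probability `target_in_title_prob` and mentioned
#' repeatedly in the body, alongside distractor phenotype mentions in
#' non-target contexts. The curated term for a target is the canonical
#' name, one of its synonyms (probability `synonym_swap_prob`), or a typo
#' variant (probability `typo_prob`), emulating the terminology mismatch
#' between curated databases and article text.
#'
#' @param cfg a [corpus_sim_config()].
#' @return list with `articles` (named list), `curated` (named record
#'   list), `dictionary` (surface -> canonical, synonyms included),
#'   `synonyms` (the same dictionary, for the synonym committee rule) and
#'   `gold` (named list doc_id -> canonical phenotype terms).
#' @export
gen_task1_corpus <- function(cfg = corpus_sim_config()) {
  vocab <- .phenotype_vocab()
  if (!is.null(cfg$n_entities)) vocab <- vocab[seq_len(min(cfg$n_entities, length(vocab)))]
  canonicals <- names(vocab)
  dict <- default_phenotype_dictionary()
  with_seed(cfg$seed, {
    articles <- list(); curated <- list(); gold <- list()
    for (d in seq_len(cfg$n_docs)) {
      id <- sprintf("T1-%04d", d)
      n_targets <- 1L + stats::rbinom(1L, 1L, 0.51)
      targets <- sample(canonicals, n_targets)
      in_ta <- stats::runif(1) < cfg$target_in_title_prob
      title <- if (in_ta) {
        sprintf("Genome-wide association study of %s in a large cohort", targets[1])
      } else {
        "A genome-wide association scan in a large cohort"
      }
      abstract <- if (in_ta) {
        sprintf(
          "We conducted a genome-wide association study of %s and identified several susceptibility loci.",
          paste(targets, collapse = " and "))
      } else {
        "We conducted a genome-wide association study and identified several susceptibility loci."
      }
      distractors <- sample(setdiff(canonicals, targets),
                            min(3L, length(canonicals) - n_targets))
      intro <- c(
        unlist(lapply(targets, function(t) {
          k <- .rint(cfg$mentions_per_doc)
          rep(sprintf("Genetic factors are known to contribute to %s.", t), k)
        })),
        vapply(distractors, function(t)
          sprintf("Previous work reported risk loci for %s in other settings.", t),
          character(1))
      )
      results <- vapply(targets, function(t)
        sprintf("We observed genome-wide significant association with %s.", t),
        character(1))
      articles[[id]] <- article(
        id, title = title, abstract = abstract,
        sections = list(
          list(title = "Introduction", paragraphs = list(paste(intro, collapse = " "))),
          list(title = "Results", paragraphs = list(paste(results, collapse = " ")))
        ))
      cur_terms <- vapply(targets, function(t) {
        r <- stats::runif(1)
        syns <- vocab[[t]]
        if (r < cfg$synonym_swap_prob && length(syns)) {
          sample(syns, 1L)
        } else if (r < cfg$synonym_swap_prob + cfg$typo_prob) {
          .typo(t)
        } else {
          t
        }
      }, character(1))
      curated[[id]] <- curated_record(id, "phenotype", phenotype_terms = cur_terms)
      gold[[id]] <- targets
    }
    list(articles = articles, curated = curated, dictionary = dict,
         synonyms = dict, gold = gold)
  })
}

#' Generate a synthetic stage-ethnicity corpus
#'
#' Each document receives one to three gold `(stage, ethnicity)` tuples.
#' With probability `stage_cue_prob` a tuple is supported by a sentence
#' that pairs an ethnicity surface term with a stage cue and
#' sample-description words in one sentence; otherwise the mention is
#' unlinked (the sentence names the sample but no stage). Distractor
#' ethnicities appear in non-sample contexts. Curated records start from
#' the gold tuples and are perturbed per document with probability
#' `label_noise` (a stage flip or an ethnicity swapped for a distractor),
#' so the weak labels derived from them are noisy while the returned
#' `gold` stays clean.
#'
#' @param cfg a [corpus_sim_config()].
#' @return list with `articles`, `curated` (noisy), `gold` (clean tuple
#'   data frame), `dictionary`, `sample_lexicon`, `initial_cues`,
#'   `replication_cues`.
#' @export
gen_task2_corpus <- function(cfg = corpus_sim_config()) {
  dict <- default_ethnicity_dictionary()
  groups <- unique(unname(dict$entries))
  surfaces_of <- split(names(dict$entries), unname(dict$entries))
  lex <- default_sample_lexicon()
  cues <- default_stage_lexicons()
  ini_words <- c("discovery", "initial", "screening")
  rep_words <- c("replication", "follow-up", "validation")
  with_seed(cfg$seed, {
    articles <- list(); curated <- list(); gold_rows <- list()
    for (d in seq_len(cfg$n_docs)) {
      id <- sprintf("T2-%04d", d)
      k <- sample(1:3, 1L)
      gsel <- sample(groups, k)
      stages <- c("initial",
                  if (k > 1L) sample(c("initial", "replication"), k - 1L,
                                     replace = TRUE))
      tuples <- data.frame(stage = stages, ethnicity = gsel,
                           stringsAsFactors = FALSE)
      sent <- character()
      for (i in seq_len(k)) {
        surf <- sample(surfaces_of[[gsel[i]]], 1L)
        n <- sample(500:5000, 1L)
        reps <- .rint(cfg$mentions_per_doc)
        for (r in seq_len(reps)) {
          if (stats::runif(1) < cfg$stage_cue_prob) {
            cue <- if (stages[i] == "initial") sample(ini_words, 1L) else
              sample(rep_words, 1L)
            sent <- c(sent, sprintf(
              "In the %s stage we genotyped %d %s participants from the study cohort.",
              cue, n, surf))
          } else {
            sent <- c(sent, sprintf(
              "A total of %d %s individuals were included in the sample.", n, surf))
          }
        }
      }
      n_dis <- sample(1:2, 1L)
      dis <- sample(setdiff(groups, gsel), n_dis)
      dis_surf <- vapply(dis, function(g) sample(surfaces_of[[g]], 1L), character(1))
      sent <- c(sent, vapply(dis_surf, function(s)
        sprintf("Earlier reports in %s groups described inconsistent findings.", s),
        character(1)))
      sent <- sample(sent)  # shuffle sentence order
      articles[[id]] <- article(
        id, title = "Genome-wide association study of a complex trait",
        abstract = "We performed a genome-wide scan with subsequent confirmation analyses.",
        sections = list(list(title = "Subjects and Methods",
                             paragraphs = list(paste(sent, collapse = " ")))))
      gold_rows[[id]] <- data.frame(doc_id = id, stage = tuples$stage,
                                    ethnicity = tuples$ethnicity,
                                    stringsAsFactors = FALSE)
      cur <- tuples
      if (stats::runif(1) < cfg$label_noise) {
        j <- sample.int(nrow(cur), 1L)
        if (stats::runif(1) < 0.5) {
          cur$stage[j] <- ifelse(cur$stage[j] == "initial", "replication", "initial")
        } else {
          cur$ethnicity[j] <- sample(dis, 1L)
        }
      }
      curated[[id]] <- curated_record(id, "stage_ethnicity", tuples = cur)
    }
    gold <- do.call(rbind, gold_rows)
    rownames(gold) <- NULL
    list(articles = articles, curated = curated, gold = gold,
         dictionary = dict, sample_lexicon = lex,
         initial_cues = cues$initial, replication_cues = cues$replication)
  })
}

#' Write a simulated corpus in the package's file formats
#'
#' Emits `articles/<doc>.xml` in the minimal XML dialect, `curated.tsv`,
#' `dictionary.tsv`, `gold.tsv`, and (stage-ethnicity task) the three
#' lexicon files, so generated data exercises the real readers.
#'
#' @param sim result of [gen_task1_corpus()] or [gen_task2_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(sim, dir) {
  dir.create(file.path(dir, "articles"), recursive = TRUE, showWarnings = FALSE)
  for (a in sim$articles) {
    write_article(a, file.path(dir, "articles", paste0(a$doc_id, ".xml")))
  }
  write_curated_table(sim$curated, file.path(dir, "curated.tsv"))
  dump_dictionary(sim$dictionary, file.path(dir, "dictionary.tsv"))
  if (is.data.frame(sim$gold)) {
    utils::write.table(
      data.frame(DOC_ID = sim$gold$doc_id, STAGE = sim$gold$stage,
                 ETHNICITY = sim$gold$ethnicity),
      file.path(dir, "gold.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sim$sample_lexicon$terms, file.path(dir, "sample_lexicon.txt"))
    writeLines(sim$initial_cues$terms, file.path(dir, "initial_cues.txt"))
    writeLines(sim$replication_cues$terms, file.path(dir, "replication_cues.txt"))
  } else {
    rows <- do.call(rbind, lapply(names(sim$gold), function(id)
      data.frame(DOC_ID = id, DISEASETRAIT = sim$gold[[id]])))
    utils::write.table(rows, file.path(dir, "gold.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @param task `"phenotype"` or `"stage_ethnicity"`.
#' @return list in the same shape as the generator output (gold included
#'   when `gold.tsv` is present).
#' @export
read_corpus <- function(dir, task = c("phenotype", "stage_ethnicity")) {
  task <- match.arg(task)
  adir <- file.path(dir, "articles")
  if (!dir.exists(adir)) stop("no articles/ directory under ", dir, call. = FALSE)
  files <- sort(list.files(adir, pattern = "\\.xml(\\.gz)?$", full.names = TRUE))
  articles <- lapply(files, read_article)
  names(articles) <- vapply(articles, `[[`, character(1), "doc_id")
  out <- list(
    articles = articles,
    curated = read_curated_table(file.path(dir, "curated.tsv"), task),
    dictionary = load_dictionary(file.path(dir, "dictionary.tsv"))
  )
  gold_path <- file.path(dir, "gold.tsv")
  if (file.exists(gold_path)) {
    if (task == "stage_ethnicity") {
      g <- utils::read.delim(gold_path, stringsAsFactors = FALSE,
                             colClasses = "character")
      out$gold <- data.frame(doc_id = g$DOC_ID, stage = g$STAGE,
                             ethnicity = g$ETHNICITY, stringsAsFactors = FALSE)
    } else {
      g <- utils::read.delim(gold_path, stringsAsFactors = FALSE,
                             colClasses = "character")
      out$gold <- split(g$DISEASETRAIT, g$DOC_ID)
    }
  }
  if (task == "stage_ethnicity") {
    for (nm in c("sample_lexicon", "initial_cues", "replication_cues")) {
      p <- file.path(dir, paste0(nm, ".txt"))
      if (file.exists(p)) {
        purpose <- switch(nm, sample_lexicon = "sample_description",
                          initial_cues = "initial_cue",
                          replication_cues = "replication_cue")
        out[[nm]] <- load_lexicon(p, purpose)
      }
    }
    out$synonyms <- NULL
  } else {
    out$synonyms <- out$dictionary
  }
  out
}
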