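# EM estimation of label reliability from the committee matrix. The model
# has one scalar error rate per weak classifier and one positive-probability
# per passage; both are smoothed with Laplace pseudo-counts.

#' Laplace priors for the EM updates
#'
#' `k/K` smooths the per-passage update, `k_prime/K_prime` the
#' per-classifier update. Defaults correspond to uniform Beta(1,1)
#' smoothing on both.
#'
#' @param k,K pseudo-count and pseudo-total for the passage update.
#' @param k_prime,K_prime pseudo-count and pseudo-total for the classifier
#'   update.
#' @return an object of class `em_priors`.
#' @export
em_priors <- function(k = 1, K = 2, k_prime = 1, K_prime = 2) {
  stopifnot(k >= 0, K > 0, k <= K, k_prime >= 0, K_prime > 0, k_prime <= K_prime)
  structure(list(k = k, K = K, k_prime = k_prime, K_prime = K_prime),
            class = "em_priors")
}

#' Estimate passage reliabilities and classifier error rates by EM
#'
#' Let `M` be the I x J binary vote matrix, `p_i` the probability that
#' passage `i` is a true positive and `e_j` the error rate of classifier
#' `j`. Starting from `e_j(0) = 0`, the updates alternate
#' \deqn{p_i(t) = (\sum_j (1 - e_j(t-1)) M_{ij} + k) / (J + K)}
#' with, under the default `disagreement` variant,
#' \deqn{e_j(t) = (\sum_i [p_i(t)(1 - M_{ij}) + (1 - p_i(t)) M_{ij}] + k') / (I + K')}
#' i.e. the expected disagreement between classifier `j`'s votes and the
#' current label beliefs. The `paper_literal` variant instead uses
#' \deqn{e_j(t) = (\sum_i p_i(t) M_{ij} + k') / (I + K')}
#' which counts agreement with probable positives as error; it is kept
#' selectable for fidelity experiments (see the methods vignette).
#' Iteration stops when `max_i |p_i(t) - p_i(t-1)| < tol` or at `max_iter`.
#'
#' @param M a `committee_matrix` or plain binary matrix.
#' @param priors an [em_priors()] object.
#' @param tol convergence tolerance on the max absolute change in `p`.
#' @param max_iter iteration cap; non-convergence returns
#'   `converged = FALSE` with the last iterate.
#' @param variant `"disagreement"` (default) or `"paper_literal"`.
#' @return an object of class `label_estimate`: `p_hat`, `e_hat`,
#'   `iterations`, `converged`, `variant`, `priors`, plus the row/column ids.
#' @export
em_estimate <- function(M, priors = em_priors(), tol = 1e-6, max_iter = 100L,
                        variant = c("disagreement", "paper_literal")) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "em_priors"), tol > 0, max_iter >= 1L)
  cm <- as_committee_matrix(M)
  A <- cm$M
  I <- nrow(A); J <- ncol(A)
  e <- rep(0, J)
  p <- rep(NA_real_, I)
  converged <- FALSE
  t <- 0L
  repeat {
    t <- t + 1L
    p_new <- (as.numeric(A %*% (1 - e)) + priors$k) / (J + priors$K)
    e <- if (variant == "disagreement") {
      (as.numeric(crossprod(1 - A, p_new) + crossprod(A, 1 - p_new)) +
         priors$k_prime) / (I + priors$K_prime)
    } else {
      (as.numeric(crossprod(A, p_new)) + priors$k_prime) / (I + priors$K_prime)
    }
    if (t > 1L && max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
    if (t >= max_iter) break
  }
  structure(
    list(p_hat = stats::setNames(p, cm$passage_ids),
         e_hat = stats::setNames(e, cm$classifier_ids),
         iterations = t, converged = converged, variant = variant,
         priors = priors),
    class = "label_estimate"
  )
}

#' @exportS3Method base::print
print.label_estimate <- function(x, ...) {
  cat(sprintf(paste0("<label_estimate: %d passages, %d classifiers; %s variant; ",
                     "%d iteration(s), %sconverged>\n"),
              length(x$p_hat), length(x$e_hat), x$variant, x$iterations,
              if (x$converged) "" else "NOT "))
  cat("  e_hat:", paste(sprintf("%.3f", x$e_hat), collapse = " "), "\n")
  invisible(x)
}

#' Majority vote over the committee matrix
#'
#' Baseline comparator for the EM estimate: label 1 iff strictly more than
#' half the votes are 1; an exact tie also labels 1.
#'
#' @param M a `committee_matrix` or binary matrix.
#' @return integer vector of length I.
#' @export
majority_vote <- function(M) {
  cm <- as_committee_matrix(M)
  as.integer(2L * rowSums(cm$M) >= ncol(cm$M))
}

#' Write a label estimate as TSV
#' @param est a `label_estimate`.
#' @param path output path for per-passage reliabilities; a companion
#'   `<path>.classifiers.tsv` carries the per-classifier error report.
#' @return `path`, invisibly.
#' @export
write_label_estimate <- function(est, path) {
  utils::write.table(
    data.frame(passage_id = names(est$p_hat), p_hat = unname(est$p_hat)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(classifier_id = names(est$e_hat), e_hat = unname(est$e_hat)),
    paste0(path, ".classifiers.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
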