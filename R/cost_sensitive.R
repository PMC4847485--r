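# Importance-reweighting cost assignment and the cost-sensitive linear SVM.
#
# The cost of a noisy-labeled example approximates p(y|x) / p_rho(y|x): the
# EM reliability over the empirical rate of its assigned class. A weighted
# linear SVM then minimizes
#   reg/2 * ||w||^2 + sum_i c_i * max(0, 1 - y_i (w.x_i + b))^2
# i.e. the L2-regularized squared hinge (the common linear-SVM loss), with
# each example's loss scaled by its misclassification cost.

round_half_up <- function(p) as.integer(p >= 0.5)

#' Assign importance-reweighting costs from a label estimate
#'
#' Hard labels are `y_i = round(p_hat_i)` (0.5 rounds up). With
#' `pos_fraction = sum(y)/I`: positives get `c_i = p_hat_i / pos_fraction`;
#' negatives get, under the default `lemma_consistent` variant,
#' `c_i = (1 - p_hat_i) / (1 - pos_fraction)` (the reliability of the
#' negative label over the negative rate), while `paper_literal` uses
#' `c_i = p_hat_i / (1 - pos_fraction)` exactly as printed in the source
#' derivation. When a class is empty its degenerate denominator is
#' replaced by 1.
#'
#' @param est a `label_estimate` or a numeric vector of reliabilities.
#' @param variant `"lemma_consistent"` (default) or `"paper_literal"`.
#' @return an object of class `cost_assignment`: `y`, `c`, `pos_fraction`,
#'   `variant`.
#' @export
assign_costs <- function(est, variant = c("lemma_consistent", "paper_literal")) {
  variant <- match.arg(variant)
  p <- if (inherits(est, "label_estimate")) est$p_hat else est
  if (length(p) == 0L) stop("empty label estimate", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  y <- round_half_up(p)
  pos_fraction <- mean(y)
  denom_pos <- if (pos_fraction > 0) pos_fraction else 1
  denom_neg <- if (pos_fraction < 1) 1 - pos_fraction else 1
  c_i <- numeric(length(p))
  c_i[y == 1L] <- p[y == 1L] / denom_pos
  c_i[y == 0L] <- if (variant == "lemma_consistent") {
    (1 - p[y == 0L]) / denom_neg
  } else {
    p[y == 0L] / denom_neg
  }
  structure(list(y = unname(y), c = unname(c_i), pos_fraction = pos_fraction,
                 variant = variant, passage_ids = names(p)),
            class = "cost_assignment")
}

#' @exportS3Method base::print
print.cost_assignment <- function(x, ...) {
  cat(sprintf("<cost_assignment: %d examples, %.1f%% positive, costs in [%.3g, %.3g], %s>\n",
              length(x$y), 100 * x$pos_fraction, min(x$c), max(x$c), x$variant))
  invisible(x)
}

#' Export costs as TSV for audit
#' @param costs a `cost_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_costs <- function(costs, path) {
  utils::write.table(
    data.frame(passage_id = costs$passage_ids %||% seq_along(costs$y),
               y = costs$y, cost = costs$c),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.svm_objective <- function(theta, x, yy, cw, reg) {
  d <- ncol(x)
  w <- theta[seq_len(d)]
  b <- theta[d + 1L]
  m <- as.numeric(x %*% w) + b
  s <- pmax(0, 1 - yy * m)
  0.5 * reg * sum(w^2) + sum(cw * s^2)
}

.svm_gradient <- function(theta, x, yy, cw, reg) {
  d <- ncol(x)
  w <- theta[seq_len(d)]
  b <- theta[d + 1L]
  m <- as.numeric(x %*% w) + b
  s <- pmax(0, 1 - yy * m)
  g <- -2 * cw * s * yy
  c(reg * w + as.numeric(Matrix::crossprod(x, g)), sum(g))
}

#' Train a cost-weighted L2-regularized linear SVM
#'
#' Deterministic batch optimization (L-BFGS-B from a zero start; no
#' shuffling), so repeated runs give identical models.
#'
#' @param x numeric matrix or `dgCMatrix`, one row per example.
#' @param costs a [assign_costs()] result, or a list with elements `y`
#'   (0/1 labels) and `c` (positive weights).
#' @param reg L2 regularization strength (coefficient of `||w||^2 / 2`).
#' @param tol optimizer tolerance (projected-gradient norm).
#' @param max_iter optimizer iteration cap.
#' @return an object of class `weighted_linear_model`: `weights`, `bias`,
#'   `reg`, `schema_id` (taken from `colnames(x)` fingerprint).
#' @export
train_weighted <- function(x, costs, reg = 1.0, tol = 1e-4, max_iter = 10000L) {
  y <- costs$y
  cw <- costs$c
  stopifnot(nrow(x) == length(y), length(cw) == length(y), all(cw > 0),
            all(is.finite(cw)))
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  yy <- ifelse(y == 1L, 1, -1)
  d <- ncol(x)
  fit <- stats::optim(
    par = numeric(d + 1L),
    fn = .svm_objective, gr = .svm_gradient,
    x = x, yy = yy, cw = cw, reg = reg,
    method = "L-BFGS-B",
    control = list(maxit = max_iter, factr = 1e4, pgtol = tol * 1e-2)
  )
  structure(
    list(weights = stats::setNames(fit$par[seq_len(d)], colnames(x)),
         bias = fit$par[d + 1L], reg = reg, loss = "squared_hinge",
         objective = fit$value, converged = fit$convergence == 0L,
         n_features = d),
    class = "weighted_linear_model"
  )
}

#' @exportS3Method base::print
print.weighted_linear_model <- function(x, ...) {
  cat(sprintf("<weighted_linear_model: %d features, reg = %g, bias = %.4g>\n",
              x$n_features, x$reg, x$bias))
  invisible(x)
}

#' Predict with a weighted linear model
#'
#' @param object a `weighted_linear_model`.
#' @param x feature matrix with the model's feature dimension.
#' @param ... unused.
#' @return data frame with columns `margin` (the linear score) and `label`
#'   (1 iff `margin >= 0`).
#' @export
predict.weighted_linear_model <- function(object, x, ...) {
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature schema mismatch: model has %d features, input %d",
                 object$n_features, ncol(x)), call. = FALSE)
  }
  margin <- as.numeric(x %*% object$weights) + object$bias
  data.frame(margin = margin, label = as.integer(margin >= 0))
}

#' Persist a weighted linear model as JSON (sparse triplets)
#' @param model a `weighted_linear_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  nz <- which(model$weights != 0)
  jsonlite::write_json(
    list(loss = model$loss, reg = model$reg, bias = model$bias,
         n_features = model$n_features,
         index = nz, value = unname(model$weights[nz]),
         name = names(model$weights)[nz]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a persisted weighted linear model
#' @param path JSON path written by [write_model()].
#' @param feature_names optional full feature-name vector to restore names.
#' @return a `weighted_linear_model`.
#' @export
read_model <- function(path, feature_names = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- numeric(obj$n_features)
  w[obj$index] <- obj$value
  if (!is.null(feature_names)) names(w) <- feature_names
  structure(list(weights = w, bias = obj$bias, reg = obj$reg, loss = obj$loss,
                 objective = NA_real_, converged = NA, n_features = obj$n_features),
            class = "weighted_linear_model")
}

## ---- learned committee members --------------------------------------------

# Ridge-penalized logistic regression (glmnet) used as the learned base
# committee member. Returns a predictor function over feature matrices.
fit_base_logistic <- function(x, y, lambda = 1e-2) {
  if (length(unique(y)) < 2L) {
    const <- as.integer(y[1])
    return(function(newx) rep.int(const, nrow(newx)))
  }
  # glmnet warns about small classes on tiny folds; the ridge fit is still
  # well-defined and deterministic
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = FALSE,
                   thresh = 1e-8))
  function(newx) {
    as.integer(as.numeric(stats::predict(fit, newx, type = "response")) > 0.5)
  }
}

# Out-of-fold 0/1 predictions of the base classifier on its own training
# set: the learned committee member never votes on rows it was fitted on.
oof_base_votes <- function(x, y, folds = 5L, seed = 0L) {
  n <- length(y)
  folds <- min(folds, n)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  out <- integer(n)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    pred <- fit_base_logistic(x[!hold, , drop = FALSE], y[!hold])
    out[hold] <- pred(x[hold, , drop = FALSE])
  }
  out
}
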