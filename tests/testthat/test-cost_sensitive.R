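test_that("importance-reweighting costs match the worked derivation exactly", {
  co <- assign_costs(c(0.9, 0.8, 0.2, 0.6))
  expect_identical(co$y, c(1L, 1L, 0L, 1L))
  expect_equal(co$pos_fraction, 0.75)
  expect_equal(co$c, c(1.2, 16 / 15, 3.2, 0.8), tolerance = 1e-12)
})

test_that("perfectly confident estimates give unit costs", {
  co <- assign_costs(rep(1, 5))
  expect_identical(co$y, rep(1L, 5))
  expect_equal(co$c, rep(1, 5))
})

test_that("an all-negative estimate uses the degenerate-denominator rule", {
  co <- assign_costs(c(0.2, 0.3))
  expect_identical(co$y, c(0L, 0L))
  expect_equal(co$c, c(0.8, 0.7))
})

test_that("the literal variant uses p-hat in the negative numerator", {
  co <- assign_costs(c(0.9, 0.2), variant = "paper_literal")
  expect_equal(co$c, c(0.9 / 0.5, 0.2 / 0.5))
})

test_that("p-hat of exactly one half rounds up to the positive class", {
  co <- assign_costs(c(0.5, 0.4))
  expect_identical(co$y, c(1L, 0L))
})

test_that("costs are positive and finite for random reliabilities", {
  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(2:30, 1))
    for (variant in c("lemma_consistent", "paper_literal")) {
      co <- assign_costs(p, variant)
      expect_true(all(is.finite(co$c)))
      if (variant == "lemma_consistent") expect_true(all(co$c > 0))
      # algebraic identity: mean positive-class cost = mean(p | y=1)/pos_frac
      if (any(co$y == 1L) && co$pos_fraction > 0) {
        expect_equal(mean(co$c[co$y == 1L]),
                     mean(p[co$y == 1L]) / co$pos_fraction, tolerance = 1e-12)
      }
    }
  }
  expect_error(assign_costs(numeric()), "empty")
})

sep_data <- function(n = 20, d = 4, seed = 8) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.2) > 0)
    list(x = x, y = y)
  })
}

test_that("duplicating an example is equivalent to doubling its cost", {
  dat <- sep_data(24)
  cw <- rep(1, 24); cw[3] <- 2
  m_weighted <- train_weighted(dat$x, list(y = dat$y, c = cw))
  x_dup <- rbind(dat$x, dat$x[3, , drop = FALSE])
  m_dup <- train_weighted(x_dup, list(y = c(dat$y, dat$y[3]), c = rep(1, 25)))
  expect_equal(unname(m_weighted$weights), unname(m_dup$weights),
               tolerance = 1e-6)
  expect_equal(m_weighted$bias, m_dup$bias, tolerance = 1e-6)
  pred_w <- predict(m_weighted, dat$x)$margin
  pred_d <- predict(m_dup, dat$x)$margin
  expect_equal(pred_w, pred_d, tolerance = 1e-6)
})

test_that("scaling all costs and the regularizer together keeps the model", {
  dat <- sep_data(30, seed = 9)
  cw <- runif(30, 0.5, 2)
  m1 <- train_weighted(dat$x, list(y = dat$y, c = cw), reg = 1)
  m2 <- train_weighted(dat$x, list(y = dat$y, c = 10 * cw), reg = 10)
  expect_equal(unname(m1$weights), unname(m2$weights), tolerance = 1e-5)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-5)
})

test_that("integer-cost training equals replicated-example training", {
  dat <- sep_data(15, seed = 10)
  cw <- withr::with_seed(11, sample(1:3, 15, replace = TRUE))
  m_w <- train_weighted(dat$x, list(y = dat$y, c = cw))
  idx <- rep(seq_len(15), cw)
  m_r <- train_weighted(dat$x[idx, ], list(y = dat$y[idx], c = rep(1, length(idx))))
  expect_equal(predict(m_w, dat$x)$margin, predict(m_r, dat$x)$margin,
               tolerance = 1e-5)
})

test_that("a separable problem is separated and training is deterministic", {
  x <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
  y <- rep(c(1L, 0L), each = 10)
  m1 <- train_weighted(x, list(y = y, c = rep(1, 20)), reg = 0.01)
  expect_identical(predict(m1, x)$label, y)
  m2 <- train_weighted(x, list(y = y, c = rep(1, 20)), reg = 0.01)
  expect_identical(m1$weights, m2$weights)
})

test_that("single-class training and schema mismatches are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(train_weighted(x, list(y = rep(1L, 5), c = rep(1, 5))),
               "degenerate")
  m <- train_weighted(rbind(x, x), list(y = rep(c(0L, 1L), each = 5),
                                        c = rep(1, 10)))
  expect_error(predict(m, matrix(0, 1, 5)), "mismatch")
})

test_that("margins are linear in any single feature and zero input gives the bias", {
  dat <- sep_data(20, seed = 12)
  m <- train_weighted(dat$x, list(y = dat$y, c = rep(1, 20)))
  z <- matrix(0, 1, 4)
  expect_equal(predict(m, z)$margin, m$bias)
  expect_identical(predict(m, z)$label, as.integer(m$bias >= 0))
  for (j in 1:4) {
    step <- z; step[1, j] <- 1
    step2 <- z; step2[1, j] <- 2
    d1 <- predict(m, step)$margin - predict(m, z)$margin
    d2 <- predict(m, step2)$margin - predict(m, step)$margin
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("models persist to JSON and reload losslessly", {
  dat <- sep_data(16, seed = 13)
  colnames(dat$x) <- paste0("f", 1:4)
  m <- train_weighted(dat$x, list(y = dat$y, c = rep(1, 16)))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path, colnames(dat$x))
  expect_equal(unname(m2$weights), unname(m$weights))
  expect_equal(m2$bias, m$bias)
  expect_equal(predict(m2, dat$x)$label, predict(m, dat$x)$label)
})

test_that("sparse feature matrices are supported end to end", {
  dat <- sep_data(20, seed = 14)
  xs <- Matrix::Matrix(dat$x, sparse = TRUE)
  m_dense <- train_weighted(dat$x, list(y = dat$y, c = rep(1, 20)))
  m_sparse <- train_weighted(xs, list(y = dat$y, c = rep(1, 20)))
  expect_equal(unname(m_sparse$weights), unname(m_dense$weights),
               tolerance = 1e-6)
})

test_that("out-of-fold base votes are deterministic under the seed", {
  dat <- sep_data(30, seed = 15)
  v1 <- curex:::oof_base_votes(dat$x, dat$y, seed = 3L)
  v2 <- curex:::oof_base_votes(dat$x, dat$y, seed = 3L)
  expect_identical(v1, v2)
  expect_true(all(v1 %in% 0:1))
})
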