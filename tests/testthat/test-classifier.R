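gaussian_features <- function(seed = 7, n = 200) {
  withr::with_seed(seed, dplyr::bind_rows(
    tibble::tibble(rmsd = stats::rnorm(n, 0.3, 0.1),
                   r_asa = stats::rnorm(n, 0.1, 0.05), label = TRUE),
    tibble::tibble(rmsd = stats::rnorm(n, 1.5, 0.2),
                   r_asa = stats::rnorm(n, 0.5, 0.1), label = FALSE)
  ))
}

test_that("a separable fixture trains to high accuracy with negative weights", {
  feats <- gaussian_features()
  m <- train_classifier(feats)
  pred <- predict_bonds(feats, m)
  expect_gte(mean(pred$is_bond == feats$label), 0.99)
  expect_lt(m$weights[["rmsd"]], 0)     # lower RMSD -> more bond-like
  expect_lt(m$weights[["r_asa"]], 0)    # more buried -> more bond-like
})

test_that("the penalized fit matches an independent ridge solver", {
  skip_if_not_installed("glmnet")
  feats <- gaussian_features(seed = 19)
  m <- train_classifier(feats)
  x <- as.matrix(feats[, c("rmsd", "r_asa")])
  # same objective in glmnet's scaling: lambda = 1 / (n * C)
  g <- glmnet::glmnet(x, as.numeric(feats$label), family = "binomial",
                      alpha = 0, lambda = 1 / nrow(x), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(m$weights),
               unname(as.numeric(g$beta)), tolerance = 0.02)
  expect_equal(m$intercept, as.numeric(g$a0), tolerance = 0.02)
})

test_that("indistinguishable classes give probabilities near one half", {
  feats <- withr::with_seed(31, dplyr::bind_rows(
    tibble::tibble(rmsd = stats::rnorm(150, 1, 0.3),
                   r_asa = stats::rnorm(150, 0.3, 0.1), label = TRUE),
    tibble::tibble(rmsd = stats::rnorm(150, 1, 0.3),
                   r_asa = stats::rnorm(150, 0.3, 0.1), label = FALSE)
  ))
  m <- train_classifier(feats)
  p <- predict_bonds(feats, m)$probability
  expect_lt(stats::median(abs(p - 0.5)), 0.1)
})

test_that("prediction follows the closed-form sigmoid with a strict threshold", {
  m0 <- isopeptider:::new_iso_model(c(rmsd = 0, r_asa = 0), intercept = 0)
  p <- predict_bonds(tibble::tibble(rmsd = 1, r_asa = 0.5), m0)
  expect_identical(p$probability, 0.5)
  expect_false(p$is_bond)              # p == threshold classifies negative

  m10 <- isopeptider:::new_iso_model(c(rmsd = 0, r_asa = 0), intercept = 10)
  expect_gt(predict_bonds(tibble::tibble(rmsd = 0, r_asa = 0),
                          m10)$probability, 0.9999)

  m <- isopeptider:::new_iso_model(c(rmsd = -2, r_asa = -3), intercept = 1)
  p1 <- predict_bonds(tibble::tibble(rmsd = 0.5, r_asa = 0.2), m)$probability
  p2 <- predict_bonds(tibble::tibble(rmsd = 0.9, r_asa = 0.2), m)$probability
  expect_lt(p2, p1)                    # monotone in rmsd under negative weight

  expect_error(predict_bonds(tibble::tibble(rmsd = NA_real_, r_asa = 0.1), m),
               "non-finite")
})

test_that("model files round-trip bitwise and single-class training errors", {
  m <- train_classifier(gaussian_features(seed = 3))
  f <- tempfile(fileext = ".txt")
  write_model(m, f)
  back <- read_model(f)
  expect_identical(back$weights, m$weights)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$threshold, m$threshold)

  ones <- tibble::tibble(rmsd = stats::runif(10), r_asa = stats::runif(10),
                         label = TRUE)
  expect_error(train_classifier(ones), "both classes")
})

test_that("tidy and glance expose coefficients and metadata", {
  m <- train_classifier(gaussian_features())
  td <- generics::tidy(m)
  expect_equal(td$term, c("(Intercept)", "rmsd", "r_asa"))
  expect_equal(td$estimate[1], m$intercept)
  gl <- generics::glance(m)
  expect_equal(gl$n_pos, 200)
  expect_equal(gl$threshold, 0.5)
})
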