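test_that("step-1 F-to-enter equals the one-way ANOVA F for every candidate", {
  set.seed(101)
  d <- gaussian_feature_table(n_per_group = 10, p = 12, delta = 2, n_signal = 2)
  n <- nrow(d); g <- 2
  vars <- setdiff(names(d), "class_label")
  for (v in vars) {
    lam <- wilks_lambda(d, v)
    F_step <- (n - g) / (g - 1) * (1 / lam - 1)
    F_aov <- summary(stats::aov(d[[v]] ~ d$class_label))[[1]]$`F value`[1]
    expect_equal(F_step, F_aov, tolerance = 1e-9)
  }
  # the first entered variable is the ANOVA-F argmax
  F_all <- vapply(vars, function(v)
    summary(stats::aov(d[[v]] ~ d$class_label))[[1]]$`F value`[1], numeric(1))
  tr <- select_features(d, features = vars)
  expect_equal(tr$variable[1], names(which.max(F_all)))
  expect_equal(tr$F[1], max(F_all), tolerance = 1e-9)
})

test_that("a lone strong variable is entered; identical groups enter nothing", {
  d <- tibble::tibble(
    x = c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)),
    class_label = rep(c("A", "B"), each = 5))
  set.seed(3); d$x <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  tr <- select_features(d, features = "x")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$action, "enter")
  expect_gt(tr$F[1], 3.84)

  d2 <- tibble::tibble(y = rep(c(1, 2, 3, 4, 5), 2),
                       class_label = rep(c("A", "B"), each = 5))
  tr2 <- select_features(d2, features = "y")
  expect_equal(nrow(tr2), 0)
  expect_length(attr(tr2, "selected"), 0)
})

test_that("a perfect duplicate of an entered variable is blocked by tolerance", {
  set.seed(107)
  d <- gaussian_feature_table(n_per_group = 15, p = 5, delta = 4, n_signal = 1)
  d$dup <- d[[1]]
  tr <- select_features(d, features = c(names(d)[1:5], "dup"))
  expect_false("dup" %in% attr(tr, "selected"))
  expect_true(names(d)[1] %in% attr(tr, "selected"))
})

test_that("constant variables are skipped with a warning", {
  set.seed(109)
  d <- gaussian_feature_table(n_per_group = 8, p = 4, delta = 3, n_signal = 1)
  d$flat <- 7
  expect_warning(tr <- select_features(d, features = c(names(d)[1:4], "flat")),
                 "constant")
  expect_false("flat" %in% attr(tr, "selected"))
})

test_that("selection requires at least two populated groups", {
  d <- gaussian_feature_table(n_per_group = 6, p = 3)
  expect_error(select_features(dplyr::filter(d, class_label == "WILD")),
               "2 non-unknown groups")
})

test_that("selection and assignment are invariant to row permutation", {
  set.seed(113)
  d <- gaussian_feature_table(n_per_group = 12, p = 20, delta = 1.5, n_signal = 4)
  tr1 <- select_features(d)
  perm <- sample(nrow(d))
  tr2 <- select_features(d[perm, ])
  expect_equal(attr(tr1, "selected"), attr(tr2, "selected"))
  expect_equal(tr1$F, tr2$F, tolerance = 1e-9)

  m <- fit_discriminant(d, tr1)
  p1 <- classify_seeds(m, d)$.pred
  m2 <- fit_discriminant(d[perm, ], tr2)
  p2 <- classify_seeds(m2, d)$.pred
  expect_identical(p1, p2)
})

test_that("selection and assignments are affine-invariant in the features", {
  set.seed(127)
  d <- gaussian_feature_table(n_per_group = 12, p = 10, delta = 2, n_signal = 3)
  tr <- select_features(d)
  pred <- classify_seeds(fit_discriminant(d, tr), d)$.pred
  d2 <- d
  d2[[1]] <- d2[[1]] + 1000       # shift one column
  d2[[2]] <- d2[[2]] * 0.001      # rescale another
  tr2 <- select_features(d2)
  expect_equal(attr(tr, "selected"), attr(tr2, "selected"))
  expect_equal(tr$F, tr2$F, tolerance = 1e-6)
  pred2 <- classify_seeds(fit_discriminant(d2, tr2), d2)$.pred
  expect_identical(pred, pred2)
})

test_that("classification functions match the closed form and MASS::lda", {
  set.seed(131)
  n <- 40
  mu <- list(A = c(0, 0), B = c(3, 1))
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  ch <- chol(S)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2) %*% ch,
             matrix(rnorm(2 * n), ncol = 2) %*% ch)
  X[1:n, ] <- sweep(X[1:n, ], 2, mu$A, `+`)
  X[-(1:n), ] <- sweep(X[-(1:n), ], 2, mu$B, `+`)
  d <- tibble::tibble(f1 = X[, 1], f2 = X[, 2],
                      class_label = rep(c("A", "B"), each = n))
  m <- fit_discriminant(d, c("f1", "f2"))
  # closed form from the sample moments the model stores
  Sinv <- solve(m$cov)
  for (k in 1:2) {
    expect_equal(unname(m$coef[, k]), unname(Sinv %*% m$means[k, ])[, 1],
                 tolerance = 1e-9)
    expect_equal(unname(m$const[k]),
                 unname(-0.5 * m$means[k, ] %*% Sinv %*% m$means[k, ] + log(0.5))[1],
                 tolerance = 1e-9)
  }
  skip_if_not_installed("MASS")
  fit_mass <- MASS::lda(X, grouping = d$class_label, prior = c(0.5, 0.5))
  expect_identical(classify_seeds(m, d)$.pred,
                   as.character(stats::predict(fit_mass, X)$class))
})

test_that("1-D symmetric groups put the decision boundary at zero", {
  d <- tibble::tibble(x = c(-1.5, -1, -0.5, 0.5, 1, 1.5),
                      class_label = rep(c("A", "B"), each = 3))
  m <- fit_discriminant(d, "x")
  res <- classify_seeds(m, tibble::tibble(x = c(-0.01, 0.01, 0)))
  expect_equal(res$.pred, c("A", "B", "A"))  # exact tie -> first label
  expect_identical(classify_seeds(m, d)$.pred, d$class_label)
})

test_that("posteriors are normalized and track the assigned group", {
  set.seed(137)
  d <- gaussian_feature_table(n_per_group = 10, p = 4, delta = 3, n_signal = 2)
  res <- classify_seeds(fit_discriminant(d, names(d)[1:4]), d)
  post <- as.matrix(res[, c(".post_CULTIVATED", ".post_WILD")])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-12)
  winner <- c("CULTIVATED", "WILD")[max.col(post)]
  expect_identical(res$.pred, winner)
})

test_that("missing selected variables and singular covariances raise errors", {
  d <- gaussian_feature_table(n_per_group = 5, p = 3)
  expect_error(fit_discriminant(d, c("V001", "nope")), "nope")
  d$twin <- d[[1]]
  expect_error(fit_discriminant(d, c("V001", "twin")), "singular")
  m <- fit_discriminant(d, "V001")
  expect_error(classify_seeds(m, d["class_label"]), "V001")
})

test_that("LOOCV is perfect for well-separated groups and honest for null data", {
  set.seed(139)
  d <- gaussian_feature_table(n_per_group = 15, p = 8, delta = 6, n_signal = 2)
  cv <- loocv(d, c("V001", "V002"))
  expect_equal(mean(cv$correct), 1)
  # LOOCV never beats resubstitution on average (selection optimism)
  set.seed(149)
  gap <- replicate(10, {
    d0 <- gaussian_feature_table(n_per_group = 8, p = 6, delta = 0, n_signal = 0)
    sel <- names(d0)[1:3]
    resub <- mean(classify_seeds(fit_discriminant(d0, sel), d0)$.pred ==
                    d0$class_label)
    resub - mean(loocv(d0, sel)$correct)
  })
  expect_gt(mean(gap), 0)
})

test_that("unknown rows are excluded from fitting but scored in the wrapper", {
  set.seed(151)
  d <- gaussian_feature_table(n_per_group = 12, p = 6, delta = 5, n_signal = 2)
  unk <- gaussian_feature_table(n_per_group = 3, p = 6, delta = 5, n_signal = 2)
  unk <- dplyr::filter(unk, class_label == "WILD")
  unk$class_label <- "UNKNOWN"
  fit <- stepwise_lda(dplyr::bind_rows(d, unk))
  expect_equal(fit$model$n, 24)
  expect_equal(sum(fit$assignments$class_label == "UNKNOWN"), 3)
  expect_true(all(fit$assignments$.pred[fit$assignments$class_label == "UNKNOWN"]
                  %in% c("WILD", "CULTIVATED")))
  g <- glance(fit)
  expect_equal(g$n_groups, 2)
  expect_gte(g$loocv_accuracy, 0.9)
  td <- tidy(fit)
  expect_setequal(unique(td$group), c("WILD", "CULTIVATED"))
  expect_true("(Intercept)" %in% td$term)
})
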