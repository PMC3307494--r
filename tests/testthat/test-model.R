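test_that("the first-stage grid is the eight powers of two", {
  g <- first_stage_grid()
  expect_identical(g, c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16))
  expect_identical(g, 2^(-3:4))
  expect_true(all(diff(g) > 0))
})

test_that("refinement rows match the fixed neighborhood table", {
  rows <- list(
    `-3` = c(0.05, 0.1, 0.15),
    `-2` = c(0.15, 0.2, 0.3, 0.35),
    `-1` = c(0.3, 0.4, 0.6, 0.7),
    `0`  = c(0.75, 1.25, 1.5),
    `1`  = c(1.5, 2.5, 3.0),
    `2`  = c(3.0, 3.5, 4.5, 5.0, 6.0),
    `3`  = c(6.0, 7.0, 9.0, 10.0, 11.0),
    `4`  = c(11.0, 12.0, 13.0, 14.0, 15.0))
  for (x in -3:4) {
    expect_identical(refinement_values(x), rows[[as.character(x)]])
  }
  expect_error(refinement_values(5), "\\[-3, 4\\]")
  expect_error(refinement_values(-4), "\\[-3, 4\\]")
  expect_error(refinement_values(0.5), "\\[-3, 4\\]")
})

test_that("refinement triggering follows the size and accuracy rule", {
  expect_true(should_refine(4999, 0.99))
  expect_true(should_refine(1, 1.0))
  expect_false(should_refine(5000, 0.99))
  expect_true(should_refine(5000, 0.79))
  expect_true(should_refine(7000, 0.79))
  expect_false(should_refine(7000, 0.80))
  expect_false(should_refine(9999, 0.80))
  expect_true(should_refine(9999, 0.7999))
  expect_false(should_refine(10000, 0.10))
  expect_false(should_refine(12000, 0.10))
})

test_that("cross-validation is exact on separable data and null on noise", {
  sets <- separable_profiles(20)
  sp <- build_feature_space(sets$a, sets$b)
  x <- profile_matrix(c(sets$a, sets$b), sp)
  labels <- rep(c("A", "B"), each = 20)
  for (C in c(0.125, 1, 16)) {
    expect_equal(cross_validate(x, labels, C, seed = 1), 1.0)
  }

  # permuted labels: accuracy hovers around chance
  w <- generate_world(delta = 1, n_per_topic = c(100, 100),
                      vocab_size = 80, seed = 5)
  spw <- build_feature_space(w$profiles[w$truth == "A"],
                             w$profiles[w$truth == "B"])
  xw <- profile_matrix(w$profiles, spw)
  accs <- vapply(1:8, function(s) {
    perm <- with(list(), {set.seed(s); sample(unname(w$truth))})
    cross_validate(xw, perm, 1, seed = s)
  }, 0)
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)

  expect_error(cross_validate(x[1:3, ], labels[c(1, 2, 21)], 1),
               "cross-validation")
  expect_error(cross_validate(x[1:6, ], rep("A", 6), 1), "both labels")
})

test_that("penalty selection traces both stages and breaks ties downward", {
  sets <- separable_profiles(20)  # n = 40 < 5000: refinement always runs
  sp <- build_feature_space(sets$a, sets$b)
  x <- profile_matrix(c(sets$a, sets$b), sp)
  labels <- rep(c("A", "B"), each = 20)
  sel <- select_C(x, labels, seed = 1)
  expect_true(sel$refined)
  expect_equal(nrow(sel$trace),
               8 + length(refinement_values(sel$x_best)))
  # separable: every grid point ties at 1.0, so the smallest evaluated C
  # wins; x_best = -3 and its refinement row starts at 0.05
  expect_equal(sel$cv_accuracy, 1.0)
  expect_equal(sel$x_best, -3)
  expect_equal(sel$chosen_C, 0.05)
  expect_true(sel$chosen_C %in% sel$trace$C)
  expect_equal(sel$cv_accuracy, max(sel$trace$cv_accuracy))

  # moderate-size set with high first-stage accuracy: no refinement
  big <- separable_profiles(3000)  # 6000 vectors
  spb <- build_feature_space(big$a, big$b)
  xb <- profile_matrix(c(big$a, big$b), spb)
  selb <- select_C(xb, rep(c("A", "B"), each = 3000), seed = 1)
  expect_false(selb$refined)
  expect_equal(nrow(selb$trace), 8)
})

test_that("the final model emits calibrated two-class probabilities", {
  sets <- separable_profiles(15)
  fit <- litrank(sets$a, sets$b, seed = 2)
  expect_s3_class(fit, "litrank")
  expect_equal(fit$test_set_accuracy, 1.0)

  p <- predict(fit, c(sets$a, sets$b))
  expect_true(all(p >= 0 & p <= 1))
  # complement probability: P(B) = 1 - P(A) by construction of the logistic
  cls <- predict(fit, c(sets$a, sets$b), type = "class")
  expect_identical(unname(cls), unname(ifelse(p > 0.5, "A", "B")))

  # scores are monotone in the linear decision value
  eta <- predict(fit, c(sets$a, sets$b), type = "link")
  expect_identical(order(eta), order(p))

  expect_error(train_final(profile_matrix(sets$a,
                                          build_feature_space(sets$a, sets$b)),
                           rep("A", 15), 1),
               "single-class")
})

test_that("model methods expose fit diagnostics", {
  sets <- separable_profiles(10)
  fit <- litrank(sets$a, sets$b, seed = 1)

  cf <- coef(fit)
  expect_equal(names(cf)[1], "(Intercept)")
  expect_length(cf, 1 + fit$space$V)
  # A-indicative term gets positive weight, B-indicative negative
  expect_gt(cf[["aaa"]], 0)
  expect_lt(cf[["bbb"]], 0)

  r <- residuals(fit)
  expect_length(r, 20)
  expect_equal(unname(r), as.numeric(fit$labels == "A") - fit$fitted)

  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(20, 3))
  expect_true(all(unlist(sims) %in% c("A", "B")))
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)

  expect_output(print(fit), "chosen C")
  expect_output(print(summary(fit)), "grid search")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("serialized models predict identically after reload", {
  w <- generate_world(delta = 0.8, n_per_topic = c(25, 25), vocab_size = 50,
                      seed = 4)
  fit <- litrank(w$profiles[w$truth == "A"], w$profiles[w$truth == "B"],
                 seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_litrank(fit, f)
  back <- read_litrank(f)
  expect_equal(back$chosen_C, fit$chosen_C)
  expect_equal(back$trace$cv_accuracy, fit$trace$cv_accuracy)
  expect_equal(predict(back, w$profiles), predict(fit, w$profiles),
               tolerance = 1e-12)
})
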