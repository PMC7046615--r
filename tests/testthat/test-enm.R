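test_that("greedy thinning keeps the expected points", {
  two_close <- data.frame(x = c(0, 30), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(two_close, 50)), 1L)
  two_far <- data.frame(x = c(0, 60), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(two_far, 50)), 2L)
  coll <- data.frame(x = seq(0, 160, by = 40), y = 0)
  kept <- thin_occurrences(coll, 50)
  expect_equal(kept$x, c(0, 80, 160))  # points 1, 3, 5
})

test_that("pseudo-absence sampling honours the disk rule and set design", {
  frame <- grid_raster(matrix(0, 64, 64), cell_size = 50)
  occ <- data.frame(x = c(525, 1825), y = c(-525, -1325))
  sets <- sample_pseudo_absences(frame, occ, n = 200, n_sets = 3,
                                 method = "disk", min_dist = 50, seed = 4)
  expect_length(sets, 3L)
  for (s in sets) {
    expect_equal(nrow(s), 200L)
    dmin <- vapply(seq_len(nrow(s)), function(i)
      min(sqrt((s$x[i] - occ$x)^2 + (s$y[i] - occ$y)^2)), numeric(1))
    expect_true(all(dmin > 50))
  }
  # ten sets of 1000 from an empty occurrence set (random method)
  sets10 <- sample_pseudo_absences(frame, occ[0, ], n = 1000, n_sets = 10,
                                   method = "random", seed = 4)
  expect_length(sets10, 10L)
  expect_true(all(vapply(sets10, nrow, integer(1)) == 1000L))
  expect_error(sample_pseudo_absences(grid_raster(matrix(0, 2, 2)), occ[0, ],
                                      n = 10, method = "random"),
               "infeasible")
})

test_that("class weights equalize the two classes exactly", {
  expect_equal(compute_weights(100, 100), list(presence = 1, pa = 1))
  expect_equal(compute_weights(183, 1000)$pa, 0.183)
  for (np in c(7, 183, 421)) for (na in c(13, 1000)) {
    w <- compute_weights(np, na)
    expect_equal(np * w$presence, na * w$pa)
  }
  expect_error(compute_weights(0, 10), "positive")
})

test_that("the 70/30 split is stratified and deterministic", {
  y <- c(rep(1, 10), rep(0, 40))
  sp <- split_train_eval(y, 0.7, seed = 2)
  expect_equal(sum(y[sp$train] == 1), 7)
  expect_equal(sum(y[sp$train] == 0), 28)
  expect_setequal(c(sp$train, sp$eval), seq_along(y))
  expect_identical(sp, split_train_eval(y, 0.7, seed = 2))
  # per-stratum proportions within one point of the overall fraction
  for (n1 in c(9, 23)) {
    yy <- c(rep(1, n1), rep(0, 31))
    s <- split_train_eval(yy, 0.7, seed = 5)
    expect_lte(abs(sum(yy[s$train] == 1) - 0.7 * n1), 1)
  }
  expect_error(split_train_eval(c(1, 0, 0, 0), 0.7), "class")
})

test_that("AUC matches hand counts, the concordance oracle and pROC", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_roc(c(5, 4, 3, 1, 2), c(1, 1, 1, 0, 0)), 1)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_roc(s, y), bf_auc(s, y))
  }
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- c(rep(1, 30), rep(0, 40)); s <- runif(70) + 0.4 * y
  expect_equal(auc_roc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("TSS maximizes sensitivity + specificity - 1 over thresholds", {
  expect_equal(tss(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$tss, 1)
  expect_equal(tss(rep(0.4, 10), rep(c(1, 0), 5))$tss, 0)
  # optimum at sens 0.9, spec 0.8 -> 0.7
  s <- c(rep(0.8, 9), 0.1, rep(0.2, 8), 0.9, 0.9)
  l <- c(rep(1, 10), rep(0, 10))
  res <- tss(s, l)
  expect_equal(res$tss, 0.7)
  expect_equal(res$threshold, 0.8)
  # invariance under strictly monotone transforms of the scores
  set.seed(12)
  for (i in 1:10) {
    y <- c(1, 0, rbinom(28, 1, 0.4))
    sc <- runif(30)
    base <- tss(sc, y)$tss
    expect_equal(tss(qlogis(sc / 2 + 0.25), y)$tss, base)
    expect_equal(tss(sc^3, y)$tss, base)
  }
  expect_error(tss(1:4, rep(1, 4)), "class")
})

test_that("learner contract: weights, degeneracy and separability", {
  set.seed(5)
  x <- data.frame(a = c(rnorm(40, 2), rnorm(40, -2)), b = rnorm(80))
  y <- rep(c(1, 0), each = 40)
  rf <- fit_single_model("rf", x, y, seed = 3)
  expect_equal(auc_roc(rf$predict(x), y), 1)  # separable: training AUC 1
  # duplicating the training set leaves the linear learner unchanged
  glm1 <- fit_single_model("glm", x, y)
  glm2 <- fit_single_model("glm", rbind(x, x), c(y, y))
  expect_equal(glm1$predict(x), glm2$predict(x), tolerance = 1e-6)
  # all-constant covariate: prediction = weighted prevalence
  xc <- data.frame(a = rep(1, 60))
  yc <- rep(c(1, 0), times = c(20, 40))
  w <- c(rep(1, 20), rep(0.5, 40))
  g <- fit_single_model("glm", xc, yc, w)
  expect_equal(unique(round(g$predict(xc), 10)),
               sum(w * yc) / sum(w))
  expect_error(fit_single_model("nope", x, y), "unknown learner")
  expect_error(fit_single_model("glm", x, rep(1, 80)), "one class")
})

test_that("permutation importance separates used from unused variables", {
  set.seed(20)
  x <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- as.integer(plogis(3 * x$a) > runif(300))
  run <- fit_single_model("glm", x, y)
  imp_a <- permutation_importance(run, x, "a", n_perm = 5, seed = 1)
  imp_b <- permutation_importance(run, x, "b", n_perm = 5, seed = 1)
  expect_gt(imp_a, 0.5)
  expect_lt(imp_b, 0.1)
  # importance of a is invariant to duplicating an unrelated variable
  x2 <- cbind(x, b2 = x$b)
  run2 <- fit_single_model("glm", x2, y)
  imp_a2 <- permutation_importance(run2, x2, "a", n_perm = 5, seed = 1)
  expect_equal(imp_a2, imp_a, tolerance = 0.1)
  expect_error(permutation_importance(run, x, "zz"), "unknown variable")
})

test_that("variable selection keeps one representative per correlated group", {
  set.seed(33)
  n <- 250
  a <- rnorm(n)
  x <- data.frame(a = a, b = a + rnorm(n, sd = 0.3), c = rnorm(n))
  # y driven by b (and independent c): within the {a, b} cluster b wins
  y <- as.integer(plogis(2.5 * x$b + 1.5 * x$c) > runif(n))
  expect_gt(abs(cor(x$a, x$b)), 0.7)
  sel <- select_variables(x, y, learners = "glm", n_perm = 5, seed = 2)
  expect_setequal(sel, c("b", "c"))
  # all pairwise |r| < 0.7: everything retained, input order preserved
  xi <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  yi <- rbinom(n, 1, 0.5)
  expect_equal(select_variables(xi, yi, learners = "glm", n_perm = 2,
                                seed = 1), c("u", "v", "w"))
  # exact duplicate: exactly one survives
  xd <- data.frame(p = a, q = a)
  expect_length(select_variables(xd, y, learners = "glm", n_perm = 2,
                                 seed = 1), 1L)
})

test_that("ensemble design enumeration matches the factorial count", {
  expect_equal(count_model_runs(8, 5, 5), 200L)
  expect_equal(count_model_runs(8, 10, 5), 400L)
  expect_equal(count_model_runs(1, 1, 1), 1L)
  expect_error(count_model_runs(0, 5, 5), "positive")
  spec <- enumerate_model_runs(paste0("alg", 1:8), 5, 5)
  expect_equal(nrow(spec), 200L)
  expect_equal(nrow(unique(spec)), 200L)
})

test_that("TSS gating, ensemble mean and CV follow their definitions", {
  frame <- flat_raster(0, 2, 2)
  mk_run <- function(tss, p) structure(
    list(tss = tss, surface = flat_raster(p, 2, 2)), class = "model_run")
  one <- build_ensemble(list(mk_run(0.9, 0.3), mk_run(0.5, 0.9)), frame)
  expect_equal(one$mean_surface$values, matrix(0.3, 2, 2))
  expect_equal(one$cv_surface$values, matrix(0, 2, 2))
  same <- build_ensemble(list(mk_run(0.8, 0.4), mk_run(0.75, 0.4)), frame)
  expect_equal(same$cv_surface$values, matrix(0, 2, 2))
  two <- build_ensemble(list(mk_run(0.8, 0.2), mk_run(0.75, 0.6)), frame)
  expect_equal(two$mean_surface$values, matrix(0.4, 2, 2))
  expect_equal(two$cv_surface$values, matrix(0.5, 2, 2))  # population sd
  expect_error(build_ensemble(list(mk_run(0.3, 0.2)), frame),
               "empty ensemble")
})

test_that("response curves respect model structure", {
  set.seed(44)
  x <- data.frame(a = runif(200, -2, 2), b = runif(200, -2, 2))
  y <- as.integer(plogis(3 * x$a) > runif(200))
  run <- fit_single_model("glm", x, y)
  run$tss <- 0.9
  run$surface <- flat_raster(0.5, 2, 2)
  ens <- build_ensemble(list(run), flat_raster(0, 2, 2))
  ens$training_medians <- vapply(x, median, numeric(1))
  ens$training_ranges <- lapply(x, range)
  rc_a <- response_curve(ens, "a", n_points = 15)
  expect_true(all(diff(rc_a$prediction) > 0))  # monotone learner
  expect_true(all(rc_a$prediction >= 0 & rc_a$prediction <= 1))
  rc_b <- response_curve(ens, "b", n_points = 15)
  expect_lt(diff(range(rc_b$prediction)), 0.05)  # near-flat in unused var
  expect_error(response_curve(ens, "zz"), "unknown variable")
})
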