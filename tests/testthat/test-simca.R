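# small deterministic training matrices used across the SIMCA tests
rank1_training <- function(m = 8, p = 30, seed = 5, noise = 0) {
  set.seed(seed)
  v <- rnorm(p)
  v <- v / sqrt(sum(v^2))
  mu <- runif(p, 10, 60)
  t <- seq(-2, 2, length.out = m) * 10
  X <- matrix(rep(mu, each = m), m, p) + outer(t, v)
  if (noise > 0) X <- X + matrix(rnorm(m * p, 0, noise), m, p)
  list(train = training_set("toy", abs(X), mz_min = 85L), v = v, mu = mu)
}

test_that("PCA class models recover noiseless low-rank structure", {
  tr <- rank1_training()
  mod <- fit_class_model(tr$train, r = 1)
  expect_equal(mod$s0, 0, tolerance = 1e-9)
  # recovered loading equals the generating direction up to sign
  expect_equal(abs(sum(mod$loadings * tr$v)), 1, tolerance = 1e-9)
  expect_equal(crossprod(mod$loadings), diag(mod$r) + 0, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(fit_class_model(tr$train, r = 7), "m = 8, r = 7")
})

test_that("reconstruction error matches the rank-r optimum (Eckart-Young)", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(runif(10 * 20, 1, 100), 10, 20)
    tr <- training_set("rnd", X, mz_min = 85L)
    for (r in c(1, 2, 3)) {
      mod <- fit_class_model(tr, r = r)
      sse <- mod$s0^2 * (mod$m - r - 1) * (mod$p - r)
      d <- svd(sweep(X, 2, colMeans(X)))$d
      expect_equal(sse, sum(d[(r + 1):length(d)]^2), tolerance = 1e-8)
    }
  }
})

test_that("training residual SD follows sqrt(SSE / ((m-r-1)(p-r)))", {
  # plug-in check of the stated formula on an all-ones residual toy
  expect_equal(simcaGC:::rsd_from_residuals(matrix(1, 5, 3), 5, 1, 3),
               sqrt(15 / (3 * 2)))
  tr <- rank1_training(noise = 2)$train
  mod <- fit_class_model(tr, r = 1)
  expect_equal(residual_sd_training(tr, mod), mod$s0)
  # manual recomputation
  Xc <- sweep(tr$X, 2, colMeans(tr$X))
  E <- Xc - (Xc %*% mod$loadings) %*% t(mod$loadings)
  expect_equal(mod$s0, sqrt(sum(E^2) / ((8 - 1 - 1) * (30 - 1))))
  # homogeneity: doubling all intensities doubles s0
  tr2 <- training_set("x2", tr$X * 2, mz_min = 85L)
  expect_equal(fit_class_model(tr2, r = 1)$s0, 2 * mod$s0)
  # noiseless rank-r data have zero residual SD
  expect_equal(fit_class_model(rank1_training()$train, r = 1)$s0, 0,
               tolerance = 1e-9)
})

test_that("projection splits an object into scores and an out-of-space residual", {
  tr <- rank1_training(noise = 1)$train
  mod <- fit_class_model(tr, r = 1)
  # the model mean projects to zero scores and zero residual
  at_mean <- project_and_residual(mod$mean, mod)
  expect_equal(at_mean$scores, 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(at_mean$s_j, 0, tolerance = 1e-12)
  # any in-space object has zero residual
  in_space <- project_and_residual(mod$mean + drop(mod$loadings %*% 3.7), mod)
  expect_equal(in_space$s_j, 0, tolerance = 1e-9)
  expect_equal(in_space$scores, 3.7, tolerance = 1e-9, ignore_attr = TRUE)
  # orthogonal offset with squared norm p - r gives s_j == 1
  set.seed(8)
  raw <- rnorm(mod$p)
  u <- raw - drop(mod$loadings %*% crossprod(mod$loadings, raw))
  u <- u * sqrt((mod$p - mod$r) / sum(u^2))
  expect_equal(project_and_residual(mod$mean + u, mod)$s_j, 1,
               tolerance = 1e-9)
  expect_error(project_and_residual(numeric(5), mod), "expects")
})

test_that("the membership F-test follows both df conventions and matches an integration oracle", {
  # s_j == s0: F = 1, never in the far upper tail
  ft <- f_test_membership(2.5, 2.5, m = 12, r = 1, alpha = 0.05)
  expect_equal(ft$F, 1)
  expect_true(ft$member)
  expect_equal(c(ft$df1, ft$df2), c(10, 100))
  # s_j == 0: F = 0, p = 1, member
  ft0 <- f_test_membership(0, 2.5, m = 12, r = 1)
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p_value, 1)
  expect_true(ft0$member)
  # organic-acid-sized class, s_j/s0 = 10: compare the upper tail against a
  # numerical integration of the F density, and reject membership
  ft10 <- f_test_membership(10, 1, m = 12, r = 1, alpha = 0.05)
  oracle <- stats::integrate(function(x) stats::df(x, 10, 100), 100, Inf,
                             rel.tol = 1e-10)$value
  expect_equal(ft10$F, 100)
  expect_equal(ft10$p_value, oracle, tolerance = 1e-8)
  expect_false(ft10$member)
  # classical convention swaps in the variable-count degrees of freedom
  ftc <- f_test_membership(1, 1, m = 12, r = 1, p = 416,
                           df_convention = "classical")
  expect_equal(c(ftc$df1, ftc$df2), c(415, 415 * 10))
  expect_error(f_test_membership(1, 0, m = 12, r = 1), "degenerate")
})

test_that("classification takes the largest p-value among accepting classes", {
  set.seed(30)
  base <- rank1_training(m = 10, p = 40, seed = 31, noise = 1)
  tight <- base$train
  loose <- training_set("loose", tight$X +
                          matrix(rnorm(10 * 40, 0, 4), 10, 40), mz_min = 85L)
  m1 <- fit_class_model(tight, r = 1)
  m2 <- fit_class_model(loose, r = 1)
  # an object at class 1's mean: accepted by both, p1 = 1 beats p2
  res <- classify_spectrum(m1$mean, list(m2, m1))
  expect_true(res$multi_class)
  expect_equal(res$final_label, "toy")
  expect_equal(max(res$per_class$p_value), 1)
  # an object orthogonal and far from both subspaces is unknown
  raw <- rnorm(40)
  u <- raw - drop(m1$loadings %*% crossprod(m1$loadings, raw))
  far <- m1$mean + u * (200 / sqrt(sum(u^2)))
  res_far <- classify_spectrum(far, list(m1, m2))
  expect_equal(res_far$final_label, "unknown")
  expect_false(any(res_far$per_class$member))
  # permutation invariance in model order
  res_swap <- classify_spectrum(m1$mean, list(m1, m2))
  expect_equal(res_swap$final_label, res$final_label)
  expect_equal(res_swap$multi_class, res$multi_class)
  # dimension mismatch names the offending model
  m3 <- fit_class_model(rank1_training(m = 6, p = 25, seed = 9)$train, r = 1)
  expect_error(classify_spectrum(m1$mean, list(m1, m3)), "toy")
})

test_that("cross-validated component choice finds the generating rank", {
  # noiseless rank-1
  expect_equal(choose_components_cv(rank1_training()$train, r_max = 4), 1L)
  # rank-2 signal at high SNR, at spectrum-like dimensionality where the
  # per-component noise gain (about 1/p of the residual) is below the 1%
  # parsimony margin
  set.seed(40)
  p <- 416
  v1 <- rnorm(p); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(p); v2 <- v2 - v1 * sum(v1 * v2); v2 <- v2 / sqrt(sum(v2^2))
  X <- 50 + outer(rnorm(15, 0, 12), v1) + outer(rnorm(15, 0, 9), v2) +
    matrix(rnorm(15 * p, 0, 0.05), 15, p)
  expect_equal(choose_components_cv(training_set("r2", abs(X), mz_min = 85L),
                                    r_max = 5), 2L)
  # pure i.i.d. noise: parsimony floor of one component
  N <- matrix(rlnorm(10 * p), 10, p)
  expect_equal(choose_components_cv(training_set("noise", N, mz_min = 85L),
                                    r_max = 4), 1L)
})

test_that("interclass distance is zero on itself, symmetric, and monotone in separation", {
  tpl <- make_default_templates(1)
  tr <- make_training_sets(tpl, sizes = c(10L, 10L, 10L, 9L, 9L), seed = 51)
  mods <- lapply(tr, fit_class_model, r = 1)
  # a model against itself: exactly zero (the Table-4-style diagonal)
  expect_identical(interclass_distance(mods[[1]], mods[[1]], tr[[1]], tr[[1]]),
                   0)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(interclass_distance(mods[[i]], mods[[j]], tr[[i]], tr[[j]]),
                 interclass_distance(mods[[j]], mods[[i]], tr[[j]], tr[[i]]))
  }
  # distance grows with mean separation in one spectral channel
  set.seed(52)
  p <- 60
  base <- matrix(rnorm(12 * p, 50, 1), 12, p)
  trA <- training_set("A", base, mz_min = 85L)
  modA <- fit_class_model(trA, r = 1)
  ds <- vapply(c(3, 12, 48), function(delta) {
    Y <- base
    Y[, 7] <- Y[, 7] + delta
    trB <- training_set("B", Y, mz_min = 85L)
    interclass_distance(modA, fit_class_model(trB, r = 1), trA, trB)
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= 0))
})

test_that("important m/z ranks the loading-dominant fragments first", {
  set.seed(60)
  # variance concentrated in one bin puts that bin first
  X <- matrix(5 + rnorm(10 * 50, 0, 0.01), 10, 50)
  X[, 5] <- rnorm(10, 50, 10)
  tr <- training_set("one-bin", abs(X), mz_min = 85L)
  mod <- fit_class_model(tr, r = 1)
  expect_equal(important_mz(mod, 1), 89L)  # bin 5 on an 85-based axis
  # adding a constant to all spectra leaves the ranking unchanged
  mod_shift <- fit_class_model(training_set("s", X + 3, mz_min = 85L), r = 1)
  expect_equal(important_mz(mod_shift, 5), important_mz(mod, 5))
  # amine-like class varying at its diagnostic fragments 86 and 174
  p <- 416
  f <- rnorm(13)
  A <- matrix(10 + rnorm(13 * p, 0, 0.05), 13, p)
  A[, 86 - 85 + 1] <- 60 + 25 * f
  A[, 174 - 85 + 1] <- 80 - 20 * f
  amod <- fit_class_model(training_set("amine-like", A, mz_min = 85L), r = 1)
  expect_true(all(c(86L, 174L) %in% important_mz(amod, 4)))
  expect_warning(top <- important_mz(mod, 100), "capped")
  expect_length(top, 50L)
})

test_that("leave-one-out cross-validation separates distinct classes and confuses duplicated ones", {
  tpl <- make_default_templates(1)
  # two copies of the same class template are indistinguishable
  dup <- make_training_sets(tpl[c(1, 1)], sizes = c(8L, 8L), seed = 61)
  dup[[2]]$class_name <- "sugar-copy"
  dup[[2]]$X <- `rownames<-`(dup[[2]]$X, paste0("c", 1:8))
  conf <- cross_validate_models(dup, alpha = 0.05, r = 1)
  expect_equal(sum(conf), 16)
  expect_gt(conf["sugar", "sugar-copy"] + conf["sugar-copy", "sugar"], 0)
  # a single class cross-validates against itself
  one <- cross_validate_models(dup[1], alpha = 0.05, r = 1)
  expect_equal(dim(one), c(1L, 2L))
  expect_equal(sum(one), 8)
})

test_that("class models survive a JSON serialization round trip", {
  tr <- make_training_sets(sizes = c(6L, 6L, 6L, 6L, 6L), seed = 62)
  models <- c(lapply(tr[1:2], fit_class_model, r = 1),
              lapply(tr[3], fit_class_model, r = 2))
  f <- tempfile(fileext = ".json")
  write_class_models(models, f)
  back <- read_class_models(f)
  for (i in seq_along(models)) {
    expect_equal(back[[i]]$loadings, models[[i]]$loadings)
    expect_equal(back[[i]]$s0, models[[i]]$s0)
    expect_equal(back[[i]]$mean, models[[i]]$mean)
  }
  x <- tr[[1]]$X[1, ]
  expect_equal(classify_spectrum(x, back), classify_spectrum(x, models))
  expect_error(read_class_models(tempfile()), "not found")
})
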