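test_that("published equation predictor reproduces its printed constants", {
  zero <- c(SPAN = 0, Mor11v = 0, MSD = 0, HATS8u = 0, G3p = 0, E3s = 0)
  expect_equal(predict_published(zero), 5.45)
  expect_equal(predict_published(zero + 1), -8.03)
  one_term <- zero; one_term["SPAN"] <- 10
  expect_equal(predict_published(one_term), 6.45)
  expect_error(predict_published(zero[-2]), "Mor11v")
})

test_that("published equation predictor is affine", {
  set.seed(2)
  nm <- c("SPAN", "Mor11v", "MSD", "HATS8u", "G3p", "E3s")
  for (i in 1:10) {
    a <- setNames(rnorm(6), nm)
    b <- setNames(rnorm(6), nm)
    zero <- setNames(numeric(6), nm)
    expect_equal(predict_published(a + b) - predict_published(a) -
                   predict_published(b) + predict_published(zero), 0,
                 tolerance = 1e-10)
  }
})

test_that("mlr recovers exact and noisy planted coefficients", {
  # exact 3-point hand case: slope 1, intercept 0, perfect fit
  m <- suppressWarnings(fit_mlr(cbind(x = c(1, 2, 3)), c(1, 2, 3)))
  cf <- m$details$coefficients[, 1]
  expect_equal(unname(cf), c(0, 1), tolerance = 1e-10)
  expect_equal(m$details$r2, 1, tolerance = 1e-10)

  # noise-free multivariate system
  set.seed(30)
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  m2 <- suppressWarnings(fit_mlr(x, drop(x %*% beta) + 4))
  expect_equal(m2$details$coefficients[-1, 1], beta, tolerance = 1e-10,
               ignore_attr = TRUE)

  # slopes land within 2 standard errors of the planted values
  hit <- replicate(20, {
    i <- sample.int(10000, 1)
    j <- gen_joint(synth_config(n = 181, seed = i))
    y <- gen_equation_response(j$descriptors, noise_sd = 0.43, seed = i + 1)
    f <- fit_mlr(j$descriptors, y)
    cf <- f$details$coefficients
    planted <- published_coefficients()$slopes[rownames(cf)[-1]]
    all(abs(cf[-1, 1] - planted) <= 2 * cf[-1, 2])
  })
  expect_gte(mean(hit), 0.75)

  expect_error(fit_mlr(cbind(a = 1:10, b = 2 * (1:10)), rnorm(10)),
               "collinear")
})

test_that("svr respects the epsilon tube and duplication invariance", {
  j <- gen_joint(synth_config(n = 120, seed = 55))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.2, seed = 56)
  cfg <- svr_config(C = 10, epsilon = 0.1, gamma = 0.1)
  m <- fit_svr(j$descriptors, y, cfg)
  pred <- predict(m, j$descriptors)
  # KKT: points that are not support vectors lie inside the tube
  sv <- m$details$fit$index
  inside <- setdiff(seq_along(y), sv)
  expect_true(all(abs(y[inside] - pred[inside]) <= cfg$epsilon + 1e-6))

  # duplicating every row doubles the slack term of the objective, which
  # is exactly equivalent to doubling C on the original data
  doubled <- fit_svr(rbind(j$descriptors, j$descriptors), c(y, y),
                     svr_config(C = cfg$C / 2, epsilon = cfg$epsilon,
                                gamma = cfg$gamma))
  expect_equal(predict(doubled, j$descriptors), pred, tolerance = 0.01)
})

test_that("svr on equation data predicts no worse than a couple of MPD points vs mlr", {
  j <- gen_joint(synth_config(n = 217, seed = 77))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.43, seed = 78)
  tr <- 1:181; te <- 182:217
  mlr <- fit_mlr(j$descriptors[tr, ], y[tr])
  # hyperparameters tuned on the training set, as in the study protocol
  grid <- expand.grid(C = c(1, 10, 91), epsilon = c(0.05, 0.1, 0.2),
                      gamma = c(0.06, 1 / 6, 0.5))
  cfg <- tune_svr(j$descriptors[tr, ], y[tr], grid, folds = 10, seed = 2)
  svr <- fit_svr(j$descriptors[tr, ], y[tr], cfg)
  mpd_mlr <- mpd(y[te], predict(mlr, j$descriptors[te, ]))$mpd
  mpd_svr <- mpd(y[te], predict(svr, j$descriptors[te, ]))$mpd
  expect_lte(mpd_svr, mpd_mlr + 2)
})

test_that("svr tuning is deterministic, honors ties and degenerate grids", {
  j <- gen_joint(synth_config(n = 100, seed = 91))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.3, seed = 92)
  single <- data.frame(C = 5, epsilon = 0.2, gamma = 0.1)
  got <- tune_svr(j$descriptors, y, single, folds = 5, seed = 3)
  expect_equal(got$C, 5)

  grid <- data.frame(C = c(10, 10), epsilon = c(0.1, 5), gamma = c(0.1, 0.1))
  t1 <- tune_svr(j$descriptors, y, grid, folds = 5, seed = 3)
  t2 <- tune_svr(j$descriptors, y, grid, folds = 5, seed = 3)
  expect_identical(unclass(t1)[1:3], unclass(t2)[1:3])
  # an epsilon tube wider than the response range cannot win
  expect_equal(t1$epsilon, 0.1)
})

test_that("ann matches ols capacity on linear targets and beats it on xor", {
  set.seed(9)
  x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(x %*% c(1, -2, 0.5, 3))
  ols_rmse <- fit_quality(y, predict(suppressWarnings(fit_mlr(x, y)), x))$rmse
  ann <- suppressWarnings(fit_ann(x, y, ann_config(seed = 2)))
  expect_lte(fit_quality(y, predict(ann, x))$rmse, ols_rmse + 0.01)

  set.seed(10)
  x2 <- matrix(runif(400 * 2, -1, 1), 400, 2,
               dimnames = list(NULL, c("a", "b")))
  y2 <- sign(x2[, 1]) * sign(x2[, 2]) + rnorm(400, 0, 0.1)
  r2_mlr <- fit_quality(y2, predict(suppressWarnings(fit_mlr(x2, y2)),
                                    x2))$r2
  ann2 <- suppressWarnings(fit_ann(x2, y2,
                                   ann_config(hidden_units = 4, seed = 4)))
  r2_ann <- fit_quality(y2, predict(ann2, x2))$r2
  expect_gt(r2_ann - r2_mlr, 0.3)
})

test_that("ann training is reproducible from its seed and warns on tiny n", {
  j <- gen_joint(synth_config(n = 181, seed = 21))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.43, seed = 22)
  expect_warning(fit_ann(j$descriptors, y, ann_config(seed = 3)),
                 "10 observations per network weight")
  a1 <- suppressWarnings(fit_ann(j$descriptors, y, ann_config(seed = 3)))
  a2 <- suppressWarnings(fit_ann(j$descriptors, y, ann_config(seed = 3)))
  expect_identical(a1$details$theta, a2$details$theta)
})

test_that("column permutation leaves all model families' predictions unchanged", {
  j <- gen_joint(synth_config(n = 150, seed = 61))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.3, seed = 62)
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- j$descriptors[, perm]
  for (fitter in list(
    function(x, y) suppressWarnings(fit_mlr(x, y)),
    fit_svr,
    function(x, y) suppressWarnings(fit_ann(x, y, ann_config(seed = 5))))) {
    m0 <- fitter(j$descriptors, y)
    mp <- fitter(xp, y)
    expect_equal(predict(mp, j$descriptors), predict(m0, j$descriptors),
                 tolerance = 1e-6)
  }
})

test_that("models serialize to json with their family parameters", {
  j <- gen_joint(synth_config(n = 100, seed = 41))
  y <- gen_equation_response(j$descriptors, noise_sd = 0.3, seed = 42)
  tmp <- withr::local_tempfile(fileext = ".json")
  for (m in list(fit_mlr(j$descriptors, y),
                 fit_svr(j$descriptors, y),
                 suppressWarnings(fit_ann(j$descriptors, y,
                                          ann_config(seed = 1))))) {
    write_model(m, tmp)
    back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
    expect_equal(back$family, m$family)
    expect_equal(back$columns, m$columns)
  }
})
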