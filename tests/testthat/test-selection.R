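test_that("correlation filter applies its three rules and logs them", {
  set.seed(1)
  n <- 60
  x1 <- rnorm(n)
  y <- x1 + rnorm(n, 0, 0.3)
  x2 <- x1 + rnorm(n, 0, 1e-8)            # exact-duplicate pair member
  const <- rep(2, n)
  mostly <- c(rep(0, 57), rnorm(3))       # 95% identical values
  m <- cbind(a = x1, b = x2, c = const, d = mostly,
             e = rnorm(n))
  out <- correlation_filter(m, y)
  expect_setequal(colnames(out$matrix), c("a", "e"))
  log <- out$drop_log
  expect_equal(log$rule[log$column == "c"], "constant")
  expect_equal(log$rule[log$column == "d"], "repeated_values")
  # the less response-correlated duplicate is the one dropped
  expect_equal(log$rule[log$column == "b"], "intercorrelated")
})

test_that("correlation filter is idempotent", {
  g <- gen_wide_matrix(60, 40, 3, seed = 4,
                       redundancy = list(n_dup = 2, n_const = 2))
  once <- correlation_filter(g$descriptors, g$response)
  twice <- correlation_filter(once$matrix, g$response)
  expect_equal(colnames(twice$matrix), colnames(once$matrix))
  expect_equal(nrow(twice$drop_log), 0)
})

test_that("gapls scoring ranks planted variables highly and is deterministic", {
  g <- gen_wide_matrix(100, 20, 3, noise_sd = 0, seed = 2)
  cfg <- gapls_config(n_runs = 5, seed = 3)
  hits <- sapply(1:10, function(i) {
    sc <- gapls_score(g$descriptors, g$response,
                      gapls_config(n_runs = 5, seed = 100 + i))
    top5 <- names(sort(sc, decreasing = TRUE))[1:5]
    all(paste0("inf", 1:3) %in% top5)
  })
  expect_gte(sum(hits), 9)
  expect_identical(gapls_score(g$descriptors, g$response, cfg),
                   gapls_score(g$descriptors, g$response, cfg))
})

test_that("gapls scores are flat when the response is pure noise", {
  set.seed(6)
  x <- matrix(rnorm(80 * 20), 80, 20)
  colnames(x) <- paste0("V", 1:20)
  y <- rnorm(80)
  sc <- gapls_score(x, y, gapls_config(n_runs = 5, seed = 8))
  # no half of the columns scores systematically above the other
  ks <- suppressWarnings(ks.test(sc[1:10], sc[11:20]))
  expect_gt(ks$p.value, 0.01)
})

test_that("iterative gapls reduces a wide pool, keeps planted truth, replays", {
  g <- gen_wide_matrix(181, 244, 6, noise_sd = 0.43, seed = 11)
  cfg <- gapls_config(n_runs = 20, seed = 5)
  res <- iterative_gapls(g$descriptors, g$response, cfg)
  expect_true(all(res$kept %in% colnames(g$descriptors)))
  expect_true(all(paste0("inf", 1:6) %in% res$kept))
  expect_lt(length(res$kept), 244)
  # history replay: kept is the top final_keep_fraction of the last round
  last <- res$history[[length(res$history)]]
  ord <- order(-last$scores, match(names(last$scores), colnames(g$descriptors)))
  n_keep <- max(1, ceiling(cfg$final_keep_fraction * length(last$scores)))
  expect_equal(res$kept, names(last$scores)[ord][seq_len(n_keep)])

  # p below subgroup_size degenerates to a single scored round
  small <- gen_wide_matrix(80, 30, 2, seed = 3)
  res1 <- iterative_gapls(small$descriptors, small$response,
                          gapls_config(n_runs = 3, seed = 4))
  expect_length(res1$history, 1)
})

test_that("stepwise selection recovers planted truth and prunes collinear pairs", {
  set.seed(20)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.5)
  res <- stepwise_select(cbind(x1 = x1, x2 = x2), y)
  expect_equal(res$kept, "x1")

  # null case: nothing enters
  y0 <- rnorm(n)
  res0 <- stepwise_select(cbind(x1 = x1, x2 = x2), y0,
                          p_enter = 0.001)
  expect_length(res0$kept, 0)

  # collinear pair (|r| ~ 0.95): the later entrant is removed and logged
  z1 <- rnorm(n)
  z2 <- 0.95 * scale(z1)[, 1] + sqrt(1 - 0.95^2) * rnorm(n)
  yz <- z1 + z2 + rnorm(n, 0, 0.2)
  resz <- stepwise_select(cbind(z1 = z1, z2 = z2), yz)
  expect_length(resz$kept, 1)
  expect_true("remove_intercorrelated" %in% resz$stepwise_path$action)
  r <- abs(cor(cbind(z1, z2)))[1, 2]
  expect_gt(r, 0.9)
})

test_that("full cascade returns exactly the planted set on synthetic data", {
  g <- gen_wide_matrix(181, 244, 6, noise_sd = 0.43, seed = 17,
                       redundancy = list(n_dup = 2, n_const = 3))
  res <- select_descriptors(g$descriptors, g$response,
                            config = gapls_config(n_runs = 15, seed = 7))
  expect_setequal(res$kept, paste0("inf", 1:6))
  expect_true(all(c("dup1", "dup2") %in%
                    res$drop_log$column[res$drop_log$rule ==
                                          "intercorrelated"]))
})

test_that("selection result serializes to json and reloads", {
  g <- gen_wide_matrix(60, 25, 2, seed = 9)
  res <- iterative_gapls(g$descriptors, g$response,
                         gapls_config(n_runs = 3, seed = 2))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$kept, res$kept)
  expect_equal(unlist(back$scores), res$scores, tolerance = 1e-12)
})

test_that("internal pls1 agrees with an independent pls implementation and ols", {
  set.seed(4)
  x <- scale(matrix(rnorm(30 * 5), 30, 5))
  colnames(x) <- paste0("V", 1:5)
  y <- rnorm(30)
  f2 <- bitterQSBR:::pls1_fit(x, y, 2)
  p2 <- bitterQSBR:::pls1_predict(f2, x, 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, scale = FALSE, mode = "regression")
  expect_equal(p2, unname(predict(ref, x)$predict[, 1, 2]),
               tolerance = 1e-10)
  # with all components PLS1 collapses to ordinary least squares
  f5 <- bitterQSBR:::pls1_fit(x, y, 5)
  expect_equal(bitterQSBR:::pls1_predict(f5, x, 5),
               unname(fitted(lm(y ~ x))), tolerance = 1e-10)
})
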