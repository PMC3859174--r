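#' Filter rules for descriptor screening
#'
#' @param intercorrelation_cutoff Absolute pairwise correlation above which
#'   one member of a descriptor pair is dropped (default 0.99).
#' @param repeat_fraction_min Minimum fraction of cases that must differ
#'   from the modal value: a column whose most frequent value covers more
#'   than `1 - repeat_fraction_min` of cases is dropped (default 0.10, i.e.
#'   the >90 percent-identical rule).
#' @return List of class `filter_rules`.
#' @export
filter_rules <- function(intercorrelation_cutoff = 0.99,
                         repeat_fraction_min = 0.10) {
  stopifnot(intercorrelation_cutoff > 0, intercorrelation_cutoff <= 1,
            repeat_fraction_min > 0, repeat_fraction_min <= 1)
  structure(list(intercorrelation_cutoff = intercorrelation_cutoff,
                 repeat_fraction_min = repeat_fraction_min),
            class = "filter_rules")
}

#' Correlation and repeated-value filter
#'
#' First stage of the selection cascade. Drops, in order: (a) constant
#' columns; (b) columns whose most frequent value occurs in more than
#' 90 percent of cases (configurable); (c) from every pair with absolute
#' intercorrelation above the cutoff, the member less correlated with the
#' response (ties drop the later column). The filter is idempotent.
#'
#' @param matrix Numeric descriptor matrix with column names.
#' @param response Numeric response, same length as `nrow(matrix)`.
#' @param rules A [filter_rules()].
#' @return List: `matrix` (surviving columns), `drop_log` (data.frame of
#'   column, rule).
#' @export
correlation_filter <- function(matrix, response, rules = filter_rules()) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(response)) {
    stop("response length does not match the number of rows")
  }
  if (nrow(matrix) < 3) stop("need at least 3 rows")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  dropped <- character(0); rule <- character(0)
  note <- function(cols, why) {
    dropped <<- c(dropped, cols); rule <<- c(rule, rep(why, length(cols)))
  }

  const <- colnames(matrix)[apply(matrix, 2, function(v) stats::sd(v) == 0)]
  note(const, "constant")
  keep <- setdiff(colnames(matrix), const)

  mode_frac <- vapply(keep, function(cn) {
    max(table(matrix[, cn])) / nrow(matrix)
  }, numeric(1))
  rep_cols <- keep[mode_frac > 1 - rules$repeat_fraction_min]
  note(rep_cols, "repeated_values")
  keep <- setdiff(keep, rep_cols)

  if (length(keep) >= 2) {
    r <- abs(stats::cor(matrix[, keep, drop = FALSE]))
    ry <- abs(stats::cor(matrix[, keep, drop = FALSE], response))[, 1]
    diag(r) <- 0
    repeat {
      hits <- which(r > rules$intercorrelation_cutoff, arr.ind = TRUE)
      if (nrow(hits) == 0) break
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      i <- hits[1, 1]; j <- hits[1, 2]
      loser <- if (ry[i] < ry[j]) i else j   # tie keeps the earlier column
      note(colnames(r)[loser], "intercorrelated")
      r <- r[-loser, -loser, drop = FALSE]
      ry <- ry[-loser]
      if (length(ry) < 2) break
    }
    keep <- names(ry)
  }
  list(matrix = matrix[, keep, drop = FALSE],
       drop_log = data.frame(column = dropped, rule = rule,
                             stringsAsFactors = FALSE))
}

## ---- PLS1 core (NIPALS) ----------------------------------------------

# Fit a PLS1 regression by NIPALS; returns coefficient paths for 1..ncomp
# components on the centered/scaled-by-nothing original variable scale.
pls1_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, p, n - 1)
  xm <- colMeans(x); ym <- mean(y)
  e <- sweep(x, 2, xm); f <- y - ym
  w_mat <- p_mat <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t <- e %*% w
    tt <- sum(t^2)
    pp <- crossprod(e, t) / tt
    q <- sum(f * t) / tt
    e <- e - t %*% t(pp)
    f <- f - q * t
    w_mat[, a] <- w; p_mat[, a] <- pp; qv[a] <- q
  }
  if (ncomp == 0) {
    return(list(xm = xm, ym = ym, beta = matrix(0, p, 1), ncomp = 0))
  }
  w_mat <- w_mat[, seq_len(ncomp), drop = FALSE]
  p_mat <- p_mat[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  r_mat <- w_mat %*% solve(crossprod(p_mat, w_mat))
  beta <- sapply(seq_len(ncomp), function(a) {
    r_mat[, seq_len(a), drop = FALSE] %*% qv[seq_len(a)]
  })
  list(xm = xm, ym = ym, beta = matrix(beta, nrow = p), ncomp = ncomp)
}

pls1_predict <- function(fit, x, ncomp = fit$ncomp) {
  x <- as.matrix(x)
  if (fit$ncomp == 0 || ncomp == 0) return(rep(fit$ym, nrow(x)))
  ncomp <- min(ncomp, fit$ncomp)
  drop(sweep(x, 2, fit$xm) %*% fit$beta[, ncomp]) + fit$ym
}

# Cross-validated explained variance (percent) of a PLS1 model, maximized
# over 1..max_ncomp components; folds is an integer assignment per row.
pls_cv_score <- function(x, y, folds, max_ncomp) {
  x <- as.matrix(x)
  n <- nrow(x)
  max_ncomp <- min(max_ncomp, ncol(x), n - 2)
  press <- matrix(0, max(folds), max_ncomp)
  for (k in seq_len(max(folds))) {
    hold <- folds == k
    fit <- pls1_fit(x[!hold, , drop = FALSE], y[!hold], max_ncomp)
    ncs <- min(max_ncomp, max(fit$ncomp, 1))
    for (a in seq_len(ncs)) {
      pred <- pls1_predict(fit, x[hold, , drop = FALSE], a)
      press[k, a] <- sum((y[hold] - pred)^2)
    }
    if (ncs < max_ncomp) {
      press[k, (ncs + 1):max_ncomp] <- press[k, ncs]
    }
  }
  sstot <- sum((y - mean(y))^2)
  q2 <- 1 - colSums(press) / sstot
  100 * max(q2)
}

## ---- GA-PLS -----------------------------------------------------------

#' GA-PLS configuration
#'
#' Genetic-algorithm internals follow Leardi's published defaults where the
#' method source is silent: population 30, single-point crossover rate 0.5,
#' per-bit mutation 0.01, 100 fitness evaluations per run, 5-fold
#' cross-validation inside the fitness, at most 10 latent variables.
#'
#' @param subgroup_size Maximum variables per scored chunk (default 200).
#' @param n_runs Independent GA repetitions whose scores are averaged
#'   (default 100).
#' @param carry_fraction Fraction of top-scoring variables carried to the
#'   next iteration (default 0.5).
#' @param next_block Variables appended per iteration (default 100).
#' @param final_keep_fraction Fraction kept from the final round
#'   (default 0.2).
#' @param pop_size,crossover_rate,mutation_rate,n_evaluations GA internals.
#' @param max_ncomp Maximum PLS components inside the fitness (default 10).
#' @param cv_folds Cross-validation folds inside the fitness (default 5).
#' @param init_include Expected variables per initial chromosome
#'   (default 5).
#' @param seed Integer seed.
#' @return List of class `gapls_config`.
#' @export
gapls_config <- function(subgroup_size = 200, n_runs = 100,
                         carry_fraction = 0.5, next_block = 100,
                         final_keep_fraction = 0.2, pop_size = 30,
                         crossover_rate = 0.5, mutation_rate = 0.01,
                         n_evaluations = 100, max_ncomp = 10, cv_folds = 5,
                         init_include = 5, seed = 1L) {
  stopifnot(carry_fraction > 0, carry_fraction <= 1,
            final_keep_fraction > 0, final_keep_fraction <= 1,
            subgroup_size >= next_block)
  structure(as.list(environment()), class = "gapls_config")
}

# one GA run over a fixed variable block; returns per-variable scores
gapls_run <- function(x, y, config, run_seed) {
  p <- ncol(x)
  with_seed(run_seed, {
    n <- nrow(x)
    folds <- sample(rep_len(seq_len(config$cv_folds), n))
    fitness_of <- function(mask) {
      if (sum(mask) == 0) return(0)
      max(0, pls_cv_score(x[, mask, drop = FALSE], y, folds,
                          config$max_ncomp))
    }
    p_on <- min(1, config$init_include / p)
    pop <- lapply(seq_len(config$pop_size), function(i) {
      m <- stats::runif(p) < p_on
      if (!any(m)) m[sample.int(p, 1)] <- TRUE
      m
    })
    fit <- vapply(pop, fitness_of, numeric(1))
    hist_mask <- do.call(rbind, pop)
    hist_fit <- fit
    evals <- config$pop_size
    while (evals < config$n_evaluations) {
      # fitness-proportional parent choice (uniform on a flat landscape
      # with fewer than two positive-fitness chromosomes)
      pr <- if (sum(fit > 0) >= 2) fit / sum(fit) else
        rep(1 / length(fit), length(fit))
      parents <- sample.int(length(pop), 2, prob = pr)
      a <- pop[[parents[1]]]; b <- pop[[parents[2]]]
      child <- if (stats::runif(1) < config$crossover_rate && p > 1) {
        cut <- sample.int(p - 1, 1)
        c(a[seq_len(cut)], b[(cut + 1):p])
      } else a
      flip <- stats::runif(p) < config$mutation_rate
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(p, 1)] <- TRUE
      f <- fitness_of(child)
      evals <- evals + 1
      worst <- which.min(fit)
      if (f > fit[worst]) { pop[[worst]] <- child; fit[worst] <- f }
      hist_mask <- rbind(hist_mask, child)
      hist_fit <- c(hist_fit, f)
    }
    # mean selection frequency weighted by fitness across the history
    drop(crossprod(hist_mask, hist_fit)) / length(hist_fit)
  })
}

#' Score variables of one block by GA-PLS
#'
#' Runs `n_runs` independent genetic algorithms over binary
#' inclusion chromosomes; the fitness is the cross-validated percentage of
#' explained variance of a PLS regression on the included variables. The
#' per-variable score is the mean selection frequency weighted by fitness,
#' averaged over runs; run-to-run variability is why downstream stages
#' carry the top half rather than a fixed short list.
#'
#' @param matrix Numeric descriptor matrix (p <= `subgroup_size`).
#' @param response Numeric response.
#' @param config A [gapls_config()].
#' @return Named numeric vector of per-variable scores.
#' @export
gapls_score <- function(matrix, response, config = gapls_config()) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 2) stop("need at least 2 variables")
  if (ncol(matrix) > config$subgroup_size) {
    stop("block exceeds subgroup_size; use iterative_gapls()")
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  run_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max, config$n_runs))
  scores <- vapply(run_seeds,
                   function(s) gapls_run(matrix, response, config, s),
                   numeric(ncol(matrix)))
  out <- rowMeans(matrix(scores, nrow = ncol(matrix)))
  names(out) <- colnames(matrix)
  out
}

#' Iterative GA-PLS over a wide descriptor matrix
#'
#' Chunks the variables into subgroups of at most `subgroup_size`, scores
#' the first chunk by [gapls_score()], carries its top `carry_fraction`
#' forward merged with the next `next_block` variables, and repeats until
#' the pool is exhausted; the final round keeps its top
#' `final_keep_fraction`. Ties in the carry sort are broken by score
#' descending then column position ascending (stable).
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param config A [gapls_config()].
#' @return List of class `selection_result`: `kept` (ordered names),
#'   `scores` (final-round scores), `history` (per-iteration membership and
#'   scores), `stepwise_path` (NULL here).
#' @export
iterative_gapls <- function(matrix, response, config = gapls_config()) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  pool <- colnames(matrix)
  ord <- stats::setNames(seq_along(pool), pool)
  current <- pool[seq_len(min(config$subgroup_size, length(pool)))]
  remaining <- setdiff(pool, current)
  history <- list()
  it <- 0
  repeat {
    it <- it + 1
    sub_config <- config
    sub_config$seed <- config$seed + it
    scores <- gapls_score(matrix[, current, drop = FALSE], response,
                          sub_config)
    rank_ord <- order(-scores, ord[names(scores)])
    history[[it]] <- list(members = current, scores = scores)
    if (length(remaining) == 0) {
      n_keep <- max(1, ceiling(config$final_keep_fraction * length(scores)))
      kept <- names(scores)[rank_ord][seq_len(n_keep)]
      break
    }
    n_carry <- max(1, ceiling(config$carry_fraction * length(scores)))
    carried <- names(scores)[rank_ord][seq_len(n_carry)]
    nxt <- remaining[seq_len(min(config$next_block, length(remaining)))]
    remaining <- setdiff(remaining, nxt)
    current <- c(carried, nxt)
  }
  structure(list(kept = kept, scores = scores, history = history,
                 stepwise_path = NULL),
            class = "selection_result")
}

#' Forward-stepwise regression with removal and an intercorrelation check
#'
#' Classical F-test-based stepwise selection: at each step the candidate
#' with the smallest enter p-value below `p_enter` is added, then any kept
#' variable whose removal p-value exceeds `p_remove` is dropped. After
#' convergence any kept pair with absolute correlation at or above 0.9 is
#' resolved by removing the later entrant, and the model is refit.
#'
#' @param matrix Numeric descriptor matrix with column names.
#' @param response Numeric response.
#' @param p_enter,p_remove Enter/remove significance levels (defaults
#'   0.05 / 0.10).
#' @param intercorrelation_max Kept-pair absolute correlation limit
#'   (default 0.9).
#' @return A `selection_result` with `kept`, `scores` (enter-step F
#'   statistics), `stepwise_path` (data.frame of enter/remove events).
#' @export
stepwise_select <- function(matrix, response, p_enter = 0.05,
                            p_remove = 0.10, intercorrelation_max = 0.9) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  d <- data.frame(.y = response, matrix, check.names = FALSE)
  kept <- character(0)
  path <- data.frame(step = integer(0), action = character(0),
                     variable = character(0), p_value = numeric(0))
  fstats <- c()
  step_i <- 0
  refit <- function(vars) {
    fm <- if (length(vars) == 0) ".y ~ 1" else
      paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + "))
    stats::lm(stats::as.formula(fm), data = d)
  }
  repeat {
    changed <- FALSE
    cands <- setdiff(colnames(matrix), kept)
    if (length(cands) > 0 && nrow(matrix) > length(kept) + 2) {
      fit0 <- refit(kept)
      scope <- stats::as.formula(
        paste("~ . +", paste(sprintf("`%s`", cands), collapse = " + ")))
      a1 <- stats::add1(fit0, scope = scope, test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) > 0 && min(pv) < p_enter) {
        best <- names(pv)[which.min(pv)]
        best_clean <- gsub("`", "", best)
        kept <- c(kept, best_clean)
        step_i <- step_i + 1
        fobs <- a1[best, "F value"]
        fstats[best_clean] <- fobs
        path <- rbind(path, data.frame(step = step_i, action = "enter",
                                       variable = best_clean,
                                       p_value = min(pv)))
        changed <- TRUE
      }
    }
    if (length(kept) > 1) {
      fit1 <- refit(kept)
      d1 <- stats::drop1(fit1, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- gsub("`", "", rownames(d1)[-1])
      pv <- pv[!is.na(pv)]
      if (length(pv) > 0 && max(pv) > p_remove) {
        worst <- names(pv)[which.max(pv)]
        kept <- setdiff(kept, worst)
        step_i <- step_i + 1
        path <- rbind(path, data.frame(step = step_i, action = "remove",
                                       variable = worst,
                                       p_value = max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # final bivariate intercorrelation check: drop the later entrant
  if (length(kept) > 1) {
    repeat {
      r <- abs(stats::cor(matrix[, kept, drop = FALSE]))
      diag(r) <- 0
      if (max(r) < intercorrelation_max) break
      hit <- which(r == max(r), arr.ind = TRUE)[1, ]
      later <- kept[max(hit)]
      kept <- setdiff(kept, later)
      step_i <- step_i + 1
      path <- rbind(path, data.frame(step = step_i,
                                     action = "remove_intercorrelated",
                                     variable = later, p_value = NA_real_))
    }
  }
  structure(list(kept = kept, scores = fstats[kept],
                 history = NULL, stepwise_path = path),
            class = "selection_result")
}

#' Full three-stage descriptor-selection cascade
#'
#' Correlation/repeated-value filter, then iterative GA-PLS, then stepwise
#' regression with the final intercorrelation check.
#'
#' The stepwise stage screens every GA survivor at every step, so with the
#' classical per-test 0.05 entry level the minimum p-value over dozens of
#' null candidates is routinely below the cutoff and spurious variables
#' enter. By default the cascade therefore Bonferroni-adjusts the entry
#' level to 0.05 / m (m = number of GA-kept candidates); pass an explicit
#' `p_enter` to override.
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param rules A [filter_rules()].
#' @param config A [gapls_config()].
#' @param p_enter Stepwise entry level; `NULL` (default) uses the
#'   multiplicity-adjusted 0.05 / m.
#' @param p_remove Stepwise removal level (default twice the entry level).
#' @return A `selection_result` from the stepwise stage, with the filter
#'   drop log in `$drop_log` and the GA-PLS result in `$gapls`.
#' @export
select_descriptors <- function(matrix, response, rules = filter_rules(),
                               config = gapls_config(), p_enter = NULL,
                               p_remove = NULL) {
  filt <- correlation_filter(matrix, response, rules)
  ga <- iterative_gapls(filt$matrix, response, config)
  if (is.null(p_enter)) p_enter <- 0.05 / max(length(ga$kept), 1)
  if (is.null(p_remove)) p_remove <- 2 * p_enter
  sw <- stepwise_select(filt$matrix[, ga$kept, drop = FALSE], response,
                        p_enter, p_remove)
  sw$drop_log <- filt$drop_log
  sw$gapls <- ga
  sw
}

#' Serialize a selection result to JSON
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  out <- list(kept = result$kept, scores = as.list(result$scores),
              history = lapply(result$history, function(h)
                list(members = h$members, scores = as.list(h$scores))),
              stepwise_path = result$stepwise_path)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
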