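#' Regenerate the headline statistics tables from the packaged dataset
#'
#' From a loaded bitterness dataset with reference predictions, recomputes
#' the external-validation criteria of the three models on the test
#' partition and the fit-quality statistics per partition and for the
#' whole set, plus MPD per model and partition — the package's versions
#' of the reference study's summary tables.
#'
#' @param dataset A [load_dataset()] result with prediction columns.
#' @return List: `external` (data.frame, one row per model),
#'   `fit` (data.frame keyed model x partition), `mpd` (data.frame).
#' @export
reproduce_tables <- function(dataset = load_dataset(bitter_fixture_path())) {
  models <- c(mlr = "pred_mlr", svm = "pred_svm", ann = "pred_ann")
  models <- models[models %in% names(dataset)]
  test <- dataset[dataset$partition == "test", ]
  external <- do.call(rbind, lapply(names(models), function(m) {
    ec <- external_criteria(test$observed, test[[models[[m]]]])
    data.frame(model = m, r2 = ec$r2, r2_r0_ratio = (ec$r2 - ec$r0_sq) / ec$r2,
               k = ec$k, r0_gap = abs(ec$r0_sq - ec$r0_prime_sq),
               rm_sq = ec$rm_sq)
  }))
  parts <- list(training = "training", test = "test",
                validation = "validation",
                test_and_validation = c("test", "validation"),
                whole = c("training", "test", "validation"))
  fit <- do.call(rbind, lapply(names(models), function(m) {
    do.call(rbind, lapply(names(parts), function(pn) {
      sub <- dataset[dataset$partition %in% parts[[pn]], ]
      fq <- fit_quality(sub$observed, sub[[models[[m]]]], p = 6)
      data.frame(model = m, partition = pn, n = fq$n, r2 = fq$r2,
                 adj_r2 = fq$adj_r2, r = sqrt(fq$r2), rmse = fq$rmse)
    }))
  }))
  mpd_tab <- do.call(rbind, lapply(names(models), function(m) {
    do.call(rbind, lapply(c("training", "test", "validation"), function(pn) {
      sub <- dataset[dataset$partition == pn, ]
      e <- mpd(sub$observed, sub[[models[[m]]]])
      data.frame(model = m, partition = pn, mpd = e$mpd, sd = e$sd, n = e$n)
    }))
  }))
  list(external = external, fit = fit, mpd = mpd_tab)
}

default_pipeline_config <- function() {
  list(
    input = list(type = "fixture", path = NULL,
                 synthetic = list(n = 181, noise_sd = 0.43)),
    screen = list(threshold = 3),
    partition = list(source = "column", n_clusters = 10,
                     fractions = c(training = 0.79, test = 0.16,
                                   validation = 0.05)),
    models = c("published"),
    svr = list(C = 91, epsilon = 0.07, gamma = 0.06, folds = 10),
    ann = list(hidden_units = 3),
    validation = list(external = TRUE, n_shuffles = 10, lmo_folds = 10),
    out_dir = NULL,
    seed = 1L)
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(default_pipeline_config(), config)
  if (!config$input$type %in% c("fixture", "csv", "synthetic")) {
    stop("input$type must be fixture, csv or synthetic")
  }
  if (config$input$type == "csv" &&
      (is.null(config$input$path) || !file.exists(config$input$path))) {
    stop("input$path missing or not found")
  }
  bad <- setdiff(config$models, c("published", "mlr", "svr", "ann"))
  if (length(bad) > 0) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("out_dir is required")
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes load/simulate, outlier screening, partitioning, model fitting
#' and validation in order, writing every artifact (resolved config,
#' per-model validation reports as JSON and a plain-text table, serialized
#' models, log) into `out_dir`. All stochastic stages derive from the
#' single `seed`, so a rerun with the same config and seed reproduces the
#' run. Any stage failure aborts with the stage name; a manifest of the
#' artifacts written so far is saved as `manifest.json`.
#'
#' For `input$type = "fixture"` (or `"csv"` with prediction columns) the
#' packaged reference predictions are validated directly, which
#' regenerates the published-table statistics; for `"synthetic"` the
#' six-descriptor generator supplies data and the requested model families
#' are fit and validated.
#'
#' @param config A list, or a path to a YAML file, with the structure of
#'   `default_pipeline_config()`; `out_dir` is mandatory.
#' @return The output directory, invisibly; its `report.json` holds all
#'   validation reports.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log_lines <- character(0)
  emit <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  finish <- function() {
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"))
  }
  stage <- function(name, expr) {
    emit("stage %s", name)
    tryCatch(expr, error = function(e) {
      emit("stage %s failed: %s", name, conditionMessage(e))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  save_artifact <- function(obj, file, writer = NULL) {
    path <- file.path(config$out_dir, file)
    if (is.null(writer)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           null = "null")
    } else writer(obj, path)
    manifest <<- c(manifest, file)
    path
  }

  save_artifact(config, "config.yaml", function(o, p) yaml::write_yaml(o, p))
  emit("seed %d", config$seed)

  data <- stage("input", {
    switch(config$input$type,
      fixture = {
        d <- load_dataset(bitter_fixture_path())
        list(descriptors = NULL, response = d$observed, dataset = d,
             partition = d$partition)
      },
      csv = {
        d <- load_dataset(config$input$path)
        list(descriptors = NULL, response = d$observed, dataset = d,
             partition = d$partition)
      },
      synthetic = {
        cfg <- synth_config(n = config$input$synthetic$n,
                            noise_sd = config$input$synthetic$noise_sd,
                            seed = config$seed)
        j <- gen_joint(cfg)
        y <- gen_equation_response(j$descriptors, noise_sd = cfg$noise_sd,
                                   seed = config$seed + 1)
        list(descriptors = j$descriptors, response = y, dataset = NULL,
             partition = NULL)
      })
  })

  stage("screen", {
    out <- screen_outliers(data$response, config$screen$threshold)
    emit("outlier screen at |z| >= %.1f: %d flagged",
         config$screen$threshold, length(out))
    save_artifact(list(threshold = config$screen$threshold,
                       flagged = out), "outliers.json")
  })

  partition <- stage("partition", {
    if (!is.null(data$partition) && config$partition$source == "column") {
      factor(data$partition, levels = c("training", "test", "validation"))
    } else {
      feats <- if (is.null(data$descriptors)) cbind(response = data$response)
               else cbind(data$descriptors, response = data$response)
      km <- kmeans_partition(feats, config$partition$n_clusters,
                             unlist(config$partition$fractions),
                             seed = config$seed)
      km$labels
    }
  })

  reports <- list()
  stage("fit_validate", {
    parts <- list(training = "training", test = "test",
                  validation = "validation")
    get_part <- function(lab) which(partition %in% parts[[lab]])
    if (!is.null(data$dataset)) {
      cols <- c(published = "pred_mlr", mlr = "pred_mlr", svm = "pred_svm",
                ann = "pred_ann")
      for (m in intersect(names(cols), c("published", "svm", "ann", "mlr"))) {
        if (!cols[[m]] %in% names(data$dataset)) next
        for (pn in names(parts)) {
          idx <- get_part(pn)
          reports[[paste(m, pn, sep = ".")]] <- validation_report(
            data$dataset$observed[idx], data$dataset[[cols[[m]]]][idx],
            model = m, partition = pn)
        }
      }
    } else {
      tr <- get_part("training")
      for (m in config$models) {
        model <- switch(m,
          published = new_qsbr_model("published",
                                     names(published_coefficients()$slopes),
                                     function(x) predict_published(x)),
          mlr = fit_mlr(data$descriptors[tr, , drop = FALSE],
                        data$response[tr]),
          svr = fit_svr(data$descriptors[tr, , drop = FALSE],
                        data$response[tr],
                        svr_config(config$svr$C, config$svr$epsilon,
                                   config$svr$gamma, config$svr$folds)),
          ann = fit_ann(data$descriptors[tr, , drop = FALSE],
                        data$response[tr],
                        ann_config(config$ann$hidden_units,
                                   seed = config$seed)))
        if (m != "published") {
          save_artifact(model, paste0("model_", m, ".json"),
                        function(o, p) write_model(o, p))
        }
        for (pn in names(parts)) {
          idx <- get_part(pn)
          if (length(idx) < 3) next
          reports[[paste(m, pn, sep = ".")]] <- validation_report(
            data$response[idx],
            predict(model, data$descriptors[idx, , drop = FALSE]),
            model = m, partition = pn,
            p = ncol(data$descriptors))
        }
      }
    }
  })

  stage("report", {
    rep <- make_report(reports)
    save_artifact(reports, "report.json",
                  function(o, p) write_validation_reports(o, p))
    writeLines(rep$text, file.path(config$out_dir, "report.txt"))
    manifest <- c(manifest, "report.txt")
    utils::write.csv(rep$ipd_bins, file.path(config$out_dir, "ipd_bins.csv"),
                     row.names = FALSE)
    manifest <- c(manifest, "ipd_bins.csv")
  })

  emit("done: %d reports", length(reports))
  finish()
  invisible(config$out_dir)
}

#' Assemble validation reports into one table
#'
#' @param results A named list of `validation_report`s.
#' @return List: `table` (data.frame keyed model x partition), `ipd_bins`
#'   (data.frame of bin fractions), `text` (plain-text rendering).
#' @export
make_report <- function(results) {
  if (inherits(results, "validation_report")) results <- list(results)
  if (length(results) == 0) stop("need at least one validation report")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r$model, partition = r$partition, n = r$n,
               mpd = r$mpd, mpd_sd = r$mpd_sd, r2 = r$fit$r2,
               rmse = r$fit$rmse,
               rm_sq = if (!is.null(r$external)) r$external$rm_sq
                       else NA_real_)
  }))
  rownames(tab) <- NULL
  bins <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r$model, partition = r$partition,
               lt15 = r$ipd_bins[["lt15"]], b15_30 = r$ipd_bins[["b15_30"]],
               gt30 = r$ipd_bins[["gt30"]])
  }))
  rownames(bins) <- NULL
  header <- sprintf("%-10s %-12s %4s %6s %6s %6s %6s", "model", "partition",
                    "n", "MPD", "R2", "RMSE", "Rm2")
  rows <- sprintf("%-10s %-12s %4d %6.1f %6.3f %6.3f %6s",
                  tab$model, tab$partition, tab$n, tab$mpd, tab$r2, tab$rmse,
                  ifelse(is.na(tab$rm_sq), "", sprintf("%.3f", tab$rm_sq)))
  list(table = tab, ipd_bins = bins, text = c(header, rows))
}
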