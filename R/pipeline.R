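#' Run configuration for the end-to-end drivers
#'
#' @param preprocess a [preprocess_config()].
#' @param k CV segments (default 10).
#' @param A_max maximum candidate factor count (default 10).
#' @param alpha uncertainty-test significance level (default 0.05).
#' @param max_iter elimination iteration cap (default 10).
#' @param train_fraction pooled-model training share (default 2/3).
#' @param screen_outliers logical, run influential-outlier screening before
#'   elimination (default TRUE).
#' @param seed master integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(), k = 10L,
                       A_max = 10L, alpha = 0.05, max_iter = 10L,
                       train_fraction = 2 / 3, screen_outliers = TRUE,
                       seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(preprocess = preprocess, k = k, A_max = A_max,
                 alpha = alpha, max_iter = max_iter,
                 train_fraction = train_fraction,
                 screen_outliers = screen_outliers, seed = seed),
            class = "run_config")
}

# preprocess + assemble the X matrix / y vector for a sample subset
assemble_xy <- function(spectra, records, config) {
  proc <- preprocess_pipeline(spectra, config$preprocess)
  X <- proc$matrix
  colnames(X) <- as.character(proc$wavelengths)
  list(X = X, y = records$delta15N, wavelengths = proc$wavelengths,
       ids = proc$sample_ids)
}

#' Species-specific model run
#'
#' The full inference chain for one species: structural filters (mature-leaf
#' exclusion where the labeling failed), spectral preprocessing,
#' influential-outlier screening, iterated uncertainty-test wavelength
#' elimination, and reporting: a one-row model report (the conventional
#' calibration-table record), the elimination trace, a VIP-by-wavelength
#' table, and measured-versus-predicted pairs normalized by the minimum
#' measured value (to display values as enrichment over the unlabeled
#' level).
#'
#' @param spectra a raw [spectra_set].
#' @param records matching metadata.
#' @param species species label to model.
#' @param config a [run_config].
#' @param exclude_mature logical: drop this species' mature leaves first
#'   (the failed-uptake filter; default FALSE).
#' @param min_n minimum samples required after filters (default 20).
#' @return list of class `species_run`: `report` (data.frame row),
#'   `elimination`, `vip_table`, `predictions`, `outliers_removed`,
#'   `species`, `seed`.
#' @export
run_species_model <- function(spectra, records, species, config = run_config(),
                              exclude_mature = FALSE, min_n = 20L) {
  keep <- records$species == species
  if (!any(keep)) stop("no samples for species ", species)
  sub_rec <- records[keep, , drop = FALSE]
  sub_set <- subset_samples(spectra, match(sub_rec$sample_id,
                                           spectra$sample_ids))
  if (exclude_mature) {
    flt <- exclude_unlabeled_mature(sub_set, sub_rec, species)
    sub_set <- flt$spectra
    sub_rec <- flt$records
  }
  if (nrow(sub_rec) < min_n)
    stop("only ", nrow(sub_rec), " samples after filters (need >= ", min_n, ")")

  dat <- assemble_xy(sub_set, sub_rec, config)
  X <- dat$X
  y <- dat$y
  ids <- dat$ids

  outliers <- character()
  if (config$screen_outliers) {
    cv0 <- cross_validate(X, y, config$A_max, config$k, config$seed)
    flag <- detect_influential_outliers(X, y, cv0$A_selected)
    if (length(flag)) {
      outliers <- ids[flag]
      message("removing ", length(flag), " influential outlier(s): ",
              paste(outliers, collapse = ", "))
      X <- X[-flag, , drop = FALSE]
      y <- y[-flag]
      ids <- ids[-flag]
    }
  }

  elim <- iterative_elimination(X, y, config$A_max, config$k, config$seed,
                                config$alpha, config$max_iter)
  cv <- elim$cv
  cal_hat <- predict(cv$fit_full, X[, elim$variables, drop = FALSE])
  stats <- model_statistics(y, cal_hat, elim$cv_predictions)
  report <- cbind(data.frame(species = species, n = length(y),
                             n_factors = cv$A_selected,
                             n_x_variables = length(elim$variables),
                             n_mut_iterations = elim$n_iterations),
                  stats, data.frame(seed = config$seed))

  v <- vip(cv$fit_full)
  vip_table <- data.frame(wavelength = as.numeric(elim$variables),
                          vip = unname(v))
  y0 <- min(y)
  predictions <- data.frame(sample_id = ids, measured = y,
                            predicted_cal = cal_hat,
                            predicted_cv = elim$cv_predictions,
                            measured_norm = y - y0,
                            predicted_cv_norm = elim$cv_predictions - y0)
  structure(list(report = report, elimination = elim, vip_table = vip_table,
                 predictions = predictions, outliers_removed = outliers,
                 species = species, seed = config$seed),
            class = "species_run")
}

#' @export
print.species_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("species model [%s]: n = %d, %d factor(s), %d ",
                     "wavelength(s), %d elimination pass(es)\n"),
              x$species, r$n, r$n_factors, r$n_x_variables,
              r$n_mut_iterations))
  cat(sprintf("  R2_cal = %.2f, R2_cv = %.2f, RMSE_cal = %.2f, RMSE_cv = %.2f (%.1f%% of range)\n",
              r$r2_cal, r$r2_cv, r$rmse_cal, r$rmse_cv, r$rmse_cv_pct_range))
  invisible(x)
}

#' Pooled model across species with an independent test set
#'
#' Randomly assigns `train_fraction` of the samples (default 2/3) to a
#' training set — stratified by species so no species can be absent from
#' either side — fits the full species-model procedure to the training set,
#' and evaluates on the held-out third. Also reports the factor-1/2 scores
#' labeled by species and a between-/within-species score variance ratio:
#' when species baselines dominate the spectra, the leading factors separate
#' species rather than resolving the isotope signal within species.
#'
#' @param spectra a raw [spectra_set].
#' @param records matching metadata (needs >= 2 species).
#' @param config a [run_config].
#' @return list of class `pooled_run`: `report_train`, `report_test`
#'   (slope/offset/R2/RMSE on the test set), `scores` (factor 1-2 scores by
#'   species), `separation_ratio`, `split` (sample assignment), `elimination`.
#' @export
run_pooled_model <- function(spectra, records, config = run_config()) {
  species <- unique(records$species)
  if (length(species) < 2L) stop("pooled model needs >= 2 species")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  in_train <- logical(nrow(records))
  for (sp in species) {
    idx <- which(records$species == sp)
    n_tr <- max(1L, round(config$train_fraction * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    in_train[sample(idx, n_tr)] <- TRUE
  }

  dat <- assemble_xy(spectra, records, config)
  X_tr <- dat$X[in_train, , drop = FALSE]
  y_tr <- dat$y[in_train]
  X_te <- dat$X[!in_train, , drop = FALSE]
  y_te <- dat$y[!in_train]

  elim <- iterative_elimination(X_tr, y_tr, config$A_max, config$k,
                                config$seed, config$alpha, config$max_iter)
  cv <- elim$cv
  fit <- cv$fit_full
  cal_hat <- predict(fit, X_tr[, elim$variables, drop = FALSE])
  report_train <- cbind(data.frame(n = length(y_tr),
                                   n_factors = cv$A_selected,
                                   n_x_variables = length(elim$variables)),
                        model_statistics(y_tr, cal_hat, elim$cv_predictions))

  te_hat <- predict(fit, X_te[, elim$variables, drop = FALSE])
  f <- stats::lm.fit(cbind(1, y_te), te_hat)
  report_test <- data.frame(
    n = length(y_te),
    offset = unname(f$coefficients[1L]), slope = unname(f$coefficients[2L]),
    r2 = 1 - sum((y_te - te_hat)^2) / sum((y_te - mean(y_te))^2),
    rmse = sqrt(mean((y_te - te_hat)^2)),
    rmse_pct_range = 100 * sqrt(mean((y_te - te_hat)^2)) /
      (max(y_te) - min(y_te)))

  # per-species test-set skill (the within-species resolution diagnostic)
  sp_te <- records$species[!in_train]
  within <- do.call(rbind, lapply(species, function(sp) {
    m <- sp_te == sp
    data.frame(species = sp, n = sum(m),
               r2_within = 1 - sum((y_te[m] - te_hat[m])^2) /
                 sum((y_te[m] - mean(y_te[m]))^2))
  }))

  n_fac <- min(2L, fit$ncomp)
  scores <- data.frame(sample_id = dat$ids[in_train],
                       species = records$species[in_train],
                       fit$scores[, seq_len(n_fac), drop = FALSE])
  names(scores)[-(1:2)] <- paste0("factor", seq_len(n_fac))
  grand <- mean(scores$factor1)
  sp_means <- tapply(scores$factor1, scores$species, mean)
  sp_sizes <- tapply(scores$factor1, scores$species, length)
  between <- sum(sp_sizes * (sp_means - grand)^2) / (length(sp_means) - 1)
  within_var <- sum((scores$factor1 -
                       sp_means[scores$species])^2) /
    (nrow(scores) - length(sp_means))
  structure(list(report_train = report_train, report_test = report_test,
                 within_species_test = within, scores = scores,
                 separation_ratio = between / within_var,
                 split = ifelse(in_train, "train", "test"),
                 elimination = elim, seed = config$seed),
            class = "pooled_run")
}

#' @export
print.pooled_run <- function(x, ...) {
  cat(sprintf("pooled model: train n = %d (R2_cv = %.2f), test n = %d (R2 = %.2f)\n",
              x$report_train$n, x$report_train$r2_cv, x$report_test$n,
              x$report_test$r2))
  cat(sprintf("  factor-1 species separation (between/within variance) = %.1f\n",
              x$separation_ratio))
  invisible(x)
}

#' Write a run's outputs as a CSV/JSON bundle
#'
#' Emits the model-report CSV (one row per species run), the VIP table, the
#' elimination trace, the prediction pairs, the retained-wavelength list
#' (one nm per line) and a JSON manifest (seeds, config, package version)
#' sufficient for an exact rerun. Figures are emitted as data tables, not
#' images.
#'
#' @param runs list of `species_run` and/or `pooled_run` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
report_run <- function(runs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(runs, "species_run") || inherits(runs, "pooled_run"))
    runs <- list(runs)
  complete <- TRUE
  reports <- list()
  for (r in runs) {
    if (inherits(r, "species_run")) {
      tag <- gsub("[^A-Za-z0-9]", "", r$species)
      reports[[length(reports) + 1L]] <- r$report
      utils::write.csv(r$vip_table,
                       file.path(dir, paste0("vip_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(r$elimination$trace,
                       file.path(dir, paste0("trace_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(r$predictions,
                       file.path(dir, paste0("predictions_", tag, ".csv")),
                       row.names = FALSE)
      writeLines(r$elimination$variables,
                 file.path(dir, paste0("wavelengths_", tag, ".txt")))
    } else if (inherits(r, "pooled_run")) {
      utils::write.csv(r$report_train, file.path(dir, "pooled_train.csv"),
                       row.names = FALSE)
      utils::write.csv(r$report_test, file.path(dir, "pooled_test.csv"),
                       row.names = FALSE)
      utils::write.csv(r$scores, file.path(dir, "pooled_scores.csv"),
                       row.names = FALSE)
    } else {
      complete <- FALSE
    }
  }
  if (length(reports))
    utils::write.csv(do.call(rbind, reports),
                     file.path(dir, "model_reports.csv"), row.names = FALSE)
  manifest <- list(
    package = "isopls",
    version = as.character(utils::packageVersion("isopls")),
    seeds = vapply(runs, function(r) r$seed, numeric(1L)),
    complete = complete,
    written = format(Sys.time(), tz = "UTC"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
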