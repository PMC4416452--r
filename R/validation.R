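#' Random k-fold segment assignment
#'
#' Partitions n samples into k random segments of size floor(n/k) or
#' ceiling(n/k); reproducible under `seed`.
#'
#' @param n number of samples.
#' @param k number of segments (default 10).
#' @param seed integer seed (mandatory: no hidden global randomness).
#' @return Integer vector of length n with values in 1..k.
#' @export
kfold_split <- function(n, k = 10L, seed) {
  if (missing(seed)) stop("seed is required")
  if (k > n) stop("k must not exceed n")
  force(seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Truncate a PLS1 model to its first factors
#'
#' Returns the model using only factors `1..a` (NIPALS factors are nested),
#' with weights, loadings, coefficients, explained sums of squares and
#' fitted values recomputed accordingly.
#'
#' @param model a [pls1] model.
#' @param a factor count, `a <= model$ncomp`.
#' @return A [pls1] model with `ncomp = a`.
#' @export
pls1_truncate <- function(model, a) {
  stopifnot(inherits(model, "pls1"))
  a <- as.integer(min(a, model$ncomp))
  if (a == model$ncomp) return(model)
  m <- model
  m$ncomp <- a
  m$weights <- model$weights[, seq_len(a), drop = FALSE]
  m$x_loadings <- model$x_loadings[, seq_len(a), drop = FALSE]
  m$y_loadings <- model$y_loadings[seq_len(a)]
  m$scores <- model$scores[, seq_len(a), drop = FALSE]
  m$ss_y_per_factor <- model$ss_y_per_factor[seq_len(a)]
  ca <- pls1_coef_at(model, a)
  m$coef_raw <- ca$coef
  m$intercept <- ca$intercept
  b_scaled <- numeric(length(model$kept))
  b_scaled[model$kept] <- (ca$coef[model$kept] / model$y_sd) * model$x_sd
  m$coef_scaled <- stats::setNames(b_scaled, model$variables)
  # calibration fit from the retained scores: y_hat = y_mean + y_sd * T q
  m$fitted_values <- model$y_mean +
    model$y_sd * drop(m$scores %*% m$y_loadings)
  m$residuals <- model$y - m$fitted_values
  m
}

# coefficients of a pls1 fit truncated to a factors (raw metric + intercept)
pls1_coef_at <- function(model, a) {
  a <- min(a, model$ncomp)
  W <- model$weights[, seq_len(a), drop = FALSE]
  P <- model$x_loadings[, seq_len(a), drop = FALSE]
  q <- model$y_loadings[seq_len(a)]
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b_raw <- b_scaled * model$y_sd / model$x_sd
  intercept <- model$y_mean - sum(b_raw * model$x_mean)
  b_full <- numeric(length(model$kept))
  b_full[model$kept] <- b_raw
  list(coef = stats::setNames(b_full, model$variables), intercept = intercept)
}

#' k-fold cross-validation of PLS1
#'
#' For each segment the model is fitted on the remaining samples —
#' re-estimating the autoscaling on that training fold only — and the
#' held-out segment is predicted for every candidate factor count 1..A_max.
#' RMSE of cross-validation per factor count is computed over all held-out
#' predictions; the factor count is then chosen by the first-local-minimum
#' rule and the per-segment coefficient vectors at that count are stored
#' (the raw material of the jackknife uncertainty test).
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param A_max maximum candidate factor count.
#' @param k segments (default 10).
#' @param seed integer seed for the segment randomization.
#' @return An object of class `pls1_cv`: list with `k`, `seed`,
#'   `assignments`, `rmse_cv_per_A`, `A_selected`, `cv_predictions` (held-out
#'   predictions at the selected count), `submodel_coefficients` (k x p,
#'   raw metric), `submodel_intercepts`, and the full-data fit `fit_full`.
#' @export
cross_validate <- function(X, y, A_max, k = 10L, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  assignments <- kfold_split(n, k, seed)
  max_train <- n - max(tabulate(assignments, k))
  A_max <- min(A_max, max_train - 1L, ncol(X))
  if (A_max < 1L) stop("not enough samples per training fold")

  pred <- matrix(NA_real_, n, A_max)
  fold_fits <- vector("list", k)
  for (s in seq_len(k)) {
    hold <- assignments == s
    fit <- suppressWarnings(pls1(X[!hold, , drop = FALSE], y[!hold], A_max))
    fold_fits[[s]] <- fit
    for (a in seq_len(A_max)) {
      ca <- pls1_coef_at(fit, a)
      pred[hold, a] <- drop(X[hold, , drop = FALSE] %*% ca$coef) + ca$intercept
    }
  }
  rmse <- sqrt(colMeans((pred - y)^2))
  A_sel <- select_n_factors(rmse, quiet = TRUE)

  B <- matrix(0, k, ncol(X), dimnames = list(NULL, colnames(X)))
  b0 <- numeric(k)
  for (s in seq_len(k)) {
    ca <- pls1_coef_at(fold_fits[[s]], A_sel)
    B[s, ] <- ca$coef
    b0[s] <- ca$intercept
  }
  # full-data fit reported at the selected factor count
  fit_full <- pls1_truncate(suppressWarnings(pls1(X, y, A_max)), A_sel)

  structure(list(k = k, seed = seed, assignments = assignments,
                 rmse_cv_per_A = rmse, A_selected = A_sel,
                 cv_predictions = pred[, A_sel], cv_predictions_per_A = pred,
                 submodel_coefficients = B, submodel_intercepts = b0,
                 fit_full = fit_full, y = y),
            class = "pls1_cv")
}

#' @export
print.pls1_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %s): A* = %d, RMSE_cv = %.4g\n",
              x$k, format(x$seed), x$A_selected,
              x$rmse_cv_per_A[x$A_selected]))
  invisible(x)
}

#' First-local-minimum factor selection
#'
#' Returns the smallest factor count A with `rmse(A) < rmse(A + 1)`. If the
#' sequence is monotone decreasing the maximum candidate is returned with a
#' warning (no interior minimum found).
#'
#' @param rmse_cv_per_A numeric vector of cross-validated RMSE by factor
#'   count.
#' @param quiet suppress the monotone warning.
#' @return Integer factor count.
#' @export
select_n_factors <- function(rmse_cv_per_A, quiet = FALSE) {
  stopifnot(length(rmse_cv_per_A) >= 1L)
  A_max <- length(rmse_cv_per_A)
  if (A_max == 1L) return(1L)
  for (a in seq_len(A_max - 1L)) {
    if (rmse_cv_per_A[a] < rmse_cv_per_A[a + 1L]) return(a)
  }
  if (!quiet)
    warning("RMSE_cv monotone decreasing: returning A_max = ", A_max)
  A_max
}

#' Calibration / cross-validation model statistics
#'
#' Computes the conventional reporting statistics of a calibration model:
#' slope and offset of the least-squares regression of predicted on
#' measured values (calibration and cross-validation), `R2_cal = 1 -
#' SSres/SStot`, `R2_cv = 1 - PRESS/SStot`, root mean square errors, and
#' RMSE_cv as a percentage of the measured range.
#'
#' @param y measured values.
#' @param y_cal_hat calibration (fitted) predictions.
#' @param y_cv_hat cross-validated (held-out) predictions.
#' @return data.frame with one row: `offset_cal`, `offset_cv`, `slope_cal`,
#'   `slope_cv`, `r2_cal`, `r2_cv`, `rmse_cal`, `rmse_cv`,
#'   `rmse_cv_pct_range`.
#' @export
model_statistics <- function(y, y_cal_hat, y_cv_hat) {
  stopifnot(length(y) == length(y_cal_hat), length(y) == length(y_cv_hat))
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("response has zero variance")
  reg <- function(pred) {
    f <- stats::lm.fit(cbind(1, y), pred)
    c(offset = unname(f$coefficients[1L]), slope = unname(f$coefficients[2L]))
  }
  rc <- reg(y_cal_hat); rv <- reg(y_cv_hat)
  data.frame(
    offset_cal = rc["offset"], offset_cv = rv["offset"],
    slope_cal = rc["slope"], slope_cv = rv["slope"],
    r2_cal = 1 - sum((y - y_cal_hat)^2) / sstot,
    r2_cv = 1 - sum((y - y_cv_hat)^2) / sstot,
    rmse_cal = sqrt(mean((y - y_cal_hat)^2)),
    rmse_cv = sqrt(mean((y - y_cv_hat)^2)),
    rmse_cv_pct_range = 100 * sqrt(mean((y - y_cv_hat)^2)) /
      (max(y) - min(y)),
    row.names = NULL)
}

#' Influential-outlier screening
#'
#' Flags samples that strongly influence the model yet are poorly described
#' by it: leverage above `3 * (A + 1) / n` (leverage from the PLS score
#' space plus intercept) AND absolute studentized calibration residual above
#' 2.5. At most 5% of samples are flagged per pass (ranked by residual
#' magnitude), so screening can never silently discard the data.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param A factor count at which to assess influence.
#' @param leverage_factor multiplier of the mean leverage (default 3).
#' @param resid_threshold studentized residual cutoff (default 2.5).
#' @param max_frac maximum fraction flagged per pass (default 0.05).
#' @return Integer vector of flagged row indices (possibly empty), with the
#'   leverage/residual table in `attr(, "details")`.
#' @export
detect_influential_outliers <- function(X, y, A, leverage_factor = 3,
                                        resid_threshold = 2.5,
                                        max_frac = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  fit <- suppressWarnings(pls1(X, y, A))
  Tm <- fit$scores
  # leverage in the latent space (T columns orthogonal) plus intercept term
  h <- 1 / n + rowSums(sweep(Tm^2, 2L, colSums(Tm^2), "/"))
  res <- fit$residuals
  dfres <- max(n - fit$ncomp - 1L, 1L)
  s <- sqrt(sum(res^2) / dfres)
  stud <- res / (s * sqrt(pmax(1 - h, 1e-8)))
  flag <- which(h > leverage_factor * (fit$ncomp + 1) / n &
                  abs(stud) > resid_threshold)
  cap <- max(1L, floor(max_frac * n))
  if (length(flag) > cap)
    flag <- flag[order(-abs(stud[flag]))][seq_len(cap)]
  flag <- sort(flag)
  attr(flag, "details") <- data.frame(index = seq_len(n), leverage = h,
                                      studentized_residual = stud)
  flag
}
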