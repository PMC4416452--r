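#' PLS1 regression by NIPALS with autoscaling
#'
#' Fits a single-response partial least squares regression. Both predictors
#' and response are mean-centered and weighted by 1/SD (sample SD, divisor
#' n - 1); scaling parameters are model state, estimated on the fitting data
#' only and re-applied to any new data. Factors are extracted by NIPALS
#' deflation; for a single response the weight vector per factor is the
#' closed form `w = X'y / ||X'y||` (algebraically identical to the iterative
#' NIPALS inner loop), followed by `t = Xw`, `p_a = X't/(t't)`,
#' `q_a = y't/(t't)` and deflation `X <- X - t p_a'`, `y <- y - q_a t`. Each
#' factor maximizes the covariance between X- and Y-scores.
#'
#' Zero-variance predictor columns are dropped with a warning before
#' fitting; their reported coefficients are zero. Factors whose score
#' sum-of-squares falls below `1e-12` times the initial X sum-of-squares
#' are truncated with a warning (rank exhausted).
#'
#' @param X numeric matrix, n samples x p predictors (e.g. derivative
#'   reflectance at p wavelengths). Column names are kept as the variable
#'   axis.
#' @param y numeric response vector, length n (e.g. delta15N, permil).
#' @param ncomp number of latent factors A, `A <= min(n - 1, p)`.
#' @return An object of class `pls1`: list with `ncomp`, `x_mean`, `x_sd`,
#'   `y_mean`, `y_sd`, `weights` (p x A, unit-norm columns), `x_loadings`
#'   (p x A), `y_loadings` (length A), `scores` (n x A, orthogonal columns),
#'   `coef_scaled` (length p, on the autoscaled metric), `coef_raw` and
#'   `intercept` (raw metric), `ss_y_per_factor` (explained Y sum of squares
#'   per factor, scaled metric), `fitted_values`, `residuals`, `variables`.
#' @seealso [predict.pls1()], [vip()], [explained_variance()],
#'   [cross_validate()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = 0.1)
#' m <- pls1(X, y, ncomp = 3)
#' summary(m)
#' @export
pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  vars <- colnames(X)
  if (is.null(vars)) vars <- as.character(seq_len(ncol(X)))

  x_sd_all <- apply(X, 2L, stats::sd)
  keep <- x_sd_all > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance predictor column(s) dropped")
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (p < 1L) stop("no predictor with variance left")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1L, p))

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) stop("response has zero variance")

  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  ys <- (y - y_mean) / y_sd

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- ss <- numeric(ncomp)
  Xd <- Xs
  yd <- ys
  ss_x0 <- sum(Xs^2)
  A <- ncomp
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, ss_x0)) { A <- a - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12 * ss_x0) {
      warning("rank exhausted: truncating to ", a - 1L, " factor(s)")
      A <- a - 1L
      break
    }
    pa <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- t
    q[a] <- qa
    ss[a] <- qa^2 * tt              # Y sum of squares captured by factor a
    Xd <- Xd - tcrossprod(t, pa)
    yd <- yd - qa * t
  }
  if (A < 1L) stop("no usable factor: X'y is numerically zero")
  if (A < ncomp) {
    W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
    Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]; ss <- ss[seq_len(A)]
  }

  # b on the autoscaled metric: b = W (P'W)^{-1} q
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b_raw_kept <- b_scaled * y_sd / x_sd
  intercept <- y_mean - sum(b_raw_kept * x_mean)

  expand <- function(v) { out <- numeric(length(keep)); out[keep] <- v; out }
  coef_raw <- stats::setNames(expand(b_raw_kept), vars)
  coef_scaled <- stats::setNames(expand(b_scaled), vars)

  fitted <- drop(X %*% b_raw_kept) + intercept
  structure(list(
    ncomp = A, variables = vars, kept = keep,
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    ss_y_per_factor = ss, ss_y_total = sum(ys^2),
    coef_scaled = coef_scaled, coef_raw = coef_raw, intercept = intercept,
    fitted_values = fitted, residuals = y - fitted, y = y, n = n
  ), class = "pls1")
}

#' Predict from a fitted PLS1 model
#'
#' Applies the model's stored autoscaling to new predictors and returns
#' predictions on the raw response metric. Applied to the training matrix it
#' reproduces the calibration fitted values.
#'
#' @param object a [pls1] model.
#' @param newdata numeric matrix with the model's variable axis (matched by
#'   column name when both are named).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$variables, colnames(newdata))
    if (length(miss))
      stop("newdata lacks model variables: ",
           paste(utils::head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L))
    newdata <- newdata[, object$variables, drop = FALSE]
  } else if (ncol(newdata) != length(object$variables)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$variables))
  }
  drop(newdata %*% object$coef_raw) + object$intercept
}

#' @export
coef.pls1 <- function(object, scaled = FALSE, ...) {
  if (scaled) object$coef_scaled
  else c("(Intercept)" = object$intercept, object$coef_raw)
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted_values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 (NIPALS, autoscaled): %d factor(s), %d variable(s), n = %d\n",
              x$ncomp, sum(x$kept), x$n))
  ev <- explained_variance(x)
  cat(sprintf("Y variance explained (cal): %.1f%%\n",
              sum(ev$y_variance_pct)))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  ev <- explained_variance(object)
  res <- list(model = object, explained = ev,
              rmse_cal = sqrt(mean(object$residuals^2)),
              r2_cal = 1 - sum(object$residuals^2) /
                sum((object$y - mean(object$y))^2))
  class(res) <- "summary.pls1"
  res
}

#' @export
print.summary.pls1 <- function(x, ...) {
  print(x$model)
  cat(sprintf("RMSE_cal = %.4g, R2_cal = %.4f\n", x$rmse_cal, x$r2_cal))
  print(x$explained, digits = 3)
  invisible(x)
}

#' Per-factor explained variance
#'
#' Percentage of the (autoscaled) response and predictor variance captured
#' by each latent factor; cumulative values are nondecreasing and bounded
#' by 100%.
#'
#' @param model a [pls1] model.
#' @return data.frame with `factor`, `y_variance_pct`, `x_variance_pct` and
#'   the cumulative columns.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pls1"))
  ss_x <- colSums(model$x_loadings^2) * colSums(model$scores^2)
  n <- model$n
  ss_x_tot <- sum(model$kept) * (n - 1)     # autoscaled X total SS
  yv <- 100 * model$ss_y_per_factor / model$ss_y_total
  xv <- 100 * ss_x / ss_x_tot
  data.frame(factor = seq_len(model$ncomp),
             y_variance_pct = yv, y_cumulative_pct = cumsum(yv),
             x_variance_pct = xv, x_cumulative_pct = cumsum(xv))
}

#' Variable importance in projection (VIP)
#'
#' Weighted sum of squares of the PLS weights, weighted by the response
#' sum-of-squares each factor explains:
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )` with unit-norm
#' weight columns. The mean of the squared VIP scores over all p retained
#' variables is exactly 1, which is why 1 (and, more liberally, 0.8) is the
#' customary importance threshold.
#'
#' @param model a [pls1] model with at least one factor and explained Y
#'   sum-of-squares > 0.
#' @return Named numeric vector of VIP scores (dropped zero-variance
#'   variables get NA).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls1"))
  ss <- model$ss_y_per_factor
  if (sum(ss) <= 0) stop("no Y variance explained: VIP undefined")
  p <- sum(model$kept)
  w2 <- model$weights^2                       # columns already unit norm
  v <- sqrt(p * drop(w2 %*% ss) / sum(ss))
  out <- rep(NA_real_, length(model$kept))
  out[model$kept] <- v
  stats::setNames(out, model$variables)
}

#' Serialize / restore a PLS1 model as JSON
#'
#' Writes the variable axis, scaling parameters, weight and loading
#' matrices, regression coefficients and per-factor explained sums of
#' squares at full precision so the model reloads exactly.
#'
#' @param model a [pls1] model.
#' @param path JSON file path.
#' @return `pls1_save`: the path, invisibly. `pls1_load`: the model.
#' @export
pls1_save <- function(model, path) {
  stopifnot(inherits(model, "pls1"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname pls1_save
#' @export
pls1_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "x_loadings", "scores")) {
    m <- obj[[f]]
    # written column-major: simplification yields one row per model column
    if (!is.matrix(m)) m <- matrix(unlist(m), nrow = obj$ncomp, byrow = TRUE)
    obj[[f]] <- t(m)
  }
  obj$kept <- as.logical(obj$kept)
  for (f in c("coef_raw", "coef_scaled"))
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), obj$variables)
  class(obj) <- "pls1"
  obj
}

#' Measured-versus-predicted plot for a PLS1 model
#'
#' @param x a [pls1] model.
#' @param ... passed to [plot()].
#' @export
plot.pls1 <- function(x, ...) {
  graphics::plot(x$y, x$fitted_values,
                 xlab = "measured", ylab = "predicted (calibration)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(x$fitted_values ~ x$y), col = "grey40")
  invisible(x)
}
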