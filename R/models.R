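#' Fixed characteristic ratios for the maximum amplitude algorithm
#'
#' Componentwise arithmetic means of training-set characteristic ratios, as
#' used by the conventional fixed-ratio MAA estimator.
#'
#' @param training list of `ratio_pair`s (or a data frame / matrix with
#'   columns `sbpr`, `dbpr`).
#' @return a `ratio_pair` with the mean `sbpr` and `dbpr`.
#' @export
maa_fixed_ratios <- function(training) {
  if (is.data.frame(training) || is.matrix(training)) {
    s <- training[, "sbpr"]; d <- training[, "dbpr"]
  } else {
    if (!length(training)) stop("empty training set")
    s <- vapply(training, function(r) r$sbpr, numeric(1))
    d <- vapply(training, function(r) r$dbpr, numeric(1))
  }
  if (!length(s)) stop("empty training set")
  structure(list(sbpr = mean(s), dbpr = mean(d)), class = "ratio_pair")
}

#' Invert characteristic ratios on the envelope to pressures
#'
#' SBP is the cuff pressure above MAP at which the envelope falls to
#' `sbpr * MA`, taking the crossing nearest MAP on the high-pressure limb;
#' DBP likewise below MAP at `dbpr * MA`. Crossings are bracketed on a
#' 0.1 mmHg grid and refined by bisection to 0.001 mmHg. A ratio of 1
#' degenerates to the MAP itself.
#'
#' @param owe a fitted `owe`.
#' @param ratios a `ratio_pair` (components in (0, 1]); `dbpr = NA` skips
#'   the diastolic inversion.
#' @return list of class `bp_estimate` with `sbp`, `dbp`, `map` (mmHg),
#'   `ratios_used` and `method`.
#' @export
estimate_bp_from_ratios <- function(owe, ratios) {
  if (is.null(owe$spline)) stop("envelope must be fitted")
  cross <- function(r, side) {
    if (is.na(r)) return(NA_real_)
    if (r <= 0 || r > 1)
      stop("characteristic ratio must lie in (0, 1], got ", format(r))
    if (r == 1) return(owe$map)
    target <- r * owe$ma
    dom <- range(owe$knots$cp)
    g <- if (side == "high") seq(owe$map, dom[2], by = 0.1)
         else seq(owe$map, dom[1], by = -0.1)
    g <- unique(c(g, if (side == "high") dom[2] else dom[1]))
    v <- owe$spline(g) - target
    i <- which(v <= 0)[1L]
    if (is.na(i))
      stop("envelope does not reach the ", if (side == "high") "systolic"
           else "diastolic", " ratio level on the ",
           if (side == "high") "high" else "low", "-pressure limb ",
           "(truncated envelope)")
    if (i == 1L) return(g[1L])
    stats::uniroot(function(x) owe$spline(x) - target,
                   lower = min(g[i - 1L], g[i]),
                   upper = max(g[i - 1L], g[i]), tol = 1e-3)$root
  }
  structure(list(sbp = cross(ratios$sbpr, "high"),
                 dbp = cross(ratios$dbpr, "low"),
                 map = owe$map, ratios_used = ratios, method = "ratio"),
            class = "bp_estimate")
}

#' Fit a multiple linear regression ratio model
#'
#' Ordinary least squares via QR decomposition; on well-conditioned input
#' the coefficients equal the normal-equations solution
#' `(X'X)^{-1} X'y`. The design matrix must carry a leading column of ones
#' (the intercept).
#'
#' @param X numeric design matrix, first column all ones, remaining columns
#'   named features; rows >= columns.
#' @param y numeric targets (characteristic ratios).
#' @return object of class `bp_linear_model` with `kind = "mlr"`,
#'   `feature_names`, `weights`, `intercept` and `train_residual_sd`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) stop("fewer rows than columns in the design matrix")
  if (any(abs(X[, 1L] - 1) > 1e-12))
    stop("first design-matrix column must be the intercept (all ones)")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qr_x$pivot[(qr_x$rank + 1L):ncol(X)]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  nms <- colnames(X)[-1L]
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X) - 1L))
  structure(list(kind = "mlr", feature_names = nms,
                 weights = unname(beta[-1L]), intercept = unname(beta[1L]),
                 hyperparams = NULL,
                 train_residual_sd = stats::sd(y - fitted)),
            class = "bp_linear_model")
}

#' Fit a linear nu-support-vector regression ratio model
#'
#' Solves the nu-SVR convex program with a linear (identity) feature map,
#' through the LIBSVM solver in \pkg{e1071}. `nu` in (0, 1] bounds the
#' fraction of support vectors from below and the fraction of margin errors
#' from above. Features are standardized internally (mean 0, SD 1); the
#' returned primal weights and intercept are expressed on the original
#' feature scale, so [predict_linear()] applies them directly.
#'
#' @param X numeric feature matrix (no intercept column), columns named.
#' @param y numeric targets.
#' @param C positive regularization constant.
#' @param nu nu parameter in (0, 1].
#' @return object of class `bp_linear_model` with `kind = "nusvr"`,
#'   primal `weights`/`intercept` on the original scale, `hyperparams`
#'   (`C`, `nu`, `sv_fraction`) and `train_residual_sd`.
#' @export
fit_nusvr <- function(X, y, C = 2^14.49, nu = 2^-1.89) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training points")
  if (!(nu > 0 && nu <= 1)) stop("nu must lie in (0, 1], got ", format(nu))
  if (C <= 0) stop("C must be positive")
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  fit <- e1071::svm(x = Xs, y = y, scale = FALSE, type = "nu-regression",
                    kernel = "linear", cost = C, nu = nu)
  w_s <- drop(crossprod(fit$coefs, fit$SV))
  b_s <- -fit$rho
  w <- w_s / sdev
  b <- b_s - sum(w_s * mu / sdev)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  fitted <- b + drop(X %*% w)
  structure(list(kind = "nusvr", feature_names = nms,
                 weights = unname(w), intercept = unname(b),
                 hyperparams = list(C = C, nu = nu,
                                    sv_fraction = fit$tot.nSV / nrow(X)),
                 train_residual_sd = stats::sd(y - fitted)),
            class = "bp_linear_model")
}

#' Predict characteristic ratios from a linear model
#'
#' Intercept plus dot product per row. Columns are matched by name when both
#' the model and `X` carry names; otherwise by position.
#'
#' @param model a `bp_linear_model` from [fit_mlr()] or [fit_nusvr()].
#' @param X feature matrix or data frame (no intercept column).
#' @return numeric vector of predictions.
#' @export
predict_linear <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", input has ", ncol(X))
  if (!is.null(colnames(X)) && all(model$feature_names %in% colnames(X)))
    X <- X[, model$feature_names, drop = FALSE]
  model$intercept + drop(X %*% model$weights)
}

#' Clip predicted characteristic ratios to the invertible range
#'
#' Predictions are clipped to (0.05, 1]; each clipping event is reported via
#' `message()` and the count attached as attribute `n_clipped`.
#'
#' @param r numeric predicted ratios.
#' @param lo lower clip bound.
#' @return clipped ratios with attribute `n_clipped`.
#' @export
clip_ratios <- function(r, lo = 0.05) {
  n_clip <- sum(r <= lo | r > 1, na.rm = TRUE)
  if (n_clip > 0)
    message(n_clip, " predicted ratio(s) clipped to (", lo, ", 1]")
  out <- pmin(pmax(r, lo + 1e-9), 1)
  attr(out, "n_clipped") <- n_clip
  out
}

#' @export
print.bp_linear_model <- function(x, ...) {
  cat(sprintf("<bp_linear_model %s: %d feature(s): %s>\n", x$kind,
              length(x$weights), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.bp_estimate <- function(x, ...) {
  cat(sprintf("<bp_estimate: SBP %.1f / DBP %s mmHg, MAP %.1f mmHg (%s)>\n",
              x$sbp, ifelse(is.na(x$dbp), "NA", sprintf("%.1f", x$dbp)),
              x$map, x$method))
  invisible(x)
}
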