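#' Latent-variable chemometrics
#'
#' Autoscaling, PCA outlier screening, NIPALS partial least squares (PLS)
#' and its discriminant variant (PLS-DA), leave-one-out cross-validation,
#' permutation significance testing, and VIP variable ranking.
#'
#' @name chemometrics
NULL

#' Autoscale a data matrix
#'
#' Mean-centers every column and divides it by its standard deviation
#' (n - 1 denominator), the unit-variance autoscaling conventional in
#' chemometrics.  Constant columns are centered, given scale 1, and
#' flagged.
#'
#' @param x Numeric matrix (samples x variables), at least 2 rows.
#' @return List of class `scaled_matrix` with `values`, `col_means`,
#'   `col_scales`, `constant` (logical flag per column).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  constant <- sdv == 0
  scales <- ifelse(constant, 1, sdv)
  vals <- sweep(sweep(x, 2, mu, "-"), 2, scales, "/")
  structure(list(values = vals, col_means = mu, col_scales = scales,
                 constant = constant),
            class = "scaled_matrix")
}

#' Apply stored scaling constants to new samples
#'
#' @param scaled A `scaled_matrix` from [autoscale()].
#' @param newdata Matrix (or vector interpreted as one row) with the same
#'   columns as the training data.
#' @return Scaled matrix of the new samples.
#' @export
apply_scaling <- function(scaled, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(sweep(newdata, 2, scaled$col_means, "-"), 2, scaled$col_scales, "/")
}

#' Principal component analysis by SVD
#'
#' SVD of an already-scaled matrix; used to screen the data set for
#' outliers before latent-variable modeling.
#'
#' @param scaled A `scaled_matrix` or a plain centered matrix.
#' @param n_components Number of components to retain (default: full rank).
#' @return List with `scores`, `loadings`, `explained_variance` (per
#'   component), `explained_fraction`, and `t2` (Hotelling-type squared
#'   Mahalanobis distance of each sample in the retained score space).
#' @export
pca_svd <- function(scaled, n_components = NULL) {
  x <- if (inherits(scaled, "scaled_matrix")) scaled$values else as.matrix(scaled)
  sv <- svd(x)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  a <- min(n_components %||% rank, rank)
  n <- nrow(x)
  scores <- sv$u[, seq_len(a), drop = FALSE] %*%
    diag(sv$d[seq_len(a)], a, a)
  ev <- sv$d^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(a)], "/"))
  list(scores = scores,
       loadings = sv$v[, seq_len(a), drop = FALSE],
       explained_variance = ev,
       explained_fraction = ev / sum(ev),
       t2 = t2)
}

# core NIPALS loop on already-scaled/centered x and centered y;
# returns weights W, loadings P, scores T, y-loadings q
.nipals_pls <- function(x, y, n_components) {
  n <- nrow(x); v <- ncol(x)
  a_max <- min(n_components, n - 1, v)
  w_mat <- matrix(0, v, a_max); p_mat <- matrix(0, v, a_max)
  t_mat <- matrix(0, n, a_max); q_vec <- numeric(a_max); tt_vec <- numeric(a_max)
  a_used <- 0
  for (a in seq_len(a_max)) {
    w <- crossprod(x, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (a == 1) warning("response is orthogonal to all variables")
      else warning("stopping early at ", a - 1, " components")
      break
    }
    w <- w / nw
    tvec <- x %*% w
    tt <- sum(tvec^2)
    p <- crossprod(x, tvec) / tt
    q <- sum(y * tvec) / tt
    x <- x - tcrossprod(tvec, p)
    y <- y - q * tvec
    w_mat[, a] <- w; p_mat[, a] <- p; t_mat[, a] <- tvec
    q_vec[a] <- q; tt_vec[a] <- tt
    a_used <- a
  }
  keep <- seq_len(max(a_used, 0))
  list(weights = w_mat[, keep, drop = FALSE],
       loadings = p_mat[, keep, drop = FALSE],
       scores = t_mat[, keep, drop = FALSE],
       y_loadings = q_vec[keep], tt = tt_vec[keep],
       n_components = a_used)
}

# regression coefficients on the scaled X scale: B = W (P'W)^-1 q
.pls_coefficients <- function(fit) {
  if (fit$n_components == 0) return(numeric(nrow(fit$weights)))
  pw <- crossprod(fit$loadings, fit$weights)
  as.numeric(fit$weights %*% solve(pw, fit$y_loadings))
}

#' Fit a PLS regression model (NIPALS)
#'
#' Single-response NIPALS: for each component, the weight vector is
#' `X'y / ||X'y||`, scores are `X w`, loadings `X't / t't`, the y-loading
#' `y't / t't`, and both `X` and `y` are deflated.  Predictor columns are
#' autoscaled and the response centered internally; regression
#' coefficients are assembled for direct prediction of new samples.
#'
#' @param x Predictor matrix (samples x variables), raw scale.
#' @param y Numeric response.
#' @param n_components Number of latent variables (capped at
#'   `min(n - 1, variables)`).
#' @return Object of class `pls_model` with weights, loadings, scores,
#'   y-loadings, coefficients and the scaling constants.
#' @export
pls_fit <- function(x, y, n_components = 2) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (n_components > min(nrow(x) - 1, ncol(x))) {
    stop("n_components exceeds min(samples - 1, variables)")
  }
  sc <- autoscale(x)
  y_mean <- mean(y)
  fit <- .nipals_pls(sc$values, y - y_mean, n_components)
  fit$coefficients <- .pls_coefficients(fit)
  fit$scaling <- sc
  fit$y_mean <- y_mean
  fit$variable_names <- colnames(x)
  class(fit) <- "pls_model"
  fit
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix of raw-scale samples (or one sample as a vector).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  z <- apply_scaling(object$scaling, newdata)
  as.numeric(z %*% object$coefficients) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d variable(s)%s\n",
              x$n_components, nrow(x$weights),
              if (!is.null(x$classes)) " (discriminant)" else ""))
  invisible(x)
}

#' Fit a two-class PLS-DA model
#'
#' Dummy-codes the two classes as 0/1, centers, and fits a NIPALS PLS
#' model; classification of a sample calls the class whose coded value
#' lies on the same side of the midpoint between the two training-class
#' mean predictions.
#'
#' @param x Predictor matrix (samples x variables), raw scale.
#' @param labels Two-class factor/character vector.
#' @param n_components Number of latent variables.
#' @return A `pls_model` with additional elements `classes`, `midpoint`
#'   and `fitted_class`.
#' @export
plsda_fit <- function(x, labels, n_components = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("PLS-DA needs exactly 2 classes")
  y <- as.numeric(labels == classes[2])
  fit <- pls_fit(x, y, n_components)
  pred <- predict(fit, x)
  midpoint <- (mean(pred[y == 1]) + mean(pred[y == 0])) / 2
  fit$classes <- classes
  fit$midpoint <- midpoint
  fit$fitted_class <- ifelse(pred >= midpoint, classes[2], classes[1])
  fit$training_accuracy <- mean(fit$fitted_class == labels)
  fit
}

#' Classify new samples with a PLS-DA model
#'
#' @param model A `pls_model` from [plsda_fit()].
#' @param newdata Raw-scale sample matrix.
#' @return Character vector of predicted class labels.
#' @export
plsda_classify <- function(model, newdata) {
  if (is.null(model$classes)) stop("model is not a PLS-DA fit")
  pred <- predict(model, newdata)
  ifelse(pred >= model$midpoint, model$classes[2], model$classes[1])
}

# fast internal LOO for a numeric (possibly 0/1-coded) response; refits
# scaling + NIPALS on each fold.  Returns held-out predictions and, for
# classification, the per-fold decision midpoint (mean of the two
# training-class mean predictions).
.loo_predictions <- function(x, y, n_components, midpoints = FALSE) {
  n <- nrow(x)
  pred <- numeric(n)
  mid <- if (midpoints) numeric(n) else NULL
  col_sum <- colSums(x)
  col_sq <- colSums(x * x)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    nt <- n - 1
    mu <- (col_sum - x[i, ]) / nt
    vr <- (col_sq - x[i, ]^2 - nt * mu^2) / (nt - 1)
    sdv <- sqrt(pmax(vr, 0))
    sdv[sdv < 1e-300] <- 1
    xs <- (xt - rep(mu, each = nt)) / rep(sdv, each = nt)
    ym <- mean(yt)
    fit <- .nipals_pls(xs, yt - ym, n_components)
    beta <- .pls_coefficients(fit)
    z <- (x[i, ] - mu) / sdv
    pred[i] <- sum(z * beta) + ym
    if (midpoints) {
      pt <- as.numeric(xs %*% beta) + ym
      ones <- yt == 1
      if (all(ones)) {
        mid[i] <- -Inf   # fold lost class 0: call the remaining class
      } else if (!any(ones)) {
        mid[i] <- Inf    # fold lost class 1
      } else {
        mid[i] <- (mean(pt[ones]) + mean(pt[!ones])) / 2
      }
    }
  }
  list(pred = pred, mid = mid)
}

#' Leave-one-out cross-validation of a PLS / PLS-DA model
#'
#' For each sample, the scaling and the model are refit on the remaining
#' samples and the held-out sample is predicted.  The summary is the
#' fraction of correct classifications (classification mode, midpoint rule
#' computed per fold from the training predictions) or the cross-validated
#' `R^2 = 1 - PRESS / SS_tot` (regression mode).
#'
#' @param x Predictor matrix, raw scale.
#' @param y_or_labels Numeric response or two-class labels.
#' @param n_components Number of latent variables.
#' @param mode `"classification"` or `"regression"`.
#' @return List with `predictions` (per held-out sample), `summary`
#'   (accuracy or CV-R^2), and `mode`.
#' @export
loo_cv <- function(x, y_or_labels, n_components = 1,
                   mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  if (mode == "classification") {
    labels <- as.character(y_or_labels)
    classes <- sort(unique(labels))
    if (length(classes) != 2) stop("classification mode needs 2 classes")
    y <- as.numeric(labels == classes[2])
    if (min(table(y)) < 2) {
      warning("a fold may lose one class entirely; ",
              "such folds predict from the remaining class proportions")
    }
    res <- .loo_predictions(x, y, n_components, midpoints = TRUE)
    call <- ifelse(res$pred >= res$mid, classes[2], classes[1])
    list(predictions = res$pred, class = call,
         summary = mean(call == labels), mode = mode)
  } else {
    y <- as.numeric(y_or_labels)
    res <- .loo_predictions(x, y, n_components)
    press <- sum((y - res$pred)^2)
    ss <- sum((y - mean(y))^2)
    list(predictions = res$pred, summary = 1 - press / ss, mode = mode)
  }
}

#' Permutation test of a cross-validated PLS / PLS-DA summary
#'
#' The observed statistic is the leave-one-out summary (classification
#' accuracy or CV-R^2) on the true labels; the null distribution is the
#' same statistic on label-permuted data, rebuilt with the same number of
#' latent variables.  The empirical p-value uses the add-one smoothing
#' convention `p = (1 + #{perm >= obs}) / (1 + n_perm)`; the significance
#' flag reproduces the "observed exceeds 95% of permuted values" rule.
#'
#' @param x Predictor matrix, raw scale.
#' @param y_or_labels Response or class labels.
#' @param n_components Number of latent variables.
#' @param n_perm Number of permutations (default 1000, minimum 20).
#' @param seed RNG seed governing the permutation order.
#' @param mode `"classification"` or `"regression"`.
#' @return List of class `permutation_result` with `observed`, `permuted`,
#'   `p_value`, `significant`.
#' @export
permutation_test <- function(x, y_or_labels, n_components = 1,
                             n_perm = 1000, seed = 1,
                             mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  if (n_perm < 20) stop("n_perm must be at least 20 for usable resolution")
  x <- as.matrix(x)
  observed <- loo_cv(x, y_or_labels, n_components, mode)$summary
  y <- if (mode == "classification") as.character(y_or_labels)
       else as.numeric(y_or_labels)
  permuted <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      suppressWarnings(
        loo_cv(x, sample(y), n_components, mode)$summary
      )
    }, numeric(1))
  })
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  cutoff <- stats::quantile(permuted, 0.95, type = 1, names = FALSE)
  structure(
    list(observed = observed, permuted = permuted, p_value = p,
         significant = observed > cutoff, n_perm = n_perm, mode = mode),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %s = %.3f, p = %.4g (%d permutations)%s\n",
    if (x$mode == "classification") "accuracy" else "CV-R2",
    x$observed, x$p_value, x$n_perm,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Choose the number of PLS components by leave-one-out CV
#'
#' Evaluates the LOO summary (classification accuracy or CV-R^2) for
#' 1..`a_max` latent variables and returns the smallest count attaining
#' the maximum (ties go to the more parsimonious model).
#'
#' @param x Predictor matrix, raw scale.
#' @param y_or_labels Response or two-class labels.
#' @param mode `"classification"` or `"regression"`.
#' @param a_max Largest number of components to consider (default 5,
#'   capped at `min(n - 2, variables)`).
#' @return List with `n_components` and `summaries` (per candidate).
#' @export
select_n_components <- function(x, y_or_labels,
                                mode = c("classification", "regression"),
                                a_max = 5) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  a_max <- min(a_max, nrow(x) - 2, ncol(x))
  sums <- vapply(seq_len(a_max), function(a) {
    suppressWarnings(loo_cv(x, y_or_labels, a, mode)$summary)
  }, numeric(1))
  list(n_components = which.max(sums), summaries = sums)
}

#' Variable Importance in Projection (VIP) scores
#'
#' `VIP_j = sqrt(V * sum_a(w_aj^2 * SS_a) / sum_a(SS_a))` with unit-norm
#' weight vectors `w_a`, `SS_a = q_a^2 * t_a't_a` the y-variance captured
#' by component `a`, and `V` the number of variables, so that the squared
#' VIPs average to 1 over variables.
#'
#' @param model A fitted `pls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (model$n_components < 1) stop("model has no components")
  ss <- model$y_loadings^2 * model$tt
  total <- sum(ss)
  if (total <= 0) stop("zero explained y-variance; VIP undefined")
  v <- nrow(model$weights)
  vip <- sqrt(v * as.numeric(model$weights^2 %*% ss) / total)
  names(vip) <- model$variable_names
  vip
}

#' VIP ranking table for a two-group comparison
#'
#' VIP scores with the direction of each variable's group-mean difference
#' (positive: higher in the carbohydrate group), sorted by decreasing VIP.
#'
#' @param model A `pls_model` from [plsda_fit()].
#' @param x Raw-scale predictor matrix used for the fit.
#' @param group Group labels aligned with the rows of `x`.
#' @return Data frame `metabolite`, `vip`, `direction`.
#' @export
vip_table <- function(model, x, group) {
  vip <- vip_scores(model)
  x <- as.matrix(x)
  is_ch <- group == "carbohydrate"
  dir <- sign(colMeans(x[is_ch, , drop = FALSE]) -
                colMeans(x[!is_ch, , drop = FALSE]))
  out <- data.frame(metabolite = names(vip), vip = unname(vip),
                    direction = unname(dir[names(vip)]),
                    stringsAsFactors = FALSE)
  out[order(-out$vip), ]
}
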