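# The four classifier families the audit covers. None of the usual classifier
# packages are assumed: the forest is compiled in src/, the RBF-SVM solves the
# dual QP with quadprog, ridge logistic regression is fit by Newton's method,
# and Gaussian naive Bayes is closed-form. Every model exposes hard class
# predictions and a continuous score monotone in P(disease = 1), which is what
# the rank-based AUC consumes.

LEARNER_FAMILIES <- c("random_forest", "logistic_regression", "svm", "gaussian_nb")

#' Default hyperparameter tuning grids
#'
#' Small published-convention grids, 3-fold internal CV, refit per run:
#' forest trees \{100, 200\} x depth \{unbounded, 8\}; logistic inverse
#' regularisation C \{0.1, 1, 10\}; RBF-SVM cost \{0.1, 1, 10\}; naive Bayes
#' has nothing to tune.
#'
#' @param family learner family.
#' @return A list of candidate parameter lists (possibly of length 1).
#' @export
default_grid <- function(family) {
  family <- match.arg(family, LEARNER_FAMILIES)
  switch(family,
    random_forest = {
      g <- expand.grid(ntree = c(100, 200), max_depth = c(0, 8))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    logistic_regression = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    svm = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    gaussian_nb = list(list())
  )
}

default_params <- function(family) {
  switch(family,
    random_forest = list(ntree = 100, max_depth = 0, min_split = 2, mtry = NULL),
    logistic_regression = list(C = 1),
    svm = list(C = 1, gamma = NULL),
    gaussian_nb = list()
  )
}

feature_matrix <- function(cohort, features) {
  df <- as.data.frame(cohort)
  miss <- setdiff(features, names(df))
  if (length(miss)) stop("cohort lacks feature columns: ", paste(miss, collapse = ", "))
  as.matrix(df[, features, drop = FALSE])
}

#' Fit a classifier on a training cohort
#'
#' Fits one of the four families on the cohort's model features and disease
#' label. With `tune = TRUE`, hyperparameters are chosen by grid search with
#' `cv_folds`-fold cross-validation **on the training cohort only**,
#' maximising CV accuracy (ties keep the earliest grid point, so a one-point
#' grid is identical to tuning off).
#'
#' @param train a preprocessed training cohort (recoded, encoded, complete).
#' @param family `"random_forest"`, `"logistic_regression"`, `"svm"` or
#'   `"gaussian_nb"`.
#' @param features feature columns (default: all model features present).
#' @param tune run the grid search.
#' @param grid candidate parameter list (default [default_grid()]).
#' @param params fixed parameters overriding the family defaults (ignored for
#'   tuned parameters when `tune = TRUE`).
#' @param cv_folds internal CV folds (default 3).
#' @param seed RNG seed (forest growth and CV fold assignment).
#' @return A `liverfair_model`; see [predict.liverfair_model()].
#' @export
fit_learner <- function(train, family, features = NULL, tune = FALSE,
                        grid = NULL, params = list(), cv_folds = 3, seed = NULL) {
  family <- match.arg(family, LEARNER_FAMILIES)
  if (is.null(features)) features <- intersect(feature_names(), names(train))
  x <- feature_matrix(train, features)
  y <- as.integer(as.data.frame(train)$disease)
  if (length(unique(y)) < 2) stop("fit error: single-class training fold")
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(default_params(family), params)

  if (tune) {
    if (is.null(grid)) grid <- default_grid(family)
    if (length(grid) > 1) {
      folds <- sample(rep_len(seq_len(cv_folds), nrow(x)))
      acc <- vapply(grid, function(g) {
        pg <- utils::modifyList(p, g)
        mean(vapply(seq_len(cv_folds), function(k) {
          tr <- folds != k
          if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) return(NA_real_)
          fit <- fit_family(family, x[tr, , drop = FALSE], y[tr], pg)
          mean((predict_family(family, fit, x[!tr, , drop = FALSE]) >= 0.5) == (y[!tr] == 1))
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      p <- utils::modifyList(p, grid[[which.max(acc)]])
    } else if (length(grid) == 1) {
      p <- utils::modifyList(p, grid[[1]])
    }
  }

  fit <- fit_family(family, x, y, p)
  structure(list(family = family, features = features, fit = fit, params = p,
                 coefficients = fit$coefficients, importance = fit$importance,
                 score_type = if (family == "svm") "decision_function" else "probability"),
            class = c(paste0("liverfair_", family), "liverfair_model"))
}

fit_family <- function(family, x, y, p) {
  switch(family,
    random_forest = fit_rf(x, y, p),
    logistic_regression = fit_ridge_logistic(x, y, p$C),
    svm = fit_rbf_svm(x, y, p$C, p$gamma),
    gaussian_nb = fit_gnb(x, y)
  )
}

predict_family <- function(family, fit, x) {
  switch(family,
    random_forest = as.numeric(.rf_predict(fit$forest, x)),
    logistic_regression = {
      eta <- drop(cbind(1, x) %*% fit$beta)
      stats::plogis(eta)
    },
    svm = {
      d2 <- outer(rowSums(x^2), rowSums(fit$sv^2), "+") - 2 * x %*% t(fit$sv)
      drop(exp(-fit$gamma * pmax(d2, 0)) %*% fit$alpha_y + fit$b)
    },
    gaussian_nb = {
      ll <- vapply(1:2, function(cl) {
        mu <- fit$mu[cl, ]; s2 <- fit$s2[cl, ]
        rowSums(-0.5 * log(2 * pi * matrix(s2, nrow(x), ncol(x), byrow = TRUE)) -
                  0.5 * sweep(x, 2, mu)^2 / matrix(s2, nrow(x), ncol(x), byrow = TRUE)) +
          log(fit$prior[cl])
      }, numeric(nrow(x)))
      ll <- matrix(ll, ncol = 2)
      1 / (1 + exp(ll[, 1] - ll[, 2]))
    }
  )
}

fit_rf <- function(x, y, p) {
  mtry <- if (is.null(p$mtry)) max(1L, floor(sqrt(ncol(x)))) else p$mtry
  f <- .rf_fit(x, as.integer(y), as.integer(p$ntree), as.integer(mtry),
               as.integer(p$max_depth), as.integer(p$min_split))
  list(forest = f, importance = stats::setNames(as.numeric(f$importance), colnames(x)))
}

# Ridge-penalised logistic regression by Newton's method: minimises
# -loglik + ||w||^2 / (2C), intercept unpenalised. Strongly convex, so the
# fit is deterministic and immune to separation.
fit_ridge_logistic <- function(x, y, C) {
  z <- cbind(1, x)
  pen <- c(0, rep(1 / C, ncol(x)))
  beta <- rep(0, ncol(z))
  for (it in 1:100) {
    eta <- drop(z %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(z, mu - y)) + pen * beta
    if (max(abs(g)) < 1e-10) break
    w <- pmax(mu * (1 - mu), 1e-10)
    h <- crossprod(z * w, z) + diag(pen, length(pen))
    beta <- beta - solve(h, g)
  }
  list(beta = beta,
       coefficients = stats::setNames(beta[-1], colnames(x)))
}

# C-SVC with an RBF kernel, fit by solving the dual QP (quadprog). gamma
# defaults to the "scale" convention 1 / (p * var(x)). A small diagonal jitter
# keeps the kernel matrix positive definite for the solver.
fit_rbf_svm <- function(x, y, C, gamma = NULL) {
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(x)
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
  K <- exp(-gamma * pmax(d2, 0))
  D <- (ys %o% ys) * K
  diag(D) <- diag(D) + 1e-6
  sol <- quadprog::solve.QP(
    Dmat = D, dvec = rep(1, n),
    Amat = cbind(ys, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- which(alpha > 1e-8 * C)
  f0 <- drop(K[, sv, drop = FALSE] %*% (alpha[sv] * ys[sv]))
  margin <- sv[alpha[sv] < C * (1 - 1e-6)]
  b <- if (length(margin)) mean(ys[margin] - f0[margin]) else mean(ys[sv] - f0[sv])
  list(sv = x[sv, , drop = FALSE], alpha_y = alpha[sv] * ys[sv],
       b = b, gamma = gamma)
}

# Gaussian naive Bayes with sklearn-style variance smoothing.
fit_gnb <- function(x, y) {
  classes <- c(0, 1)
  mu <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                 numeric(ncol(x))))
  s2 <- t(vapply(classes, function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    colMeans(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(ncol(x))))
  eps <- 1e-9 * max(apply(x, 2, function(v) mean((v - mean(v))^2)), 1e-12)
  s2 <- s2 + eps
  list(mu = mu, s2 = s2, prior = c(mean(y == 0), mean(y == 1)))
}

#' Predict from a fitted audit classifier
#'
#' @param object a `liverfair_model` from [fit_learner()].
#' @param newdata a cohort (or a numeric matrix with the model's feature
#'   columns).
#' @param type `"class"` for hard 0/1 labels, `"score"` for the continuous
#'   score monotone in P(disease = 1) (predicted probability where native, the
#'   decision-function value for the SVM).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.liverfair_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata[, object$features, drop = FALSE] else
    feature_matrix(newdata, object$features)
  score <- predict_family(object$family, object$fit, x)
  if (type == "score") return(score)
  threshold <- if (object$score_type == "decision_function") 0 else 0.5
  as.integer(score >= threshold)
}
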