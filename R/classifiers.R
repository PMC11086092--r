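## The sixteen classifier presets: three decision trees, logistic
## regression, six SVMs and six KNN variants, each with the one tuned
## hyperparameter of the published suite plus the toolbox-default settings
## needed to make them concrete (Gaussian kernel scales sqrt(P)/4, sqrt(P),
## 4 sqrt(P) for P predictors; squared-inverse-distance KNN weights;
## cosine and Minkowski-3 KNN distances; Gini trees; a 1e-8 ridge to keep
## logistic regression defined under separation).
CLASSIFIER_PRESETS <- list(
  list(name = "Fine Tree",      family = "tree", maxSplits = 4L),
  list(name = "Medium Tree",    family = "tree", maxSplits = 20L),
  list(name = "Coarse Tree",    family = "tree", maxSplits = 100L),
  list(name = "Logistic Regression", family = "logistic", ridge = 1e-8),
  list(name = "Linear SVM",     family = "svm", kernel = "linear",
       cost = 3),
  list(name = "Quadratic SVM",  family = "svm", kernel = "polynomial",
       degree = 2L, cost = 3),
  list(name = "Cubic SVM",      family = "svm", kernel = "polynomial",
       degree = 3L, cost = 4),
  list(name = "Fine Gaussian SVM",   family = "svm", kernel = "radial",
       cost = 3, scaleFactor = 0.25),
  list(name = "Medium Gaussian SVM", family = "svm", kernel = "radial",
       cost = 3, scaleFactor = 1),
  list(name = "Coarse Gaussian SVM", family = "svm", kernel = "radial",
       cost = 1, scaleFactor = 4),
  list(name = "Fine KNN",     family = "knn", k = 1L,   distance = "euclidean",
       weighted = FALSE),
  list(name = "Medium KNN",   family = "knn", k = 10L,  distance = "euclidean",
       weighted = FALSE),
  list(name = "Coarse KNN",   family = "knn", k = 100L, distance = "euclidean",
       weighted = FALSE),
  list(name = "Cosine KNN",   family = "knn", k = 10L,  distance = "cosine",
       weighted = FALSE),
  list(name = "Cubic KNN",    family = "knn", k = 10L,  distance = "minkowski3",
       weighted = FALSE),
  list(name = "Weighted KNN", family = "knn", k = 10L,  distance = "euclidean",
       weighted = TRUE))

#' The sixteen classifier presets
#'
#' @param names optional subset of preset names.
#' @return named list of classifier specifications.
#' @seealso [buildClassifier()], [loocv()]
#' @export
#' @examples
#' names(classifierSpecs())
classifierSpecs <- function(names = NULL) {
  specs <- setNames(CLASSIFIER_PRESETS,
                    vapply(CLASSIFIER_PRESETS, `[[`, "", "name"))
  if (is.null(names)) return(specs)
  miss <- setdiff(names, base::names(specs))
  if (length(miss)) stop("unknown classifier preset(s): ",
                         paste(miss, collapse = ", "))
  specs[names]
}

#' One classifier preset by name
#'
#' @param name preset name, e.g. `"Cosine KNN"`.
#' @return classifier specification list.
#' @export
classifierSpec <- function(name) classifierSpecs(name)[[1L]]

#' Build a deterministic train/predict factory from a preset
#'
#' Returns `function(X, y)` fitting the preset on a numeric matrix `X`
#' (rows = subjects) and factor `y` (two levels), and returning an object
#' whose `$predict(newX)` yields factor labels. No preset involves
#' stochastic initialization, so fits are deterministic given the data.
#' Prediction ties (KNN votes, logistic at exactly 0.5) break toward the
#' first factor level.
#'
#' @param spec a [classifierSpec()].
#' @return training function.
#' @export
buildClassifier <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$family))
  switch(spec$family,
    tree = function(X, y) fit_tree(X, y, spec),
    logistic = function(X, y) fit_logistic(X, y, spec),
    svm = function(X, y) fit_svm(X, y, spec),
    knn = function(X, y) fit_knn(X, y, spec),
    stop("unknown classifier family: ", spec$family))
}

## fall-back used by every family when the training fold is single-class
single_class_model <- function(lev, only) {
  list(predict = function(newX)
    factor(rep(only, nrow(newX)), levels = lev))
}

fit_tree <- function(X, y, spec) {
  lev <- levels(y)
  if (length(unique(y)) < 2L) return(single_class_model(lev, unique(y)))
  df <- data.frame(y = y, X)
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2L, minbucket = 1L, cp = 0,
                        maxdepth = 30L, xval = 0L,
                        maxsurrogate = 0L, maxcompete = 0L))
  cpt <- fit$cptable
  ok <- which(cpt[, "nsplit"] <= spec$maxSplits)
  if (length(ok) && max(cpt[, "nsplit"]) > spec$maxSplits)
    fit <- rpart::prune(fit, cp = cpt[max(ok), "CP"])
  list(predict = function(newX) {
    p <- predict(fit, newdata = data.frame(newX), type = "class")
    factor(as.character(p), levels = lev)
  })
}

fit_logistic <- function(X, y, spec) {
  lev <- levels(y)
  if (length(unique(y)) < 2L) return(single_class_model(lev, unique(y)))
  X1 <- cbind(1, X)
  yy <- as.numeric(y == lev[2L])
  beta <- numeric(ncol(X1))
  lambda <- spec$ridge
  for (it in seq_len(50L)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (yy - p) / w
    A <- crossprod(X1 * w, X1) + diag(lambda, ncol(X1))
    newbeta <- solve(A, crossprod(X1 * w, z))
    if (max(abs(newbeta - beta)) < 1e-10) { beta <- newbeta; break }
    beta <- newbeta
  }
  list(predict = function(newX) {
    p <- 1 / (1 + exp(-drop(cbind(1, newX) %*% beta)))
    factor(lev[ifelse(p > 0.5, 2L, 1L)], levels = lev)
  })
}

fit_svm <- function(X, y, spec) {
  lev <- levels(y)
  if (length(unique(y)) < 2L) return(single_class_model(lev, unique(y)))
  P <- ncol(X)
  args <- list(x = X, y = y, type = "C-classification", scale = FALSE,
               cost = spec$cost, kernel = spec$kernel)
  if (spec$kernel == "polynomial") {
    args$degree <- spec$degree; args$gamma <- 1; args$coef0 <- 1
  } else if (spec$kernel == "radial") {
    s <- spec$scaleFactor * sqrt(P)     # kernel scale preset
    args$gamma <- 1 / s^2               # exp(-||u - v||^2 / s^2)
  }
  fit <- do.call(e1071::svm, args)
  list(predict = function(newX)
    factor(as.character(predict(fit, newX)), levels = lev))
}

fit_knn <- function(X, y, spec) {
  lev <- levels(y)
  k <- min(spec$k, nrow(X))
  list(predict = function(newX) {
    out <- character(nrow(newX))
    for (i in seq_len(nrow(newX))) {
      d <- knn_dist(X, newX[i, ], spec$distance)
      nb <- order(d)[seq_len(k)]
      dn <- d[nb]
      if (spec$weighted) {
        if (any(dn == 0)) { w <- as.numeric(dn == 0) } else w <- 1 / dn^2
      } else w <- rep(1, length(nb))
      votes <- vapply(lev, function(cl) sum(w[y[nb] == cl]), numeric(1))
      out[i] <- lev[which.max(votes)]  # which.max ties -> first level
    }
    factor(out, levels = lev)
  })
}

knn_dist <- function(X, v, distance) {
  switch(distance,
    euclidean = sqrt(colSums((t(X) - v)^2)),
    minkowski3 = colSums(abs(t(X) - v)^3)^(1 / 3),
    cosine = {
      nx <- sqrt(rowSums(X^2))
      nv <- sqrt(sum(v^2))
      ifelse(nx * nv == 0, 1, 1 - drop(X %*% v) / (nx * nv))
    },
    stop("unknown KNN distance: ", distance))
}

#' Leave-one-out cross-validated accuracy
#'
#' Fits the preset n times, each time leaving one subject out, and returns
#' the fraction of held-out subjects classified correctly. Deterministic
#' given the inputs and invariant to subject order.
#'
#' @param X numeric matrix, subjects x features.
#' @param y two-level factor (or vector coercible to one).
#' @param spec a [classifierSpec()].
#' @return accuracy in `[0, 1]`.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' loocv(X, rep(c("a", "b"), each = 10), classifierSpec("Linear SVM"))
loocv <- function(X, y, spec) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("LOOCV needs both classes present")
  if (nlevels(y) > 2L) stop("binary classification only")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects")
  trainer <- buildClassifier(spec)
  correct <- 0L
  for (i in seq_len(n)) {
    model <- trainer(X[-i, , drop = FALSE], droplevels(y[-i]))
    pred <- model$predict(X[i, , drop = FALSE])
    correct <- correct + as.integer(as.character(pred) == as.character(y[i]))
  }
  correct / n
}
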