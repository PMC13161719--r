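# Classifier wrappers used by the REFS ensemble and the validation module.
#
# Every learner is a list of closures over a common contract:
#   fit(X, y)        X: numeric matrix with colnames, y: two-level factor
#                    (positive class = LAST level); returns a model object.
#   predict(m, X)    class labels (factor levels of y).
#   score(m, X)      numeric score, larger = more positive-class.
#   importance(m)    non-negative vector named by feature (may be missing
#                    for validation-only learners).
#
# glmnet needs >= 2 columns, so single-feature inputs are padded with a
# constant column that is stripped from importances again.

pad2 <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, ".pad" = rep(0, nrow(X)))
}

named_importance <- function(raw, features) {
  v <- stats::setNames(numeric(length(features)), features)
  raw <- raw[names(raw) %in% features]
  v[names(raw)] <- pmax(as.numeric(raw), 0)
  v
}

# Least-squares ridge classifier: regression of +/-1 class indicators with
# an L2 penalty, solved exactly through the thin SVD of the centred design
# (cheap at n << p). Predicted class = sign of the fitted value.
ridge_ls_learner <- function(lambda = 1) {
  list(
    fit = function(X, y) {
      yy <- ifelse(y == levels(y)[2], 1, -1)
      xm <- colMeans(X)
      Xc <- sweep(X, 2, xm)
      sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
      d <- sv$d
      w <- sv$v %*% ((d / (d^2 + lambda)) * crossprod(sv$u, yy))
      list(w = drop(w), b = mean(yy) - sum(xm * w), levels = levels(y),
           features = colnames(X))
    },
    predict = function(m, X) {
      s <- drop(X %*% m$w) + m$b
      factor(m$levels[(s > 0) + 1], levels = m$levels)
    },
    score = function(m, X) drop(X %*% m$w) + m$b,
    importance = function(m)
      named_importance(stats::setNames(abs(m$w), m$features), m$features))
}

glmnet_learner <- function(alpha, lambda = 0.01) {
  list(
    fit = function(X, y) {
      m <- glmnet::glmnet(pad2(X), y, family = "binomial", alpha = alpha,
                          lambda = lambda)
      attr(m, "features") <- colnames(X)
      m
    },
    predict = function(m, X)
      factor(drop(predict(m, pad2(X), type = "class")),
             levels = m$classnames),
    score = function(m, X) drop(predict(m, pad2(X), type = "link")),
    importance = function(m) {
      co <- abs(as.matrix(stats::coef(m))[-1, 1])
      named_importance(co, attr(m, "features"))
    })
}

svm_linear_learner <- function(cost = 1) {
  list(
    fit = function(X, y) e1071::svm(X, y, kernel = "linear", cost = cost,
                                    scale = FALSE),
    predict = function(m, X) predict(m, X),
    score = function(m, X) {
      dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
      # positive decision value favours the class named FIRST in the column
      # label "a/b"; the positive class is the last factor level
      d <- drop(dv)
      if (startsWith(colnames(dv)[1], paste0(m$levels[2], "/"))) d else -d
    },
    importance = function(m) {
      w <- drop(crossprod(m$coefs, m$SV))
      named_importance(abs(w), colnames(m$SV))
    })
}

ranger_learner <- function(extratrees = FALSE, num.trees = 100,
                           probability = FALSE) {
  args <- list(num.trees = num.trees, importance = "impurity",
               num.threads = 1, probability = probability)
  if (extratrees) {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1
  }
  list(
    fit = function(X, y) {
      m <- do.call(ranger::ranger,
                   c(list(x = X, y = y, seed = sample.int(1e6, 1)), args))
      attr(m, "levels") <- levels(y)
      m
    },
    predict = function(m, X) {
      pr <- predict(m, data = X, num.threads = 1)$predictions
      if (is.matrix(pr))
        factor(attr(m, "levels")[max.col(pr, ties.method = "first")],
               levels = attr(m, "levels"))
      else pr
    },
    score = function(m, X) {
      pr <- predict(m, data = X, num.threads = 1)$predictions
      if (is.matrix(pr)) pr[, attr(m, "levels")[2]]
      else as.numeric(pr == attr(m, "levels")[2])
    },
    importance = function(m)
      named_importance(ranger::importance(m), m$forest$independent.variable.names))
}

xgb_learner <- function(booster = "gbtree", nrounds = 30) {
  params <- if (booster == "gbtree")
    list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
         tree_method = "hist", nthread = 1)
  else
    list(objective = "binary:logistic", booster = "gblinear", nthread = 1)
  list(
    fit = function(X, y) {
      m <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X, label = as.numeric(y == levels(y)[2])),
        nrounds = nrounds, verbose = 0)
      attr(m, "levels") <- levels(y)
      attr(m, "features") <- colnames(X)
      m
    },
    predict = function(m, X) {
      pr <- predict(m, xgboost::xgb.DMatrix(X))
      factor(attr(m, "levels")[(pr > 0.5) + 1], levels = attr(m, "levels"))
    },
    score = function(m, X) predict(m, xgboost::xgb.DMatrix(X)),
    importance = function(m) {
      imp <- tryCatch(xgboost::xgb.importance(model = m),
                      error = function(e) NULL)
      if (is.null(imp) || nrow(imp) == 0)
        return(stats::setNames(numeric(length(attr(m, "features"))),
                               attr(m, "features")))
      col <- if ("Gain" %in% names(imp)) "Gain" else "Weight"
      named_importance(stats::setNames(abs(imp[[col]]), imp$Feature),
                       attr(m, "features"))
    })
}

rpart_learner <- function() {
  ctl <- rpart::rpart.control(xval = 0, maxcompete = 0, maxsurrogate = 0)
  list(
    fit = function(X, y) {
      d <- data.frame(X, check.names = FALSE)
      d$.y <- y
      m <- rpart::rpart(.y ~ ., data = d, method = "class", control = ctl)
      attr(m, "features") <- colnames(X)
      attr(m, "levels") <- levels(y)
      m
    },
    predict = function(m, X)
      predict(m, data.frame(X, check.names = FALSE), type = "class"),
    score = function(m, X)
      predict(m, data.frame(X, check.names = FALSE),
              type = "prob")[, attr(m, "levels")[2]],
    importance = function(m)
      named_importance(m$variable.importance, attr(m, "features")))
}

nnet_learner <- function(size = 8, decay = 0.01, maxit = 200) {
  list(
    fit = function(X, y) {
      m <- nnet::nnet(X, as.numeric(y == levels(y)[2]), size = size,
                      decay = decay, maxit = maxit, entropy = TRUE,
                      trace = FALSE)
      attr(m, "levels") <- levels(y)
      m
    },
    predict = function(m, X) {
      pr <- drop(predict(m, X))
      factor(attr(m, "levels")[(pr > 0.5) + 1], levels = attr(m, "levels"))
    },
    score = function(m, X) drop(predict(m, X)))
}

adaboost_learner <- function(n_rounds = 50) {
  list(
    fit = function(X, y) {
      m <- fit_ada_stumps(X, as.numeric(y == levels(y)[2]), n_rounds = n_rounds)
      attr(m, "levels") <- levels(y)
      m
    },
    predict = function(m, X) {
      s <- predict_ada_stumps(m, X)
      factor(attr(m, "levels")[(s > 0) + 1], levels = attr(m, "levels"))
    },
    score = function(m, X) predict_ada_stumps(m, X))
}

#' Default REFS base-classifier ensemble
#'
#' Eight heterogeneous classifiers, all exposing either coefficients or
#' impurity importances: a least-squares ridge classifier, lasso and
#' elastic-net penalised logistic regression, a linear support-vector
#' machine, a boosted linear model, a random forest, extremely randomised
#' trees and gradient-boosted trees.
#'
#' @return Named list of learner definitions.
#' @export
default_refs_ensemble <- function() {
  list(
    ridge_classifier = ridge_ls_learner(),
    lasso_logistic = glmnet_learner(alpha = 1),
    elastic_net = glmnet_learner(alpha = 0.5),
    linear_svm = svm_linear_learner(),
    sgd_linear = xgb_learner(booster = "gblinear"),
    random_forest = ranger_learner(extratrees = FALSE),
    extra_trees = ranger_learner(extratrees = TRUE, num.trees = 64),
    gradient_boosting = xgb_learner(booster = "gbtree", nrounds = 20))
}

#' Default five-classifier validation module
#'
#' Multilayer perceptron, AdaBoost over decision stumps, extremely
#' randomised trees, ridge-penalised logistic regression and a random
#' forest; each scores held-out samples with a positive-class probability
#' (or margin) for AUC-ROC computation.
#'
#' @return Named list of learner definitions.
#' @export
default_validation_classifiers <- function() {
  list(
    mlp = nnet_learner(),
    adaboost = adaboost_learner(),
    extra_trees = ranger_learner(extratrees = TRUE, probability = TRUE),
    logistic_regression = glmnet_learner(alpha = 0, lambda = 0.001),
    random_forest = ranger_learner(extratrees = FALSE, probability = TRUE))
}
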