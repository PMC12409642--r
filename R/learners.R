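# Base learner factories: the five classifier families used by the
# confounder screen and the soft-voting ensemble.

LEARNER_FAMILIES <- c("rf", "svm", "mlp", "logr", "gnb")

#' Create a base-learner factory
#'
#' Returns a fit/predict pair for one of the five classifier families:
#' random forest (\code{"rf"}, ranger), support vector machine with RBF
#' kernel (\code{"svm"}, e1071; class probabilities via Platt scaling of the
#' decision values, fitted on the training data), single-hidden-layer
#' multi-layer perceptron (\code{"mlp"}, nnet), logistic regression
#' (\code{"logr"}, IRLS via \code{stats::glm.fit}) and Gaussian naive Bayes
#' (\code{"gnb"}, e1071). All learners expose \code{fit(X, y)} on a numeric
#' matrix with \code{y} in \{0, 1\} and \code{predict_proba(model, X)}
#' returning class-1 probabilities in [0, 1]. Hyperparameters are ecosystem
#' defaults apart from a fixed modest MLP size; learners that use random
#' initialisation draw their seeds from the R random stream, so fits are
#' reproducible under \code{set.seed}.
#'
#' @param family one of \code{"rf"}, \code{"svm"}, \code{"mlp"},
#'   \code{"logr"}, \code{"gnb"}.
#' @return an object of class \code{learner_spec} with elements
#'   \code{family}, \code{fit} and \code{predict_proba}.
#' @export
make_learner <- function(family) {
  if (!family %in% LEARNER_FAMILIES)
    stop("unknown learner family '", family, "'; expected one of: ",
         paste(LEARNER_FAMILIES, collapse = ", "), call. = FALSE)
  spec <- switch(family,
    rf = list(
      fit = function(X, y) {
        ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 300,
                       num.threads = 1,
                       seed = sample.int(.Machine$integer.max, 1))
      },
      predict_proba = function(model, X) {
        unname(stats::predict(model, data = as.data.frame(X),
                              num.threads = 1)$predictions[, "1"])
      }),
    svm = list(
      fit = function(X, y) {
        fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                          kernel = "radial", scale = FALSE)
        dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                              "decision.values"))
        # the Platt fit learns the decision-value orientation via its slope
        platt <- suppressWarnings(
          stats::glm.fit(cbind(1, dv), y,
                         family = stats::binomial())$coefficients)
        list(svm = fit, platt = platt)
      },
      predict_proba = function(model, X) {
        dv <- as.numeric(attr(stats::predict(model$svm, X,
                                             decision.values = TRUE),
                              "decision.values"))
        unname(stats::plogis(model$platt[1] + model$platt[2] * dv))
      }),
    mlp = list(
      fit = function(X, y) {
        nnet::nnet(x = X, y = y, size = 5, decay = 0.1, maxit = 200,
                   entropy = TRUE, trace = FALSE)
      },
      predict_proba = function(model, X) {
        as.numeric(stats::predict(model, X))
      }),
    logr = list(
      fit = function(X, y) {
        cf <- suppressWarnings(
          stats::glm.fit(cbind(1, X), y,
                         family = stats::binomial())$coefficients)
        cf[is.na(cf)] <- 0
        cf
      },
      predict_proba = function(model, X) {
        unname(stats::plogis(drop(cbind(1, X) %*% model)))
      }),
    gnb = list(
      fit = function(X, y) {
        e1071::naiveBayes(x = as.data.frame(X),
                          y = factor(y, levels = c(0, 1)))
      },
      predict_proba = function(model, X) {
        p <- stats::predict(model, newdata = as.data.frame(X), type = "raw")
        unname(p[, "1"])
      })
  )
  structure(list(family = family, fit = spec$fit,
                 predict_proba = spec$predict_proba),
            class = "learner_spec")
}

#' The default five-learner panel
#'
#' @return list of \code{\link{make_learner}} specs for random forest, SVM,
#'   MLP, logistic regression and Gaussian naive Bayes.
#' @export
default_learners <- function() {
  lapply(LEARNER_FAMILIES, make_learner)
}

# training-set standardisation: returns centred/scaled matrix and params
.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}

.standardize_apply <- function(X, std) {
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}
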