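# Binary logistic-regression classifier over person-time samples.

#' Fit an unregularized binary logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`stats::glm`, binomial logit; convergence tolerance 1e-8, at most 100
#' iterations), with the case group as the positive class. The design is
#' checked for rank deficiency, and for *perfect separation*: a feature
#' one of whose group ranges lies strictly beyond the other group's range
#' splits the classes exactly, the likelihood has no maximum, and the fit
#' is refused with an error naming the offending feature(s) (or, with
#' `on_separation = "warn"`, recorded as a non-converged saturated fit so
#' that batch pipelines can continue).
#'
#' @param samples sample table with `group` (`"case"`/`"control"`) and the
#'   feature columns.
#' @param features predictor columns, at least one.
#' @param on_separation `"error"` (default) or `"warn"`.
#' @return object of class `night_logit`: `coefficients` (intercept
#'   first), `features`, `converged`, `fitted` (probabilities of case),
#'   `y` (observed class), `n`.
#' @export
fit_logistic <- function(samples, features, on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  if (length(features) < 1) stop("need at least one feature")
  stopifnot(all(features %in% names(samples)))
  y <- as.integer(samples$group == "case")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(samples[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in features")

  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("rank-deficient design matrix (collinear or constant features)")
  }

  sep <- features[vapply(features, function(f) {
    x0 <- X[y == 0, f]
    x1 <- X[y == 1, f]
    (min(x1) > max(x0)) || (min(x0) > max(x1))
  }, logical(1))]
  if (length(sep)) {
    msg <- paste0("perfect separation; non-convergent likelihood for feature(s): ",
                  paste(sep, collapse = ", "))
    if (on_separation == "error") stop(msg) else warning(msg)
  }

  dat <- data.frame(.y = y, X, check.names = FALSE)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
      # IRLS hitting maxit is reported through the 'converged' flag
      if (grepl("algorithm did not converge", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(coefficients = stats::coef(fit),
         features = features,
         converged = fit$converged && length(sep) == 0,
         quasi_separated = sep_warned,
         fitted = as.numeric(stats::fitted(fit)),
         y = y, n = length(y)),
    class = "night_logit"
  )
}

#' Predicted case probabilities from a fitted classifier
#'
#' @param object a `night_logit`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric probabilities in (0, 1).
#' @export
predict.night_logit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  eta <- drop(cbind(1, X) %*% object$coefficients)
  stats::plogis(eta)
}
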