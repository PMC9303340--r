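#' Three-class cell-size classification
#'
#' Cell size is discretized as small (L <= 28 um), medium (28 < L <= 42) or
#' large (L > 42), and classified from (D, K) by multinomial logistic
#' regression on the same 10-monomial basis as PolyMap. Chance-level accuracy
#' intervals come from retraining on permuted training labels (validation
#' labels intact).
#'
#' @name classify
NULL

#' Discretize cell size
#'
#' @param L Cell size(s) in um (> 0).
#' @return Factor with levels `small`, `medium`, `large` (boundaries
#'   inclusive on the left class: 28 is small, 42 is medium).
#' @export
discretize_size <- function(L) {
  if (any(L <= 0)) stop("L must be positive")
  cut(L, breaks = c(0, 28, 42, Inf),
      labels = c("small", "medium", "large"), right = TRUE)
}

#' Fit the multinomial cell-size classifier
#'
#' Maximum-likelihood multinomial logit on [design_matrix()] features. On
#' apparent separation (runaway coefficients) the fit is repeated with a tiny
#' ridge penalty.
#'
#' @param D,K Training cumulants.
#' @param label Training classes (factor from [discretize_size()]).
#' @param context Optional context descriptor stored on the model.
#' @return A `sizeclass_model`.
#' @export
fit_classifier <- function(D, K, label, context = NULL) {
  label <- factor(label, levels = c("small", "medium", "large"))
  if (nlevels(droplevels(label)) < 3)
    stop("fit_classifier: all three classes must be present in training data")
  X <- design_matrix(D, K)[, -1, drop = FALSE]  # multinom adds its intercept
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(label = label, X)
  fit <- nnet::multinom(label ~ ., data = dat, trace = FALSE, maxit = 600,
                        decay = 0, MaxNWts = 5000, reltol = 1e-12)
  if (max(abs(coef(fit))) > 1e3) {
    warning("fit_classifier: separation suspected; refitting with ridge 1e-6")
    fit <- nnet::multinom(label ~ ., data = dat, trace = FALSE, maxit = 600,
                          decay = 1e-6, MaxNWts = 5000, reltol = 1e-12)
  }
  structure(list(fit = fit, levels = levels(label), context = context),
            class = "sizeclass_model")
}

#' Predict cell-size classes
#'
#' @param object A `sizeclass_model`.
#' @param D,K Cumulants.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.sizeclass_model <- function(object, D, K, ...) {
  X <- design_matrix(D, K)[, -1, drop = FALSE]
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- predict(object$fit, newdata = data.frame(X))
  factor(p, levels = object$levels)
}

#' Classification accuracy with per-class recalls
#'
#' @param model A `sizeclass_model`.
#' @param D,K Validation cumulants.
#' @param label True classes.
#' @return List with `accuracy`, `per_class` (recall per class, NA when a
#'   class is absent from the validation set) and the `confusion` table.
#' @export
classify_accuracy <- function(model, D, K, label) {
  label <- factor(label, levels = model$levels)
  pred <- predict(model, D, K)
  acc <- mean(pred == label)
  per <- vapply(model$levels, function(cl) {
    idx <- label == cl
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == cl)
  }, numeric(1))
  list(accuracy = acc, per_class = per,
       confusion = table(truth = label, predicted = pred))
}

#' Permutation interval for chance-level accuracy
#'
#' Training labels are randomly permuted `n_perm` times; for each permutation
#' the classifier is retrained and its validation accuracy recorded. Returns
#' the central 95% interval (2.5 and 97.5 percentiles) of those accuracies.
#'
#' @param D_train,K_train,label_train Training data.
#' @param D_val,K_val,label_val Validation data (labels intact).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `lo`, `hi` and the vector of permuted `accuracies`.
#' @export
permutation_interval <- function(D_train, K_train, label_train,
                                 D_val, K_val, label_val,
                                 n_perm = 1000L, seed = 1L) {
  label_train <- factor(label_train, levels = c("small", "medium", "large"))
  label_val <- factor(label_val, levels = c("small", "medium", "large"))
  accs <- vapply(seq_len(n_perm), function(p) {
    perm <- with_seed(derive_seed(seed, p), sample(label_train))
    m <- tryCatch(fit_classifier(D_train, K_train, perm),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    mean(predict(m, D_val, K_val) == label_val)
  }, numeric(1))
  accs <- accs[!is.na(accs)]
  if (length(accs) == 1) return(list(lo = accs, hi = accs, accuracies = accs))
  list(lo = quantile(accs, 0.025, names = FALSE),
       hi = quantile(accs, 0.975, names = FALSE),
       accuracies = accs)
}
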