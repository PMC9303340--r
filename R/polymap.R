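#' PolyMap: polynomial mapping from (D, K) to microstructure
#'
#' Degree-3 bivariate polynomial regression
#' m = a0 + a1 D + a2 K + a3 DK + a4 D^2 + a5 K^2 + a6 D^2 K + a7 D K^2 +
#' a8 D^3 + a9 K^3, fitted by ordinary least squares separately for targets
#' D0 and L. A mapping is specific to the diffusion protocol and SNR it was
#' trained on; models therefore carry their context and refuse silent
#' application elsewhere.
#'
#' @name polymap
NULL

#' Monomial feature row
#'
#' @param D Apparent diffusion coefficient (um^2/ms).
#' @param K Apparent kurtosis.
#' @return Numeric 10-vector (1, D, K, DK, D^2, K^2, D^2 K, D K^2, D^3, K^3).
#' @export
design_row <- function(D, K) {
  c(1, D, K, D * K, D^2, K^2, D^2 * K, D * K^2, D^3, K^3)
}

#' Monomial design matrix
#'
#' @param D,K Numeric vectors of equal length.
#' @return n x 10 matrix, rows as [design_row()].
#' @export
design_matrix <- function(D, K) {
  cbind(1, D, K, D * K, D^2, K^2, D^2 * K, D * K^2, D^3, K^3,
        deparse.level = 0)
}

#' Split grid centres into training and validation sets
#'
#' With the full 1189-centre grid the split is 700 training / 489 validation;
#' for reduced grids pass `n_train` explicitly (the same 700:489 proportion is
#' a sensible choice).
#'
#' @param ids Vector of centre identifiers.
#' @param n_train Number of training centres (default 700, requiring
#'   `length(ids) == 1189`).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List with `train` and `validation` id vectors (disjoint,
#'   exhaustive).
#' @export
split_train_validation <- function(ids, n_train = 700L, seed = 1L) {
  n <- length(ids)
  if (missing(n_train) && n != 1189)
    stop("split_train_validation: expected 1189 centres; pass n_train for reduced grids")
  if (n_train >= n || n_train < 1)
    stop("split_train_validation: invalid n_train")
  tr <- with_seed(seed, sample(n, n_train))
  list(train = ids[sort(tr)], validation = ids[sort(setdiff(seq_len(n), tr))])
}

#' Fit the PolyMap model
#'
#' @param D,K Training cumulants.
#' @param D0,L Training ground truth.
#' @param context Optional list describing the training context (protocol
#'   timings, bmax, SNR); stored on the model and checked at prediction time.
#' @return A `polymap_model` with 10 coefficients per target.
#' @export
fit_polymap <- function(D, K, D0, L, context = NULL) {
  X <- design_matrix(D, K)
  if (nrow(X) < 10) stop("fit_polymap: need at least 10 training rows")
  qrX <- qr(X)
  if (qrX$rank < 10)
    warning("fit_polymap: rank-deficient design; minimum-norm solution")
  solve_ls <- function(y) {
    cf <- qr.coef(qrX, y)
    cf[is.na(cf)] <- 0
    unname(cf)
  }
  structure(list(coef_D0 = solve_ls(D0), coef_L = solve_ls(L),
                 context = context, n_train = nrow(X)),
            class = "polymap_model")
}

#' Predict D0 and L from cumulants
#'
#' @param object A `polymap_model`.
#' @param D,K Cumulants to map.
#' @param context Context of the data being mapped; must match the training
#'   context unless `override = TRUE`.
#' @param override Allow cross-context application (discouraged: the mapping
#'   is protocol- and SNR-specific).
#' @param ... Unused.
#' @return Data frame with `D0_hat`, `L_hat`.
#' @export
predict.polymap_model <- function(object, D, K, context = NULL,
                                  override = FALSE, ...) {
  if (!is.null(object$context) && !override) {
    if (is.null(context) || !identical(object$context, context))
      stop("polymap: context mismatch (protocol/SNR); pass override = TRUE to force")
  }
  X <- design_matrix(D, K)
  data.frame(D0_hat = as.numeric(X %*% object$coef_D0),
             L_hat = as.numeric(X %*% object$coef_L))
}

#' Prediction errors with per-bin summaries
#'
#' Error = prediction - ground truth; rows are returned per observation and
#' summarized per unique ground-truth value (median and interquartile range).
#'
#' @param model A `polymap_model`.
#' @param D,K Validation cumulants.
#' @param D0,L Validation ground truth.
#' @param context,override Passed to [predict.polymap_model()].
#' @return List with `errors` (per-row data frame) and `by_truth`
#'   (per-ground-truth-bin medians/IQRs for each target).
#' @export
predict_and_score <- function(model, D, K, D0, L, context = NULL,
                              override = FALSE) {
  pr <- predict(model, D, K, context = context, override = override)
  err <- data.frame(D0 = D0, L = L, D0_hat = pr$D0_hat, L_hat = pr$L_hat,
                    err_D0 = pr$D0_hat - D0, err_L = pr$L_hat - L)
  bin_summary <- function(truth, e) {
    u <- sort(unique(truth))
    do.call(rbind, lapply(u, function(v) {
      ei <- e[truth == v]
      data.frame(truth = v, median = median(ei),
                 q25 = quantile(ei, 0.25, names = FALSE),
                 q75 = quantile(ei, 0.75, names = FALSE), n = length(ei))
    }))
  }
  list(errors = err,
       by_truth = list(D0 = bin_summary(D0, err$err_D0),
                       L = bin_summary(L, err$err_L)))
}
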