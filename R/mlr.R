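# Multinomial logistic regression core: deterministic Newton (Fisher
# scoring) fit with an optional tiny ridge on slopes so forward selection
# never crashes on perfectly separable teaching subsets. The first declared
# class is the baseline; coefficients are (features + intercept) x (K - 1).

mlr_nll <- function(B, X, y_idx, ridge) {
  eta <- cbind(0, X %*% B)
  mx <- row_max(eta)
  lse <- mx + log(rowSums(exp(eta - mx)))
  -sum(eta[cbind(seq_along(y_idx), y_idx)] - lse) +
    ridge / 2 * sum(B[-1, , drop = FALSE]^2)
}

mlr_newton <- function(X, y_idx, K, ridge = 1e-6, maxit = 200, tol = 1e-10) {
  n <- nrow(X); d <- ncol(X); np <- d * (K - 1)
  B <- matrix(0, d, K - 1)
  pen <- rep(seq_len(d) != 1L, K - 1)
  nll <- mlr_nll(B, X, y_idx, ridge)
  Yd <- matrix(0, n, K); Yd[cbind(seq_len(n), y_idx)] <- 1
  for (it in seq_len(maxit)) {
    eta <- cbind(0, X %*% B)
    mx <- row_max(eta)
    E <- exp(eta - mx); P <- E / rowSums(E)
    G <- as.vector(crossprod(X, P[, -1, drop = FALSE] - Yd[, -1, drop = FALSE]))
    G <- G + ridge * ifelse(pen, as.vector(B), 0)
    H <- matrix(0, np, np)
    for (a in seq_len(K - 1)) {
      for (b in seq_len(a)) {
        w <- P[, a + 1] * ((a == b) - P[, b + 1])
        blk <- crossprod(X, X * w)
        ia <- (a - 1) * d + seq_len(d); ib <- (b - 1) * d + seq_len(d)
        H[ia, ib] <- blk
        if (a != b) H[ib, ia] <- blk
      }
    }
    diag(H) <- diag(H) + ridge * pen + 1e-12
    step <- tryCatch(solve(H, G), error = function(e) G / max(diag(H)))
    s <- 1
    repeat {
      Bn <- B - s * matrix(step, d, K - 1)
      nn <- mlr_nll(Bn, X, y_idx, ridge)
      if (is.finite(nn) && nn <= nll + 1e-12) break
      s <- s / 2
      if (s < 1e-10) { Bn <- B; nn <- nll; break }
    }
    dec <- nll - nn
    B <- Bn; nll <- nn
    if (dec < tol) break
  }
  list(B = B, nll_pen = nll, iterations = it)
}

#' Fit a multinomial logistic regression model
#'
#' Maximum-likelihood multinomial logit with intercept (binary logistic for
#' two classes), fitted by Newton iterations from a zero start, so the fit is
#' a deterministic function of its input. A tiny ridge penalty on the slopes
#' (default `1e-6`) keeps coefficients finite under perfect separation; such
#' fits are flagged. BIC is `-2 loglik + p_total log(n)` with `p_total =
#' (features + 1)(K - 1)`; the ridge is excluded from the parameter count and
#' the log-likelihood is reported unpenalized.
#'
#' @param x Numeric matrix (samples x features) with column names; zero
#'   columns give the intercept-only model.
#' @param y Class labels (factor; its levels declare the class order, first
#'   level = baseline).
#' @param ridge Ridge penalty on slopes.
#' @return A `signature_model`: ordered `features`, `classes`, coefficient
#'   matrix, `loglik`, `bic`, `n`, optional `threshold`, `flag`.
#' @export
fit_mlr <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) abort("Need >= 2 classes present.", class = "sevlip_model_error")
  if (anyNA(x)) abort("Features contain missing values.", class = "sevlip_model_error")
  if (nrow(x) != length(y)) abort("x and y are not conformable.", class = "sevlip_model_error")
  p <- ncol(x)
  if (nrow(x) <= p + 1) {
    abort("Need n > p + 1 samples to fit.", class = "sevlip_model_error")
  }
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Rank-deficient features: %s collinear with the rest.",
                  paste(dropped, collapse = ", ")),
          class = "sevlip_model_error")
  }
  fit <- mlr_newton(X, as.integer(y), K, ridge = ridge)
  B <- fit$B
  dimnames(B) <- list(colnames(X), levels(y)[-1])
  loglik <- -mlr_nll(B, X, as.integer(y), ridge = 0)
  n_params <- (p + 1) * (K - 1)
  flag <- if (max(abs(B)) > 10) "possible_separation" else NA_character_
  structure(
    list(features = colnames(x) %||% character(), classes = levels(y),
         coef = B, loglik = loglik,
         bic = -2 * loglik + n_params * log(nrow(x)),
         n = nrow(x), n_params = n_params, ridge = ridge,
         threshold = NULL, flag = flag),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d-class multinomial logit, %d feature(s)\n",
              length(x$classes), length(x$features)))
  if (length(x$features)) {
    cat("  features (addition order): ", paste(x$features, collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  loglik %.3f, BIC %.3f, n = %d\n", x$loglik, x$bic, x$n))
  if (!is.null(x$threshold)) cat(sprintf("  decision threshold %.4f\n", x$threshold))
  invisible(x)
}

#' Predicted class probabilities
#'
#' @param object A `signature_model`.
#' @param newdata Samples x features matrix (or data frame) containing the
#'   model's features by name.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns in declared class order).
#' @export
predict.signature_model <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata))
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f)) {
    abort(sprintf("Feature column(s) missing: %s.", paste(missing_f, collapse = ", ")),
          class = "sevlip_model_error")
  }
  X <- cbind(1, newdata[, object$features, drop = FALSE])
  eta <- cbind(0, X %*% object$coef)
  mx <- row_max(eta)
  E <- exp(eta - mx)
  P <- E / rowSums(E)
  colnames(P) <- object$classes
  P
}

#' Maximum-a-posteriori classification
#'
#' Assigns each sample to the class with the highest predicted probability;
#' exact ties go to the earlier class in the declared order.
#'
#' @param model A `signature_model`.
#' @param features Samples x features matrix.
#' @return Factor of class labels (levels = the model's classes).
#' @export
map_classify <- function(model, features) {
  P <- predict(model, features)
  # probabilities within 1e-9 of the row maximum count as tied; ties resolve
  # to the earliest class in the declared order
  mx <- row_max(P)
  first_tied <- apply(P >= mx - 1e-9, 1L, which.max)
  factor(model$classes[first_tied], levels = model$classes)
}
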