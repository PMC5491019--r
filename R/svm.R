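## RBF-kernel support vector classifier with probability outputs.
##
## No SVM library is assumed: training solves the C-SVC dual by sequential
## minimal optimization on a precomputed RBF kernel (see src/svm.cpp), and
## probabilities come from a Platt sigmoid fitted to the training decision
## values by penalized maximum likelihood.

#' RBF-kernel SVM hyperparameters
#'
#' @param gamma RBF width `K(s_i, s_j) = exp(-gamma * ||s_i - s_j||^2)`;
#'   `NULL` means `1 / n_features` at fit time.
#' @param cost Soft-margin penalty C.
#' @return List of class `"svm_params"`.
#' @export
svm_params <- function(gamma = NULL, cost = 1) {
  stopifnot(is.null(gamma) || gamma > 0, cost > 0)
  structure(list(gamma = gamma, cost = cost), class = "svm_params")
}

#' Train a binary RBF-kernel SVM
#'
#' @param x Numeric feature matrix (one row per sample).
#' @param y Labels: logical, 0/1, or a character vector with
#'   `"positive"` as the positive class.
#' @param params An [svm_params()].
#' @param probability Fit a Platt sigmoid for probability estimates
#'   (default `TRUE`).
#' @param eps SMO stopping tolerance on the KKT violation gap.
#' @param max_iter Iteration cap (default scales with sample count).
#' @return Object of class `"palm_svm"`.
#' @export
svm_train <- function(x, y, params = svm_params(), probability = TRUE,
                      eps = 1e-3, max_iter = NULL) {
  x <- as.matrix(x)
  yy <- as_pm1(y)
  if (length(yy) != nrow(x)) stop("x and y lengths differ")
  if (length(unique(yy)) < 2L) stop("training data contain a single class")
  gamma <- params$gamma %||% (1 / ncol(x))
  if (is.null(max_iter)) max_iter <- max(20000L, 200L * nrow(x))
  K <- rbf_kernel_cpp(x, x, gamma)
  sol <- smo_solve_cpp(K, yy, params$cost, eps, as.integer(max_iter))
  if (!sol$converged) {
    warning("SMO hit the iteration cap (", sol$iterations, ")")
  }
  sv <- which(sol$alpha > 1e-8)
  model <- structure(list(sv_x = x[sv, , drop = FALSE],
                          coef = sol$alpha[sv] * yy[sv],
                          b = sol$b, gamma = gamma, cost = params$cost,
                          n_features = ncol(x), platt = NULL,
                          iterations = sol$iterations,
                          converged = sol$converged),
                     class = "palm_svm")
  if (probability) {
    f <- as.vector(K[, sv, drop = FALSE] %*% model$coef) + model$b
    model$platt <- platt_fit(f, yy)
  }
  model
}

as_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.numeric(y)) return(ifelse(y > 0, 1, -1))
  ifelse(as.character(y) == "positive", 1, -1)
}

#' Decision values and probabilities of a trained SVM
#'
#' @param model A `"palm_svm"`.
#' @param x Feature matrix with the training dimensionality.
#' @return `svm_decision()`: numeric decision values (positive side of the
#'   hyperplane > 0). `svm_probability()`: Platt-calibrated probabilities
#'   of the positive class in \[0, 1\].
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) stop("feature dimension mismatch")
  Kx <- rbf_kernel_cpp(x, model$sv_x, model$gamma)
  as.vector(Kx %*% model$coef) + model$b
}

#' @rdname svm_decision
#' @export
svm_probability <- function(model, x) {
  if (is.null(model$platt)) stop("model was trained without probability = TRUE")
  platt_predict(model$platt, svm_decision(model, x))
}

## Platt sigmoid fit (penalized ML with smoothed targets), Newton descent
## with backtracking line search.
platt_fit <- function(f, y, max_iter = 100L) {
  y <- as_pm1(y)
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  nll <- function(A, B) {
    z <- A * f + B
    ## stable cross-entropy: t*z + log(1 + exp(-z)) for z >= 0, else
    ## (t - 1)*z + log(1 + exp(z))
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- nll(A, B)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- p * q
    g1 <- sum(f * (t - p)); g2 <- sum(t - p)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d1) + sigma
    h22 <- sum(d1) + sigma
    h21 <- sum(f * d1)
    det <- h11 * h22 - h21 * h21
    ## Newton descent on the nll: gradient is (g1, g2), step -H^{-1} g
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newval <- nll(newA, newB)
      if (newval < val + 1e-4 * step * gd || step < 1e-10) break
      step <- step / 2
    }
    if (step < 1e-10) break
    A <- A + step * dA; B <- B + step * dB
    val <- nll(A, B)
  }
  list(A = A, B = B)
}

platt_predict <- function(platt, f) {
  z <- platt$A * f + platt$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}
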