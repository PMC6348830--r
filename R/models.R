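#' Physical decay constant of Lu-177
#'
#' Decay constant \eqn{\lambda_{phys} = \ln 2 / T_{1/2}} for Lu-177
#' (half-life 6.647 d), in 1/h. Effective clearance rates of a Lu-177
#' labelled compound can never fall below this value: even perfectly
#' retained activity decays physically.
#'
#' @return Decay constant in 1/h (about 4.345e-3).
#' @export
#' @examples
#' log(2) / lambda_phys_lu177() / 24 # half-life in days
lambda_phys_lu177 <- function() log(2) / (6.647 * 24)

#' Sum-of-exponentials time-activity model
#'
#' Represents a fitted (or ground-truth) time-activity function
#' \eqn{f(t) = \sum_i A_i e^{-\lambda_i t}} where the \eqn{\lambda_i} are
#' *effective* rate constants (biological clearance plus physical decay).
#' Amplitudes are in curve units (%IA for organs, %IA/mL for blood).
#'
#' Validity requires every \eqn{\lambda_i \ge \lambda_{phys}} and
#' \eqn{f(t) \ge 0} for all \eqn{t \ge 0}. Non-negativity is enforced
#' structurally: either all amplitudes are non-negative, or the model is an
#' uptake-washout ("bi-uptake") pattern with one positive slow term and one
#' negative fast term whose amplitudes sum to a non-negative value.
#'
#' @param A Numeric vector of amplitudes (1 or 2 terms).
#' @param lambda Numeric vector of effective rate constants (1/h), same
#'   length as `A`.
#' @param lambda_phys Physical decay constant (1/h). Default Lu-177.
#' @return An object of class `exp_model` with elements `terms`
#'   (data frame with columns `A`, `lambda`) and `lambda_phys`.
#' @export
#' @examples
#' m <- exp_model(A = c(30, 10), lambda = c(0.5, 0.01))
#' predict(m, c(0, 1, 24))
exp_model <- function(A, lambda, lambda_phys = lambda_phys_lu177()) {
  if (length(A) != length(lambda)) {
    stop_bk("'A' and 'lambda' must have the same length")
  }
  if (length(A) < 1L || length(A) > 2L) {
    stop_bk("a model must have 1 or 2 exponential terms")
  }
  if (!is.numeric(A) || !is.numeric(lambda) || anyNA(A) || anyNA(lambda)) {
    stop_bk("amplitudes and rates must be finite numbers")
  }
  if (!is_number(lambda_phys) || lambda_phys < 0) {
    stop_bk("'lambda_phys' must be a non-negative number")
  }
  tol <- 1e-12
  if (any(lambda < lambda_phys - tol)) {
    stop_bk(
      "every effective rate must be >= lambda_phys (",
      format(lambda_phys), " 1/h); got ",
      paste(format(lambda), collapse = ", ")
    )
  }
  if (any(A < 0)) {
    # only the uptake-washout sign pattern is allowed: positive slow term,
    # negative fast term, f(0) = sum(A) >= 0
    if (length(A) != 2L) stop_bk("a single term must have A >= 0")
    pos <- which(A >= 0)
    neg <- which(A < 0)
    if (length(pos) != 1L || length(neg) != 1L ||
        lambda[neg] <= lambda[pos] || sum(A) < -tol) {
      stop_bk(
        "negative amplitudes are only valid as an uptake-washout pattern ",
        "(A_fast < 0, lambda_fast > lambda_slow, A_slow + A_fast >= 0)"
      )
    }
  }
  # store fast term first for positive models (display convention)
  ord <- if (all(A >= 0)) order(lambda, decreasing = TRUE) else order(A, decreasing = TRUE)
  structure(
    list(
      terms = data.frame(A = A[ord], lambda = lambda[ord]),
      lambda_phys = lambda_phys
    ),
    class = "exp_model"
  )
}

#' Evaluate a sum-of-exponentials model
#'
#' @param object An [exp_model()].
#' @param t Times (h) at which to evaluate; must be >= 0.
#' @param ... Unused.
#' @return Model values at `t`, in curve units.
#' @export
predict.exp_model <- function(object, t, ...) {
  if (any(t < 0)) stop_bk("model defined for t >= 0 only")
  vals <- numeric(length(t))
  for (i in seq_len(nrow(object$terms))) {
    vals <- vals + object$terms$A[i] * exp(-object$terms$lambda[i] * t)
  }
  vals
}

#' @export
print.exp_model <- function(x, ...) {
  cat("<exp_model>", nrow(x$terms), "term(s), lambda_phys =",
      format(x$lambda_phys), "1/h\n")
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  A = %-12.6g lambda = %-12.6g (t1/2 eff = %.3g h)\n",
                x$terms$A[i], x$terms$lambda[i], log(2) / x$terms$lambda[i]))
  }
  invisible(x)
}

# number of exponential terms
n_terms <- function(model) nrow(model$terms)
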