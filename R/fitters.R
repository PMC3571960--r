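#' @import data.table
#' @importFrom stats plogis qlogis qnorm qchisq quantile median sd setNames
#'   rnorm runif rbinom rgamma complete.cases
#' @importFrom utils write.csv head
NULL

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Core fitting routine for every pooled logistic model in the package
#' (treatment, censoring and outcome models). Fisher scoring on the
#' Bernoulli log-likelihood with per-row weights, convergence declared when
#' the deviance changes by less than `tol`, hard cap of `maxit` iterations.
#'
#' @param X numeric design matrix (including the intercept column).
#' @param y 0/1 response vector.
#' @param w optional non-negative row weights (default all 1).
#' @param tol convergence tolerance on the deviance (default `1e-8`).
#' @param maxit iteration cap (default 100).
#' @return list with `coef`, `vcov` (inverse Fisher information), `fitted`
#'   (probabilities), `deviance`, `converged`, `iter`.
#' @keywords internal
logit_irls <- function(X, y, w = NULL, tol = 1e-8, maxit = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(y) == n, length(w) == n, all(w >= 0), all(y %in% c(0, 1)))
  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  p <- rep(mean(y), n)
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    # clamp to keep the weighted least-squares step finite under separation
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p)))
    if (abs(dev_old - dev) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    ww <- w * p * (1 - p)
    XtWX <- crossprod(X, X * ww)
    score <- crossprod(X, w * (y - p))
    step <- tryCatch(solve(XtWX, score), error = function(e) {
      stop("singular information matrix in logistic fit (separation or collinearity): ",
           conditionMessage(e), call. = FALSE)
    })
    beta <- beta + drop(step)
  }
  eta <- drop(X %*% beta)
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  ww <- w * p * (1 - p)
  XtWX <- crossprod(X, X * ww)
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = setNames(drop(beta), colnames(X)), vcov = vc, fitted = p,
       deviance = dev_old, converged = converged, iter = iter)
}

#' Knot locations for the follow-up-time spline
#'
#' Percentile knots (by default the 5th, 25th, 50th, 75th and 95th) of the
#' person-month follow-up times in the analysis table. Knots are placed on
#' the time values of all person-month rows, not on event times.
#'
#' @param months vector of follow-up month values (one per person-month row).
#' @param probs knot percentiles as probabilities.
#' @return numeric vector of strictly increasing knots.
#' @export
spline_knots <- function(months, probs = c(0.05, 0.25, 0.50, 0.75, 0.95)) {
  if (length(unique(months)) < length(probs))
    stop("fewer distinct month values than knots; use linear time instead",
         call. = FALSE)
  k <- unique(unname(quantile(months, probs, type = 7)))
  if (length(k) < 3)
    stop("knot percentiles collapse to <3 distinct values; use linear time instead",
         call. = FALSE)
  k
}

#' Restricted (natural) cubic spline basis
#'
#' Truncated-power natural cubic spline: K knots give K-1 columns, the first
#' being the identity (linear term). The basis is linear beyond the boundary
#' knots and every nonlinear column vanishes at and below the first knot.
#' No rescaling of the cubic terms is applied; coefficients are therefore in
#' units of months^3 for the nonlinear columns.
#'
#' @param x evaluation points (months).
#' @param knots strictly increasing knot vector (from [spline_knots()]).
#' @return matrix with `length(knots) - 1` columns named `t`, `t_nl1`, ...
#' @export
spline_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  K <- length(knots)
  if (K < 3) stop("need at least 3 knots for a restricted cubic basis", call. = FALSE)
  kK <- knots[K]
  kK1 <- knots[K - 1]
  cub <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), K - 1)
  B[, 1] <- x
  for (j in seq_len(K - 2)) {
    B[, j + 1] <- cub(x - knots[j]) -
      cub(x - kK1) * (kK - knots[j]) / (kK - kK1) +
      cub(x - kK)  * (kK1 - knots[j]) / (kK - kK1)
  }
  colnames(B) <- c("t", if (K > 2) paste0("t_nl", seq_len(K - 2)))
  B
}

# --- design-matrix builders shared by the weight and outcome models -------

baseline_design <- function(pm) {
  cbind(age = pm$age_entry,
        male = as.numeric(pm$gender == "male"),
        cd4_art_start100 = pm$cd4_art_start / 100,
        cd4_entry100 = pm$cd4_entry / 100,
        vl_supp_entry = as.numeric(pm$vl_suppressed_entry),
        art_years = pm$art_duration_entry / 12,
        who34 = as.numeric(pm$who_stage == "III/IV"))
}

timevarying_design <- function(pm) {
  cbind(cd4_current100 = pm$cd4_current / 100,
        cd4_lag6_100 = pm$cd4_lag6 / 100,
        vl_supp = as.numeric(pm$vl_suppressed))
}

time_design <- function(pm, knots) {
  if (is.null(knots)) cbind(t = pm$t) else spline_basis(pm$t, knots)
}

# drop zero-variance non-intercept columns (e.g. entry suppression in the
# rebound analysis, which is restricted to entry-suppressed patients)
drop_constant_cols <- function(X) {
  ranges <- apply(X, 2, function(col) diff(range(col)))
  X[, colnames(X) == "(Intercept)" | ranges > .Machine$double.eps,
    drop = FALSE]
}
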