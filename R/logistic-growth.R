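#' Logistic growth parameters
#'
#' Container for the three parameters of the logistic growth model
#' \deqn{y(t) = A / (1 + B e^{-Kt})}
#' where `t` is age in days and `y(t)` body weight in kg.
#'
#' @param A Asymptotic (mature) body weight, kg. Must be positive.
#' @param B Dimensionless shape parameter locating the inflection at
#'   `t = ln(B)/K`. Must be positive.
#' @param K Intrinsic growth-rate parameter, per day. Must be positive.
#'
#' @return An object of class `logistic_params`: a named list with elements
#'   `A`, `B`, `K`.
#' @examples
#' yp <- logistic_params(A = 160.493, B = 16.901, K = 0.022)
#' predict_weight(yp, age = 150)
#' @export
logistic_params <- function(A, B, K) {
  vals <- c(A = A, B = B, K = K)
  if (length(vals) != 3L || !is.numeric(vals)) {
    stop("A, B and K must each be a single numeric value", call. = FALSE)
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid logistic parameters: A, B and K must all be positive and finite",
         call. = FALSE)
  }
  structure(list(A = unname(A), B = unname(B), K = unname(K)),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic growth parameters: A = %.6g kg, B = %.6g, K = %.6g /day\n",
              x$A, x$B, x$K))
  invisible(x)
}

# Coerce a logistic_params, a named list, or a length-3 numeric (A, B, K).
as_logistic_params <- function(x) {
  if (inherits(x, "logistic_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(logistic_params(x[[1]], x[[2]], x[[3]]))
  if (is.list(x) && all(c("A", "B", "K") %in% names(x))) {
    return(logistic_params(x$A, x$B, x$K))
  }
  stop("cannot interpret 'params' as logistic parameters (need A, B, K)",
       call. = FALSE)
}

#' Predicted body weight under the logistic growth model
#'
#' Evaluates `y(t) = A / (1 + B exp(-K t))`.
#'
#' @param params A [logistic_params()] object (or anything coercible: a named
#'   list or a length-3 numeric `c(A, B, K)`).
#' @param age Age(s) in days, `>= 0`.
#' @return Predicted weight(s) in kg, strictly between 0 and `A`.
#' @export
predict_weight <- function(params, age) {
  p <- as_logistic_params(params)
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    stop("'age' must be finite and non-negative (days)", call. = FALSE)
  }
  p$A / (1 + p$B * exp(-p$K * age))
}

#' Instantaneous growth rate of the logistic model
#'
#' First derivative of [predict_weight()] with respect to age:
#' `dy/dt = A K B exp(-Kt) / (1 + B exp(-Kt))^2`, maximal exactly at the
#' inflection age `ln(B)/K` where it equals `A K / 4`.
#'
#' @inheritParams predict_weight
#' @return Growth rate(s) in kg per day (always positive).
#' @export
growth_rate <- function(params, age) {
  p <- as_logistic_params(params)
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    stop("'age' must be finite and non-negative (days)", call. = FALSE)
  }
  u <- p$B * exp(-p$K * age)
  p$A * p$K * u / (1 + u)^2
}

#' Age at which the logistic curve reaches a given weight
#'
#' Inverse of [predict_weight()]: `t = ln(B y / (A - y)) / K`.
#'
#' @inheritParams predict_weight
#' @param weight Target weight(s) in kg, strictly between 0 and `A`.
#' @return Age(s) in days (possibly negative for weights below `y(0)`).
#' @export
age_at_weight <- function(params, weight) {
  p <- as_logistic_params(params)
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight >= p$A)) {
    stop("'weight' must lie strictly between 0 and the asymptote A", call. = FALSE)
  }
  log(p$B * weight / (p$A - weight)) / p$K
}

#' Growth landmarks of a fitted logistic curve
#'
#' Closed-form landmark quantities of the logistic model:
#' \itemize{
#'   \item inflection age `ln(B)/K` (days) — where daily gain peaks;
#'   \item inflection weight `A/2` (kg);
#'   \item maximum daily gain `A K / 4`, reported in g/day (`250 A K` for
#'     `A` in kg);
#'   \item maximum-deceleration age `[ln(B) + ln(2 + sqrt(3))]/K` (days) —
#'     the post-inflection root of the third derivative, where the growth
#'     rate declines fastest; proposed as the optimal slaughter age;
#'   \item weight at that age, `A (3 + sqrt(3)) / 6` (kg).
#' }
#'
#' @inheritParams predict_weight
#' @return An object of class `growth_landmarks`: a named list with elements
#'   `inflection_age`, `inflection_weight`, `max_daily_gain` (g/day),
#'   `max_decel_age`, `max_decel_weight`.
#' @examples
#' growth_landmarks(logistic_params(160.493, 16.901, 0.022))
#' @export
growth_landmarks <- function(params) {
  p <- as_logistic_params(params)
  structure(list(
    inflection_age    = log(p$B) / p$K,
    inflection_weight = p$A / 2,
    max_daily_gain    = 250 * p$A * p$K,
    max_decel_age     = (log(p$B) + log(2 + sqrt(3))) / p$K,
    max_decel_weight  = p$A * (3 + sqrt(3)) / 6
  ), class = "growth_landmarks")
}

#' @export
print.growth_landmarks <- function(x, ...) {
  cat("Growth landmarks (logistic model)\n")
  cat(sprintf("  inflection:        %.2f kg at %.2f days\n",
              x$inflection_weight, x$inflection_age))
  cat(sprintf("  max daily gain:    %.2f g/day\n", x$max_daily_gain))
  cat(sprintf("  max deceleration:  %.2f kg at %.2f days\n",
              x$max_decel_weight, x$max_decel_age))
  invisible(x)
}

#' Fit the logistic growth model to longitudinal weight records
#'
#' Pools all supplied (age, weight) observations — by default every animal of
#' one breed, giving one population curve — and estimates `(A, B, K)` by
#' Levenberg–Marquardt nonlinear least squares on log-transformed parameters
#' (so positivity is enforced by construction). Starting values are
#' `A0 = 1.05 * max(weight)` and a linear regression of
#' `log(A0 / y - 1)` on age (`intercept = ln B0`, `slope = -K0`).
#'
#' @param records A data frame with numeric columns `age_days` and
#'   `weight_kg` (extra columns such as `animal_id`, `breed` are kept for
#'   bookkeeping only).
#' @param max_iter Maximum Levenberg–Marquardt iterations.
#' @param tol Relative SSE convergence tolerance.
#' @return An object of class `logistic_fit` with elements `params`
#'   ([logistic_params()]), `pcc` (Pearson correlation between observed and
#'   fitted weights), `n_animals`, `n_points`, `residual_sd` (kg), and
#'   `fitted`.
#' @export
fit_logistic <- function(records, max_iter = 500, tol = 1e-10) {
  if (!is.data.frame(records) ||
      !all(c("age_days", "weight_kg") %in% names(records))) {
    stop("'records' must be a data frame with columns age_days and weight_kg",
         call. = FALSE)
  }
  age <- as.numeric(records$age_days)
  w   <- as.numeric(records$weight_kg)
  ok  <- is.finite(age) & is.finite(w) & age > 0 & w > 0
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with non-finite or non-positive values dropped")
    age <- age[ok]; w <- w[ok]
  }
  if (nrow(unique(cbind(age, w))) < 4L) {
    stop("insufficient data: need at least 4 distinct (age, weight) points",
         call. = FALSE)
  }
  mid <- (min(w) + max(w)) / 2
  if (all(w <= mid) || all(w >= mid)) {
    warning("weights do not span both sides of the empirical mid-weight; ",
            "the asymptote may be poorly identified")
  }

  A0 <- 1.05 * max(w)
  z  <- log(pmax(A0 / w - 1, 1e-8))
  ols <- stats::lm.fit(cbind(1, age), z)
  B0 <- exp(ols$coefficients[[1]])
  K0 <- -ols$coefficients[[2]]
  if (!is.finite(K0) || K0 <= 0) K0 <- 0.02
  if (!is.finite(B0) || B0 <= 0) B0 <- 10

  dat <- data.frame(age = age, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ exp(lA) / (1 + exp(lB) * exp(-exp(lK) * age)),
      data = dat,
      start = list(lA = log(A0), lB = log(B0), lK = log(K0)),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol)
    ),
    error = function(e) {
      stop("logistic fit failed to converge: ", conditionMessage(e),
           " (starting values A0=", signif(A0, 6), ", B0=", signif(B0, 4),
           ", K0=", signif(K0, 4), ")", call. = FALSE)
    }
  )
  cf <- exp(stats::coef(fit))
  params <- logistic_params(A = cf[["lA"]], B = cf[["lB"]], K = cf[["lK"]])
  fitted_w <- predict_weight(params, age)
  resid <- w - fitted_w
  n_par <- 3L
  structure(list(
    params      = params,
    pcc         = stats::cor(w, fitted_w),
    n_animals   = if ("animal_id" %in% names(records))
                    length(unique(records$animal_id[ok])) else NA_integer_,
    n_points    = length(w),
    residual_sd = sqrt(sum(resid^2) / max(length(w) - n_par, 1L)),
    fitted      = fitted_w
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic growth fit: %d points%s, PCC = %.4f, residual SD = %.3f kg\n",
    x$n_points,
    if (!is.na(x$n_animals)) sprintf(" (%d animals)", x$n_animals) else "",
    x$pcc, x$residual_sd))
  print(x$params)
  invisible(x)
}

#' Average daily gain at given ages
#'
#' The field's "ADG" has no single definition; two conventions are offered.
#' `"cumulative"` (default) is the cumulative gain since `start_age` divided
#' by the elapsed days, `(y(t) - y(start)) / (t - start)`; `"instantaneous"`
#' is the model growth rate `dy/dt` at `t`. Both are reported in g/day.
#'
#' @inheritParams predict_weight
#' @param ages Group mean ages, days (`> start_age` for the cumulative
#'   convention).
#' @param convention `"cumulative"` or `"instantaneous"`.
#' @param start_age Reference age for the cumulative convention, days
#'   (default 50, the start of routine fattening-period weighing).
#' @return Numeric vector of ADG values, g/day, one per age.
#' @export
adg_table <- function(params, ages,
                      convention = c("cumulative", "instantaneous"),
                      start_age = 50) {
  convention <- match.arg(convention)
  p <- as_logistic_params(params)
  if (any(!is.finite(ages)) || any(ages <= 0)) {
    stop("'ages' must be positive and finite", call. = FALSE)
  }
  if (convention == "instantaneous") {
    return(1000 * growth_rate(p, ages))
  }
  if (any(ages <= start_age)) {
    stop("cumulative ADG needs ages greater than start_age", call. = FALSE)
  }
  1000 * (predict_weight(p, ages) - predict_weight(p, start_age)) /
    (ages - start_age)
}
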