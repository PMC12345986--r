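#' Fit a trait-versus-body-weight trajectory
#'
#' Models how a slaughter trait (e.g. loin muscle area or intramuscular fat)
#' changes with body weight over the post-inflection range. Two families are
#' supported: a quadratic polynomial and the three-parameter asymptotic
#' (monomolecular) curve `y = a - b exp(-c bw)` with `c > 0`, which rises (or
#' falls, `b < 0`) towards the plateau `a`. With `model_form = "auto"` both
#' are fitted and the lower-AIC family kept.
#'
#' @param bw Body weights, kg (strictly positive).
#' @param trait Trait values, same length as `bw`.
#' @param model_form `"auto"`, `"asymptotic"` or `"quadratic"`.
#' @param trait_name,breed Optional labels carried into the result.
#' @return An object of class `trait_curve_fit`: list with `trait`, `breed`,
#'   `model_form`, `coefficients` (named `c0,c1,c2` for quadratic;
#'   `a,b,c` for asymptotic), `aic`, `bw_range`, `n`.
#' @export
fit_trait_curve <- function(bw, trait,
                            model_form = c("auto", "asymptotic", "quadratic"),
                            trait_name = NA_character_, breed = NA_character_) {
  model_form <- match.arg(model_form)
  ok <- is.finite(bw) & is.finite(trait)
  bw <- bw[ok]; trait <- trait[ok]
  if (any(bw <= 0)) stop("'bw' must be strictly positive (kg)", call. = FALSE)
  if (length(bw) < 6L) {
    stop("insufficient data: need at least 6 (bw, trait) points", call. = FALSE)
  }

  if (model_form == "auto") {
    fq <- fit_trait_curve(bw, trait, "quadratic", trait_name, breed)
    fa <- tryCatch(fit_trait_curve(bw, trait, "asymptotic", trait_name, breed),
                   error = function(e) NULL)
    if (is.null(fa) || fq$aic <= fa$aic) return(fq) else return(fa)
  }

  if (model_form == "quadratic") {
    m <- stats::lm(trait ~ bw + I(bw^2))
    coefs <- stats::setNames(stats::coef(m), c("c0", "c1", "c2"))
    aic <- stats::AIC(m)
  } else {
    # starting values: a0 just beyond the data extreme the curve approaches,
    # then log-linear regression of log|a0 - y| on bw for b0, c0
    increasing <- stats::cor(bw, trait) >= 0
    rng <- diff(range(trait))
    a0 <- if (increasing) max(trait) + 0.05 * max(rng, 1e-6)
          else            min(trait) - 0.05 * max(rng, 1e-6)
    resid0 <- a0 - trait
    zl <- log(pmax(abs(resid0), 1e-10))
    ols <- stats::lm.fit(cbind(1, bw), zl)
    c0 <- max(-ols$coefficients[[2]], 1e-4)
    b0 <- if (increasing) exp(ols$coefficients[[1]]) else -exp(ols$coefficients[[1]])
    m <- tryCatch(
      minpack.lm::nlsLM(
        trait ~ a - b * exp(-exp(lc) * bw),
        data = data.frame(bw = bw, trait = trait),
        start = list(a = a0, b = b0, lc = log(c0)),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) stop("asymptotic trait-curve fit failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    cf <- stats::coef(m)
    coefs <- c(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
               c = unname(exp(cf[["lc"]])))
    aic <- stats::AIC(m)
  }

  structure(list(
    trait = trait_name, breed = breed, model_form = model_form,
    coefficients = coefs, aic = aic,
    bw_range = range(bw), n = length(bw)
  ), class = "trait_curve_fit")
}

#' @export
print.trait_curve_fit <- function(x, ...) {
  lbl <- if (!is.na(x$trait)) paste0(x$trait, " ") else ""
  cat(sprintf("Trait trajectory fit (%s%s family), n = %d, AIC = %.2f\n",
              lbl, x$model_form, x$n, x$aic))
  print(signif(x$coefficients, 6))
  cat(sprintf("  body-weight range: %.1f - %.1f kg\n",
              x$bw_range[1], x$bw_range[2]))
  invisible(x)
}

#' Analytic slope of a fitted trait trajectory
#'
#' @param fit A [fit_trait_curve()] result.
#' @param bw Body weight(s), kg, at which to evaluate d(trait)/d(bw).
#' @return Slope(s) in trait units per kg.
#' @export
trait_slope <- function(fit, bw) {
  stopifnot(inherits(fit, "trait_curve_fit"))
  cf <- fit$coefficients
  if (fit$model_form == "quadratic") {
    cf[["c1"]] + 2 * cf[["c2"]] * bw
  } else {
    cf[["b"]] * cf[["c"]] * exp(-cf[["c"]] * bw)
  }
}

#' Detect the plateau weight of a trait trajectory
#'
#' A trajectory is declared to plateau at the smallest body weight in the
#' observed range where the magnitude of the fitted local slope falls below
#' `threshold_fraction` times the maximum fitted slope magnitude in range.
#' For the asymptotic family this has the closed form
#' `bw = bw_min + log(1/threshold_fraction) / c`; for other families the
#' slope is scanned on a grid.
#'
#' @param fit A [fit_trait_curve()] result.
#' @param threshold_fraction Fraction of the maximum in-range slope below
#'   which the curve counts as flat (default 0.1).
#' @param step Grid step for the numerical scan, kg.
#' @return An object of class `plateau_result`: list with `plateau_weight`
#'   (kg, or `NA` when the slope never drops below the threshold in range),
#'   `slope_at_plateau`, `max_slope`, `threshold_fraction`, plus the labels of
#'   the fit.
#' @export
plateau_weight <- function(fit, threshold_fraction = 0.1, step = 0.1) {
  stopifnot(inherits(fit, "trait_curve_fit"))
  if (!is.finite(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("'threshold_fraction' must lie in (0, 1)", call. = FALSE)
  }
  lo <- fit$bw_range[1]; hi <- fit$bw_range[2]
  grid <- seq(lo, hi, by = step)
  slopes <- abs(trait_slope(fit, grid))
  max_slope <- max(slopes)

  pw <- NA_real_
  if (max_slope > 0) {
    if (fit$model_form == "asymptotic") {
      # |slope| = |b| c e^{-c bw} is maximal at lo; crosses the threshold at
      # bw = lo + log(1/tf)/c
      cand <- lo + log(1 / threshold_fraction) / fit$coefficients[["c"]]
      if (cand <= hi) pw <- cand
    } else {
      idx <- which(slopes < threshold_fraction * max_slope)
      if (length(idx)) pw <- grid[min(idx)]
    }
  }

  structure(list(
    trait = fit$trait, breed = fit$breed,
    plateau_weight = pw,
    slope_at_plateau = if (is.na(pw)) NA_real_ else trait_slope(fit, pw),
    max_slope = max_slope,
    threshold_fraction = threshold_fraction
  ), class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  lbl <- if (!is.na(x$trait)) paste0(x$trait, ": ") else ""
  if (is.na(x$plateau_weight)) {
    cat(lbl, "no plateau within the observed body-weight range\n", sep = "")
  } else {
    cat(sprintf("%splateau at %.1f kg (slope %.4g, %.0f%% of max slope %.4g)\n",
                lbl, x$plateau_weight, x$slope_at_plateau,
                100 * x$threshold_fraction, x$max_slope))
  }
  invisible(x)
}
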