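#' Relative expression by the 2^-deltaCt method
#'
#' Per replicate, `deltaCt = Ct_target - Ct_reference` and expression
#' `2^-deltaCt` relative to the endogenous control (e.g. GAPDH); summarized as
#' mean and SD across replicates. Adding a constant to both Ct columns leaves
#' the result unchanged.
#'
#' @param target_ct,reference_ct paired Ct replicate vectors (finite, > 0).
#' @return list with `mean`, `sd`, `expression` (per replicate), `delta_ct`.
#' @export
relative_expression <- function(target_ct, reference_ct) {
  if (length(target_ct) != length(reference_ct)) {
    stop("target and reference Ct replicates must be paired")
  }
  if (any(!is.finite(target_ct)) || any(!is.finite(reference_ct)) ||
      any(target_ct <= 0) || any(reference_ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  dct <- target_ct - reference_ct
  expr <- 2^(-dct)
  list(mean = mean(expr), sd = stats::sd(expr), expression = expr,
       delta_ct = dct)
}

#' ER-stress decay call with IRE1-inhibitor rescue
#'
#' Tests whether a transcript decays under an ER-stress inducer in an
#' IRE1-dependent way. Decay: two-sided Welch t-test on replicate deltaCt,
#' inducer vs control, significant at `alpha` with lower expression under the
#' inducer. Rescue by the IRE1 RNase inhibitor 4u8c: met when expression with
#' inducer + inhibitor is not significantly below control
#' (`p_rescue >= alpha`) or recovers at least `rescue_fraction` of the control
#' mean (partial rescue counts). The gene is called IRE1-dependent when both
#' hold.
#'
#' @param control,inducer,inducer_4u8c lists with paired `target_ct` and
#'   `reference_ct` replicate vectors (as for [relative_expression()]).
#' @param alpha significance level (default 0.05).
#' @param rescue_fraction minimum recovered fraction of control expression
#'   (default 0.75).
#' @return list of class `"decay_call"`: per-condition mean expressions,
#'   `p_decay`, `p_rescue`, `ire1_dependent`, `testable`.
#' @export
decay_call <- function(control, inducer, inducer_4u8c, alpha = 0.05,
                       rescue_fraction = 0.75) {
  re <- lapply(list(control = control, inducer = inducer,
                    inducer_4u8c = inducer_4u8c),
               function(s) relative_expression(s$target_ct, s$reference_ct))
  n <- vapply(re, function(r) length(r$expression), integer(1))
  if (any(n < 2)) {
    return(structure(list(expr_control = re$control$mean,
                          expr_treated = re$inducer$mean,
                          expr_treated_plus_4u8c = re$inducer_4u8c$mean,
                          p_decay = NA_real_, p_rescue = NA_real_,
                          ire1_dependent = NA, testable = FALSE),
                     class = "decay_call"))
  }
  # Welch tests on the deltaCt scale (approximately normal, unlike 2^-dCt)
  p_decay <- stats::t.test(re$inducer$delta_ct, re$control$delta_ct)$p.value
  p_rescue <- stats::t.test(re$inducer_4u8c$delta_ct, re$control$delta_ct)$p.value
  decayed <- p_decay < alpha && re$inducer$mean < re$control$mean
  rescued <- p_rescue >= alpha ||
    re$inducer_4u8c$mean >= rescue_fraction * re$control$mean
  structure(list(expr_control = re$control$mean,
                 expr_treated = re$inducer$mean,
                 expr_treated_plus_4u8c = re$inducer_4u8c$mean,
                 p_decay = p_decay, p_rescue = p_rescue,
                 ire1_dependent = decayed && rescued, testable = TRUE),
            class = "decay_call")
}

#' @export
print.decay_call <- function(x, ...) {
  cat(sprintf(paste0("<decay_call> control %.3f | inducer %.3f (p=%.3g) | ",
                     "+4u8c %.3f (p=%.3g) -> IRE1-dependent: %s\n"),
              x$expr_control, x$expr_treated, x$p_decay,
              x$expr_treated_plus_4u8c, x$p_rescue, x$ire1_dependent))
  invisible(x)
}

#' Protein half-life from densitometry time courses
#'
#' Normalizes levels to the t = 0 value, fits `ln(level) = -k t` by least
#' squares, and returns `t1/2 = ln(2) / k`. A non-decaying series (`k <= 0`)
#' returns `Inf`.
#'
#' @param times time points in hours (>= 2, including 0).
#' @param levels normalized protein levels (> 0), same length.
#' @return list with `t_half` (hours), `k` (per hour), `r2`.
#' @export
half_life <- function(times, levels) {
  if (length(times) < 2 || length(levels) != length(times)) {
    stop("need >= 2 paired time points")
  }
  if (any(levels <= 0)) stop("protein levels must be positive")
  if (!any(times == 0)) stop("a t = 0 reference point is required")
  levels <- levels / levels[which(times == 0)[1]]
  fit <- stats::lm(log(levels) ~ times)
  k <- -unname(stats::coef(fit)[2])
  r2 <- if (length(times) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  list(t_half = if (k <= 0) Inf else log(2) / k, k = k, r2 = r2)
}

#' Fit the Chou-Talalay median-effect equation
#'
#' The median-effect model `fa/fu = (D/Dm)^m` linearizes to
#' `log(fa/(1-fa)) = m log D - m log Dm`; ordinary least squares on the
#' transformed points gives the slope `m` (sigmoidicity) and the median-effect
#' dose `Dm` (dose for 50% effect). Affected fractions are computed from
#' viabilities as `fa = 1 - V/V_control` when supplied. Boundary points
#' (`fa <= 0` or `fa >= 1`) are dropped with a warning.
#'
#' @param doses positive dose vector.
#' @param fa affected fractions in (0, 1); or supply `viability` and
#'   `v_control` instead.
#' @param viability,v_control raw viabilities and their untreated control.
#' @return object of class `"median_effect"`: `m`, `Dm`, `r2`, `n`.
#' @export
fit_median_effect <- function(doses, fa = NULL, viability = NULL,
                              v_control = NULL) {
  if (is.null(fa)) {
    if (is.null(viability) || is.null(v_control)) {
      stop("supply either fa or viability + v_control")
    }
    fa <- 1 - viability / v_control
  }
  if (length(fa) != length(doses)) stop("doses and fa must be paired")
  ok <- is.finite(fa) & fa > 0 & fa < 1 & doses > 0
  if (any(!ok)) warning(sum(!ok), " boundary/invalid point(s) dropped from median-effect fit")
  if (sum(ok) < 2) stop("median-effect fit needs >= 2 usable dose points")
  x <- log(doses[ok])
  y <- log(fa[ok] / (1 - fa[ok]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  dm <- exp(-unname(stats::coef(fit)[1]) / m)
  r2 <- if (sum(ok) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(m = m, Dm = dm, r2 = r2, n = sum(ok)),
            class = "median_effect")
}

#' @export
print.median_effect <- function(x, ...) {
  cat(sprintf("<median_effect> m = %.4g, Dm = %.4g (r2 = %.3f, n = %d)\n",
              x$m, x$Dm, x$r2, x$n))
  invisible(x)
}

#' @export
coef.median_effect <- function(object, ...) {
  c(m = object$m, Dm = object$Dm)
}

#' Predicted affected fraction at a dose
#' @param object a `"median_effect"` fit.
#' @param doses doses at which to predict.
#' @param ... unused.
#' @return predicted `fa` values.
#' @export
predict.median_effect <- function(object, doses, ...) {
  r <- (doses / object$Dm)^object$m
  r / (1 + r)
}

# Dose of a single drug producing affected fraction fa under its fit.
effective_dose <- function(fit, fa) {
  if (fa <= 0 || fa >= 1) stop("fa must be strictly inside (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' `CI = d1/Dx1 + d2/Dx2`, where `Dx_i` is the dose of drug `i` alone that
#' would produce the combination's observed affected fraction under its
#' median-effect fit. CI < 1 indicates synergy, 1 additivity, > 1 antagonism.
#' The default is the mutually exclusive form; `exclusive = FALSE` adds the
#' mutually nonexclusive cross term `d1 d2 / (Dx1 Dx2)`.
#'
#' @param fit1,fit2 single-drug `"median_effect"` fits.
#' @param d1,d2 doses of the two drugs in the combination.
#' @param fa_combo affected fraction observed for the combination, in (0, 1).
#' @param exclusive use the mutually exclusive form (default TRUE).
#' @return the combination index.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa_combo, exclusive = TRUE) {
  dx1 <- effective_dose(fit1, fa_combo)
  dx2 <- effective_dose(fit2, fa_combo)
  ci <- d1 / dx1 + d2 / dx2
  if (!exclusive) ci <- ci + (d1 * d2) / (dx1 * dx2)
  ci
}
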