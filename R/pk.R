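# Mono-exponential kinetics and time-activity curve integration.

#' Fit a mono-exponential to a time-activity curve
#'
#' Fits `A(t) = a0 * exp(-lambda_bio * t)` to the decay-corrected mean curve.
#' The default is ordinary least squares on log-transformed means (the
#' classic linearization: reproducible, no starting-value sensitivity); a
#' nonlinear least-squares fit on the natural scale is available with
#' `method = "nls"` (Levenberg-Marquardt, started from the log-linear
#' estimate).
#'
#' Organs that are still accumulating over the sampled window (e.g. a tumor
#' rising to a late peak) yield a negative fitted `lambda_bio`; the raw value
#' is kept in `lambda_bio_raw` and the working value is clamped to 0, so the
#' closed-form integral never grows beyond physical decay. The hybrid
#' integrator ([cumulated_activity_hybrid()]) is the preferred scheme for
#' such curves.
#'
#' @param curve a [tac()].
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return object of class `monoexp_fit`: list with `a0`, `lambda_bio`
#'   (clamped at 0), `lambda_bio_raw`, `lambda_eff` (= clamped biological +
#'   physical), `rss_log` (residual sum of squares in the log domain),
#'   `method`, `organ`, `units`, `nuclide`.
#' @export
#' @examples
#' lu <- nuclide("lu177")
#' tt <- c(2, 24, 72, 168)
#' crv <- tac(tt, 10 * exp(-0.01 * tt), nuclide = lu)
#' fit_monoexp(crv)$lambda_bio # 0.01
fit_monoexp <- function(curve, method = c("loglinear", "nls")) {
  stopifnot(inherits(curve, "tac"))
  method <- match.arg(method)
  nuc <- attr(curve, "nuclide")
  keep <- is.finite(curve$value) & curve$value > 0
  if (any(!keep)) {
    warning(sprintf("%d non-positive point(s) excluded from the fit",
                    sum(!keep)), call. = FALSE)
  }
  t_h <- curve$time_h[keep]
  v <- curve$value[keep]
  if (length(v) < 2) {
    abort_mirdose("need at least 2 positive points to fit",
                  class = "mirdose_fit_error")
  }
  lmfit <- stats::lm(log(v) ~ t_h)
  a0 <- exp(unname(stats::coef(lmfit)[1]))
  lambda_raw <- -unname(stats::coef(lmfit)[2])
  rss_log <- sum(stats::resid(lmfit)^2)
  if (method == "nls") {
    nl <- try(minpack.lm::nlsLM(
      v ~ a0n * exp(-ln * t_h),
      start = list(a0n = a0, ln = lambda_raw),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(nl, "try-error")) {
      warning("nonlinear fit failed; falling back to log-linear estimates",
              call. = FALSE)
    } else {
      cf <- stats::coef(nl)
      a0 <- unname(cf["a0n"])
      lambda_raw <- unname(cf["ln"])
      rss_log <- sum((log(stats::predict(nl)) - log(v))^2)
    }
  }
  lambda_bio <- max(0, lambda_raw)
  structure(
    list(a0 = a0, lambda_bio = lambda_bio, lambda_bio_raw = lambda_raw,
         lambda_eff = lambda_bio + nuc$lambda_phys, rss_log = rss_log,
         method = method, organ = attr(curve, "organ"),
         units = attr(curve, "units"), nuclide = nuc),
    class = "monoexp_fit"
  )
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> %s (%s): a0 = %.4g %s, lambda_bio = %.4g /h%s, lambda_eff = %.4g /h\n",
    x$organ, x$method, x$a0, if (x$units == "pidg") "%ID/g" else "%ID",
    x$lambda_bio,
    if (x$lambda_bio_raw < 0)
      sprintf(" (raw %.4g clamped to 0)", x$lambda_bio_raw) else "",
    x$lambda_eff))
  invisible(x)
}

#' Cumulated activity from a mono-exponential fit (closed form)
#'
#' Integrates `a0 * exp(-lambda_bio t) * exp(-lambda_phys t)` from 0 to
#' infinity: `A~ = (a0 / 100) * injected / lambda_eff`. With `a0` in %ID/g
#' the result is MBq h per gram of tissue; with `a0` in organ-total %ID it is
#' MBq h in the organ. The residence time `tau = A~ / injected` is
#' independent of the injected activity.
#'
#' @param fit a [fit_monoexp()] result.
#' @param injected injected activity in MBq.
#' @return object of class `cumulated_activity`: list with `value` (MBq h),
#'   `residence_time_h`, `per_gram` flag, `scheme = "monoexp"`, `organ`.
#' @export
cumulated_activity_monoexp <- function(fit, injected) {
  stopifnot(inherits(fit, "monoexp_fit"))
  assert_positive(injected, "injected")
  if (fit$lambda_eff <= 0) {
    abort_mirdose("effective decay constant must be positive",
                  class = "mirdose_fit_error")
  }
  tau <- (fit$a0 / 100) / fit$lambda_eff
  structure(
    list(value = tau * injected, residence_time_h = tau,
         per_gram = fit$units == "pidg", scheme = "monoexp",
         organ = fit$organ),
    class = "cumulated_activity"
  )
}

#' Cumulated activity by trapezoid integration with an analytic tail (hybrid)
#'
#' A single falling exponential cannot represent an uptake-washout curve
#' (e.g. a tumor peaking days after injection). The hybrid scheme integrates
#' the decay-inclusive curve `value(t)/100 * exp(-lambda_phys t)` numerically
#' over the observed window, then adds an analytic tail from the last
#' timepoint:
#'
#' * `tail = "physical"` (default): no further biological clearance; the tail
#'   decays at the physical rate only (the conservative choice for an
#'   antibody still resident at the last sample).
#' * `tail = "fitted"`: terminal effective rate from the last two
#'   decay-corrected points, floored at the physical rate.
#'
#' At `t = 0` tissues are assumed empty (`t0 = "zero"`, tissues fill from
#' blood); for blood itself `t0 = "extrapolate"` back-extrapolates the first
#' two points to injection time.
#'
#' @param curve a [tac()] with decay-corrected values.
#' @param injected injected activity, MBq.
#' @param tail `"physical"` or `"fitted"`.
#' @param t0 `"zero"` or `"extrapolate"`.
#' @return a `cumulated_activity` (scheme `"hybrid"`).
#' @export
cumulated_activity_hybrid <- function(curve, injected,
                                      tail = c("physical", "fitted"),
                                      t0 = c("zero", "extrapolate")) {
  stopifnot(inherits(curve, "tac"))
  assert_positive(injected, "injected")
  if (!is.character(tail) || !all(tail %in% c("physical", "fitted"))) {
    abort_mirdose(sprintf("unknown tail scheme '%s'", tail[1]),
                  class = "mirdose_config_error")
  }
  tail <- match.arg(tail)
  t0 <- match.arg(t0)
  nuc <- attr(curve, "nuclide")
  if (!attr(curve, "decay_corrected")) {
    abort_mirdose("hybrid integration expects a decay-corrected curve")
  }
  t_h <- curve$time_h
  v <- pmax(curve$value, 0)

  # prepend the injection-time boundary point
  if (t_h[1] > 0) {
    v0 <- if (t0 == "zero" || length(v) < 2 || v[1] <= 0 || v[2] <= 0) {
      0
    } else {
      lam01 <- log(v[1] / v[2]) / (t_h[2] - t_h[1])
      v[1] * exp(lam01 * t_h[1])
    }
    t_h <- c(0, t_h)
    v <- c(v0, v)
  }
  f <- v / 100 * exp(-nuc$lambda_phys * t_h)
  area <- pracma::trapz(t_h, f)

  k <- length(v)
  f_last <- f[k]
  lambda_tail <- nuc$lambda_phys
  if (tail == "fitted" && k >= 2 && v[k] > 0 && v[k - 1] > 0) {
    lam_term <- log(v[k - 1] / v[k]) / (t_h[k] - t_h[k - 1])
    lambda_tail <- nuc$lambda_phys + max(0, lam_term)
  }
  tail_area <- if (f_last > 0) f_last / lambda_tail else 0

  tau <- area + tail_area
  structure(
    list(value = tau * injected, residence_time_h = tau,
         per_gram = attr(curve, "units") == "pidg", scheme = "hybrid",
         tail = tail, organ = attr(curve, "organ")),
    class = "cumulated_activity"
  )
}

#' @export
print.cumulated_activity <- function(x, ...) {
  cat(sprintf(
    "<cumulated_activity> %s [%s]: %.4g MBq.h%s, residence time %.4g h\n",
    x$organ, x$scheme, x$value, if (x$per_gram) "/g" else "",
    x$residence_time_h))
  invisible(x)
}

#' Fit and integrate every organ of a study
#'
#' Convenience wrapper running [fit_monoexp()] on each organ mean curve and
#' integrating with the scheme the fit calls for: mono-exponential closed
#' form when the fitted biological rate is non-negative, hybrid trapezoid
#' with the requested tail when the organ is still accumulating
#' (`scheme = "auto"`, the default pipeline behaviour; the scheme actually
#' used is recorded per organ).
#'
#' @param study a [biodist_study()].
#' @param scheme `"auto"`, `"monoexp"` or `"hybrid"`.
#' @param tail tail assumption for hybrid integration.
#' @param method fit method, see [fit_monoexp()].
#' @return data.frame with one row per organ: `organ`, `a0`, `lambda_bio`,
#'   `lambda_bio_raw`, `lambda_eff`, `residence_time_h` (per gram when input
#'   is %ID/g), `scheme`, `rss_log`.
#' @export
fit_study <- function(study, scheme = c("auto", "monoexp", "hybrid"),
                      tail = "physical", method = "loglinear") {
  stopifnot(inherits(study, "biodist_study"))
  scheme <- match.arg(scheme)
  organs <- sort(unique(study$samples$organ))
  injected <- if (is.finite(study$injected_mbq)) study$injected_mbq else 1
  rows <- lapply(organs, function(o) {
    crv <- organ_tac(study, o)
    if (all(crv$value <= 0)) {
      return(data.frame(organ = o, a0 = 0, lambda_bio = NA_real_,
                        lambda_bio_raw = NA_real_, lambda_eff = NA_real_,
                        residence_time_h = 0, scheme = "none",
                        rss_log = NA_real_))
    }
    fit <- fit_monoexp(crv, method = method)
    use_hybrid <- scheme == "hybrid" ||
      (scheme == "auto" && fit$lambda_bio_raw < 0)
    ca <- if (use_hybrid) {
      cumulated_activity_hybrid(crv, injected, tail = tail,
                                t0 = if (o == "blood") "extrapolate" else "zero")
    } else {
      cumulated_activity_monoexp(fit, injected)
    }
    data.frame(organ = o, a0 = fit$a0, lambda_bio = fit$lambda_bio,
               lambda_bio_raw = fit$lambda_bio_raw,
               lambda_eff = fit$lambda_eff,
               residence_time_h = ca$residence_time_h, scheme = ca$scheme,
               rss_log = fit$rss_log)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
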