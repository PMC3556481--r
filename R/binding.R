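# Antibody-binding analytics: KD from SPR rate constants, 1:1 Langmuir
# sensorgram simulation and global fitting, 4-parameter logistic ELISA fits.
#
# Units: rate constants in 1/(M s) and 1/s; analyte concentrations in molar
# internally; KD is REPORTED in nM (the SPR-table convention). ELISA
# concentrations in ng/ml, responses in optical density.

#' Equilibrium dissociation constant from SPR rate constants
#'
#' KD = kd / ka, reported in nM. Rounding happens only at display.
#'
#' @param ka association rate constant, 1/(M s); must be > 0
#' @param kd dissociation rate constant, 1/s; must be >= 0
#' @return KD in nM (vectorised)
#' @examples
#' kd_from_rates(7208, 0.003898)  # 540.8 nM
#' @export
kd_from_rates <- function(ka, kd) {
  if (!is.numeric(ka) || !is.numeric(kd) || any(is.na(ka)) || any(is.na(kd))) {
    stop_validation("`ka` and `kd` must be numeric")
  }
  if (any(ka <= 0)) stop_validation("`ka` must be positive")
  if (any(kd < 0)) stop_validation("`kd` must be non-negative")
  (kd / ka) * 1e9
}

# 1:1 Langmuir model response. Association: R(t) = Req (1 - exp(-(ka C + kd) t))
# with Req = Rmax C / (C + KD); dissociation: exponential decay at rate kd
# from the response reached at t_assoc. Continuous at t_assoc by construction.
langmuir_response <- function(time, conc, t_assoc, ka, kd, rmax) {
  KD <- kd / ka
  req <- ifelse(conc + KD > 0, rmax * conc / (conc + KD), 0)
  kobs <- ka * conc + kd
  r_ta <- req * (1 - exp(-kobs * t_assoc))
  ifelse(time <= t_assoc,
         req * (1 - exp(-kobs * time)),
         r_ta * exp(-kd * (time - t_assoc)))
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Noiseless model: association `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = Rmax C / (C + KD)`, followed from `t_assoc` by pure exponential
#' dissociation at rate `kd`. Gaussian noise of standard deviation
#' `noise_sd` (response units) is added reproducibly under `seed`; a seed is
#' required whenever `noise_sd > 0`, and the caller's RNG state is left
#' untouched.
#'
#' @param ka association rate constant, 1/(M s)
#' @param kd dissociation rate constant, 1/s
#' @param conc analyte concentration, M (>= 0)
#' @param rmax saturation response, RU
#' @param t_assoc association phase length, s
#' @param t_total total record length, s (`t_assoc < t_total`)
#' @param dt sampling interval, s
#' @param noise_sd Gaussian noise sd, RU
#' @param seed RNG seed (required when `noise_sd > 0`)
#' @return object of class `sensorgram`: time, response, conc, t_assoc, and
#'   the generating parameters
#' @export
simulate_sensorgram <- function(ka, kd, conc, rmax, t_assoc = 120,
                                t_total = 320, dt = 1, noise_sd = 0,
                                seed = NULL) {
  if (!is.numeric(ka) || ka <= 0 || !is.numeric(kd) || kd < 0) {
    stop_validation("`ka` must be > 0 and `kd` >= 0")
  }
  if (!is.numeric(conc) || length(conc) != 1L || is.na(conc) || conc < 0) {
    stop_validation("analyte concentration must be a single number >= 0")
  }
  if (rmax <= 0) stop_validation("`rmax` must be positive")
  if (t_assoc <= 0 || t_total <= t_assoc) {
    stop_validation("need 0 < t_assoc < t_total")
  }
  time <- seq(0, t_total, by = dt)
  response <- langmuir_response(time, conc, t_assoc, ka, kd, rmax)
  if (noise_sd > 0) {
    if (is.null(seed)) {
      stop_validation("`seed` is required when `noise_sd` > 0 (no hidden RNG state)")
    }
    response <- response +
      with_seed(seed, stats::rnorm(length(time), sd = noise_sd))
  }
  structure(
    list(time = time, response = response, conc = conc, rmax = rmax,
         t_assoc = t_assoc, t_total = t_total,
         truth = list(ka = ka, kd = kd, rmax = rmax),
         noise_sd = noise_sd),
    class = "sensorgram"
  )
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> C = %.3g M, %d points, t_assoc = %g s, peak %.2f RU\n",
              x$conc, length(x$time), x$t_assoc, max(x$response)))
  invisible(x)
}

# deterministic start-value policy for the global Langmuir fit:
# kd from a log-linear fit to the dissociation tail of the highest-response
# curve; Rmax from the largest observed response; ka from assuming KD is of
# the order of the median analyte concentration.
langmuir_start <- function(sensorgrams) {
  peak <- vapply(sensorgrams, function(s) max(s$response), numeric(1L))
  s <- sensorgrams[[which.max(peak)]]
  diss <- s$time > s$t_assoc
  tt <- s$time[diss]
  rr <- s$response[diss]
  ok <- rr > max(rr) * 0.05 & rr > 0
  kd0 <- 0.01
  if (sum(ok) >= 3L) {
    slope <- stats::coef(stats::lm(log(rr[ok]) ~ tt[ok]))[[2L]]
    if (is.finite(slope) && slope < 0) kd0 <- min(max(-slope, 1e-5), 10)
  }
  concs <- vapply(sensorgrams, function(s) s$conc, numeric(1L))
  ka0 <- kd0 / stats::median(concs)
  rmax0 <- 1.5 * max(peak)
  list(ka = ka0, kd = kd0, rmax = rmax0)
}

#' Globally fit the 1:1 Langmuir model to a set of sensorgrams
#'
#' Least-squares fit of shared (ka, kd, Rmax) across all curves, on the log
#' scale to enforce positivity, using Levenberg-Marquardt. Start values
#' follow a deterministic policy (see Details); given the same data the fit
#' is fully reproducible.
#'
#' Identifiability requires several analyte concentrations spanning roughly
#' 0.1-10x the true KD; a warning is issued when fewer than three distinct
#' concentrations are supplied.
#'
#' @details Starting values: kd from a log-linear regression on the
#' dissociation tail of the highest-response curve; Rmax = 1.5x the largest
#' observed response; ka = kd / median(concentration), i.e. KD assumed near
#' the middle of the concentration series.
#'
#' @param sensorgrams list of `sensorgram` objects at different analyte
#'   concentrations
#' @param start optional named list overriding the start values
#'   (`ka`, `kd`, `rmax`)
#' @return object of class `langmuir_fit` with elements `ka`, `kd`, `rmax`,
#'   `KD_nM`, standard errors (`ka_se`, `kd_se`, `rmax_se`, `KD_nM_se`),
#'   `rms` residual, and the underlying `nls` fit
#' @export
fit_langmuir <- function(sensorgrams, start = NULL) {
  if (!is.list(sensorgrams) || length(sensorgrams) == 0L ||
      !all(vapply(sensorgrams, inherits, logical(1L), what = "sensorgram"))) {
    stop_validation("`sensorgrams` must be a non-empty list of sensorgram objects")
  }
  concs <- vapply(sensorgrams, function(s) s$conc, numeric(1L))
  if (length(unique(concs)) < 3L) {
    warning("fewer than 3 distinct analyte concentrations: (ka, kd, Rmax) are weakly identifiable; interpret the fit with caution",
            call. = FALSE)
  }
  df <- do.call(rbind, lapply(sensorgrams, function(s) {
    data.frame(time = s$time, response = s$response, conc = s$conc,
               t_assoc = s$t_assoc)
  }))
  s0 <- langmuir_start(sensorgrams)
  if (!is.null(start)) s0[names(start)] <- start
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ langmuir_response(time, conc, t_assoc,
                                   exp(lka), exp(lkd), exp(lrmax)),
      data = df,
      start = list(lka = log(s0$ka), lkd = log(s0$kd), lrmax = log(s0$rmax)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop_computation(
        "Langmuir fit failed to converge: %s [start ka=%.4g, kd=%.4g, rmax=%.4g; %d curves at concentrations %s M]",
        conditionMessage(e), s0$ka, s0$kd, s0$rmax, length(sensorgrams),
        paste(signif(concs, 3), collapse = ", "))
    }
  )
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 3L, 3L, dimnames = list(names(co), names(co)))
  })
  est <- exp(co)
  se <- est * sqrt(diag(vc))  # delta method back from log scale
  kd_nm <- (est[["lkd"]] / est[["lka"]]) * 1e9
  v_logKD <- vc["lkd", "lkd"] + vc["lka", "lka"] - 2 * vc["lka", "lkd"]
  structure(
    list(ka = est[["lka"]], kd = est[["lkd"]], rmax = est[["lrmax"]],
         KD_nM = kd_nm,
         ka_se = se[["lka"]], kd_se = se[["lkd"]], rmax_se = se[["lrmax"]],
         KD_nM_se = kd_nm * sqrt(max(v_logKD, 0)),
         rms = sqrt(mean(stats::resid(fit)^2)),
         n_curves = length(sensorgrams), concentrations = concs,
         fit = fit),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf(
    "<langmuir_fit> ka = %.4g +/- %.2g 1/(M s)  kd = %.4g +/- %.2g 1/s\n  Rmax = %.4g RU  KD = %.4g +/- %.2g nM  (RMS %.3g RU, %d curves)\n",
    x$ka, x$ka_se, x$kd, x$kd_se, x$rmax, x$KD_nM, x$KD_nM_se, x$rms,
    x$n_curves))
  invisible(x)
}

#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Model: `y = bottom + (top - bottom) / (1 + (EC50 / x)^hill)`, the standard
#' ELISA parameterisation in which hill > 0 gives an increasing signal and
#' y(EC50) is exactly midway between bottom and top. Start values are
#' deterministic: bottom/top from the response extrema, EC50 from the
#' concentration nearest half-maximal response, hill = 1. After fitting the
#' parameters are normalised so bottom <= top (the curve is invariant under
#' swapping bottom/top and negating hill).
#'
#' @param concentration dose values (> 0), e.g. ng/ml; at least 5 points
#' @param response measured signal (e.g. optical density)
#' @return object of class `fourpl_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   standard errors, `ec50_se`, `r_squared`, and the underlying `nls` fit
#' @export
fit_4pl <- function(concentration, response) {
  if (!is.numeric(concentration) || !is.numeric(response) ||
      length(concentration) != length(response)) {
    stop_validation("`concentration` and `response` must be numeric vectors of equal length")
  }
  if (length(concentration) < 5L) {
    stop_validation("at least 5 concentration points are required for a 4PL fit")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop_validation("all concentrations must be positive and finite")
  }
  span <- diff(range(response))
  if (span <= .Machine$double.eps^0.5 * max(1, max(abs(response)))) {
    stop_computation("response data are flat; no dose-response to fit")
  }
  b0 <- min(response)
  t0 <- max(response)
  e0 <- concentration[which.min(abs(response - (b0 + t0) / 2))]
  df <- data.frame(x = concentration, y = response)
  tss <- sum((response - mean(response))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (ec50 / x)^hill),
      data = df,
      start = list(bottom = b0, top = t0, ec50 = e0, hill = 1),
      lower = c(-Inf, -Inf, .Machine$double.xmin, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # diagnose with a raw Levenberg-Marquardt pass so non-monotone or
    # noise-dominated data report their (poor) R^2 rather than a bare
    # convergence message
    raw <- try(minpack.lm::nls.lm(
      par = c(b0, t0, e0, 1),
      fn = function(p) response -
        (p[1] + (p[2] - p[1]) / (1 + (p[3] / concentration)^p[4])),
      lower = c(-Inf, -Inf, .Machine$double.xmin, -Inf)
    ), silent = TRUE)
    if (!inherits(raw, "try-error")) {
      r2d <- 1 - sum(raw$fvec^2) / tss
      if (is.finite(r2d) && r2d < 0.5) {
        stop_computation("4PL fit quality unacceptable (R^2 = %.3f); data may be non-monotone or dominated by noise",
                         r2d)
      }
    }
    stop_computation("4PL fit failed to converge: %s", conditionMessage(fit))
  }
  rss <- sum(stats::resid(fit)^2)
  r2 <- 1 - rss / tss
  if (!is.finite(r2) || r2 < 0.5) {
    stop_computation("4PL fit quality unacceptable (R^2 = %.3f); data may be non-monotone or dominated by noise",
                     r2)
  }
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 4L), names(co))
  })
  bottom <- co[["bottom"]]; top <- co[["top"]]; hill <- co[["hill"]]
  bottom_se <- se[["bottom"]]; top_se <- se[["top"]]
  if (bottom > top) {  # normalise direction
    tmp <- bottom; bottom <- top; top <- tmp
    tmp <- bottom_se; bottom_se <- top_se; top_se <- tmp
    hill <- -hill
  }
  structure(
    list(bottom = bottom, top = top, ec50 = co[["ec50"]], hill = hill,
         bottom_se = bottom_se, top_se = top_se,
         ec50_se = se[["ec50"]], hill_se = se[["hill"]],
         r_squared = r2, n = length(response), fit = fit),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> EC50 = %.4g +/- %.2g  hill = %.3g  bottom = %.3g  top = %.3g  (R^2 = %.4f, n = %d)\n",
    x$ec50, x$ec50_se, x$hill, x$bottom, x$top, x$r_squared, x$n))
  invisible(x)
}

#' Predict from a 4PL fit
#' @param object a `fourpl_fit`
#' @param newdata optional vector of concentrations
#' @param ... ignored
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$fit$m$getEnv()$x else newdata
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50 / x)^object$hill)
}

#' Fold difference between two EC50s
#'
#' `ec50_weak / ec50_strong`: how many fold weaker the second binder is.
#' The SPR/ELISA convention reports e.g. "25-fold higher affinity" as the
#' ratio of the weaker binder's EC50 to the stronger one's.
#'
#' @param ec50_strong EC50 of the tighter binder (> 0)
#' @param ec50_weak EC50 of the weaker binder (> 0)
#' @return the ratio
#' @examples
#' fold_difference(9.278, 247.3)  # 26.65
#' @export
fold_difference <- function(ec50_strong, ec50_weak) {
  if (!is.numeric(ec50_strong) || !is.numeric(ec50_weak) ||
      any(ec50_strong <= 0) || any(ec50_weak <= 0)) {
    stop_validation("EC50 values must be positive")
  }
  ec50_weak / ec50_strong
}

#' Simulate an ELISA dose-response curve from known 4PL parameters
#'
#' @param concentrations dose values (> 0)
#' @param bottom,top,ec50,hill generating 4PL parameters
#' @param noise_sd Gaussian noise sd in response units
#' @param seed RNG seed (required when `noise_sd > 0`)
#' @return data.frame with columns `concentration`, `response`
#' @export
simulate_elisa_curve <- function(concentrations, bottom = 0, top = 1,
                                 ec50 = 10, hill = 1, noise_sd = 0,
                                 seed = NULL) {
  if (any(concentrations <= 0)) {
    stop_validation("concentrations must be positive")
  }
  if (ec50 <= 0) stop_validation("`ec50` must be positive")
  y <- bottom + (top - bottom) / (1 + (ec50 / concentrations)^hill)
  if (noise_sd > 0) {
    if (is.null(seed)) {
      stop_validation("`seed` is required when `noise_sd` > 0")
    }
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  }
  data.frame(concentration = concentrations, response = y)
}

#' Count positive calls in an immunohistochemistry table
#'
#' Tallies '+' entries in a +/- scored staining column, e.g. MUC1 positivity
#' by a glycopeptide-specific antibody across patient samples. Accepts ASCII
#' '-' or the typographic minus for negatives; any other symbol is a parse
#' error. An empty table counts 0.
#'
#' @param table data.frame, e.g. from [read_ihc_table()]
#' @param column name of the scored column (default `"MUC1_16A"`)
#' @return integer count of positive rows
#' @export
summarize_positivity <- function(table = read_ihc_table(),
                                 column = "MUC1_16A") {
  if (!is.data.frame(table)) stop_validation("`table` must be a data.frame")
  if (!column %in% names(table)) {
    stop_validation("column '%s' not found (columns: %s)",
                    column, paste(names(table), collapse = ", "))
  }
  vals <- trimws(as.character(table[[column]]))
  if (length(vals) == 0L) return(0L)
  neg <- c("-", "−", "–")
  bad <- setdiff(unique(vals), c("+", neg))
  if (length(bad) > 0L) {
    stop_validation("unrecognised score symbol '%s' in column '%s' (expected '+' or '-')",
                    bad[1L], column)
  }
  sum(vals == "+")
}
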