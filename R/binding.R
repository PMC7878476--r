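#' Fraction of tracer bound, one-site model with ligand depletion
#'
#' Exact solution of the one-site mass balance
#' \eqn{J + L \rightleftharpoons JL} for tracer at total concentration
#' `tracer_conc` titrated with ligand at `ligand_conc`: the complex
#' concentration is the root in \[0, min(T, L)\] of the quadratic
#' \eqn{JL^2 - (T + L + K_d)JL + TL = 0}. At vanishing tracer this reduces
#' to the familiar hyperbola \eqn{L/(L + K_d)}; at tracer comparable to
#' \eqn{K_d} (the depletion regime) the hyperbola is biased and the exact
#' root must be used.
#'
#' @param tracer_conc Total tracer concentration (uM, >= 0).
#' @param ligand_conc Total ligand concentration(s) (uM, >= 0), vectorised.
#' @param kd Dissociation constant (uM, > 0).
#' @return Fraction bound in \[0, 1\].
#' @export
#' @examples
#' fraction_bound_one_site(0, 4.4, 4.4) # 0.5 at L = Kd, no depletion
fraction_bound_one_site <- function(tracer_conc, ligand_conc, kd) {
  stopifnot(tracer_conc >= 0, all(ligand_conc >= 0), kd > 0)
  if (tracer_conc == 0) {
    return(ligand_conc / (ligand_conc + kd))
  }
  s <- tracer_conc + ligand_conc + kd
  complex <- (s - sqrt(s^2 - 4 * tracer_conc * ligand_conc)) / 2
  pmin(pmax(complex / tracer_conc, 0), 1)
}

#' Two-competitor equilibrium for a shared tracer
#'
#' Solves the coupled mass balances for a tracer J binding competitor 1
#' (C, dissociation constant `kd1`) and competitor 2 (H, `kd2`)
#' simultaneously:
#' \deqn{J_f = J_t / (1 + C_f/K_1 + H_f/K_2)}
#' \deqn{C_f = C_t / (1 + J_f/K_1), \quad H_f = H_t / (1 + J_f/K_2)}
#' by damped fixed-point iteration to a mass-balance residual below `tol`.
#' This is the model behind the FP competition experiment in which tracer
#' preincubated with one partner is titrated with the other.
#'
#' @param tracer_conc,comp1_conc,comp2_conc Total concentrations (uM).
#' @param kd1,kd2 Dissociation constants (uM, > 0).
#' @param tol Convergence tolerance on the relative mass-balance residual.
#' @param max_iter Iteration cap.
#' @return Named list: tracer fractions `free`, `bound1`, `bound2`
#'   (summing to 1) and free concentrations.
#' @export
competitive_equilibrium <- function(tracer_conc, comp1_conc, comp2_conc,
                                    kd1, kd2, tol = 1e-12,
                                    max_iter = 10000) {
  stopifnot(tracer_conc >= 0, comp1_conc >= 0, comp2_conc >= 0,
            kd1 > 0, kd2 > 0)
  if (tracer_conc == 0) {
    return(list(free = 1, bound1 = 0, bound2 = 0,
                tracer_free = 0, comp1_free = comp1_conc,
                comp2_free = comp2_conc))
  }
  jf <- tracer_conc
  cf <- comp1_conc
  hf <- comp2_conc
  damp <- 0.5
  for (it in seq_len(max_iter)) {
    jf_new <- tracer_conc / (1 + cf / kd1 + hf / kd2)
    cf_new <- comp1_conc / (1 + jf_new / kd1)
    hf_new <- comp2_conc / (1 + jf_new / kd2)
    jf <- damp * jf_new + (1 - damp) * jf
    cf <- damp * cf_new + (1 - damp) * cf
    hf <- damp * hf_new + (1 - damp) * hf
    b1 <- jf * cf / kd1
    b2 <- jf * hf / kd2
    res <- abs(jf + b1 + b2 - tracer_conc) / tracer_conc +
      (if (comp1_conc > 0) abs(cf + b1 - comp1_conc) / comp1_conc else 0) +
      (if (comp2_conc > 0) abs(hf + b2 - comp2_conc) / comp2_conc else 0)
    if (res < tol) {
      return(list(
        free = jf / tracer_conc, bound1 = b1 / tracer_conc,
        bound2 = b2 / tracer_conc,
        tracer_free = jf, comp1_free = cf, comp2_free = hf
      ))
    }
  }
  stop("competitive equilibrium did not converge; residual = ",
       format(res, digits = 3))
}

#' Polarization signal from bound-state fractions
#'
#' Linear mixture of plateau polarizations weighted by state fractions:
#' free tracer tumbles fast (low mP); each complex plateaus at its own mP.
#'
#' @param fractions Named list/vector with `free`, `bound1`, `bound2`
#'   (missing entries treated as 0).
#' @param plateaus Named numeric with `free`, `bound1`, `bound2` (mP).
#' @return Polarization in mP.
#' @export
fp_signal <- function(fractions, plateaus) {
  states <- c("free", "bound1", "bound2")
  f <- vapply(states, function(s) {
    v <- fractions[[s]]
    if (is.null(v)) 0 else v
  }, numeric(1))
  p <- vapply(states, function(s) {
    v <- plateaus[[s]]
    if (is.null(v) || is.na(v)) 0 else v
  }, numeric(1))
  sum(f * p)
}

one_site_mp <- function(conc, tracer, kd, fp_min, fp_max) {
  fb <- fraction_bound_one_site(tracer, conc, kd)
  fp_min + (fp_max - fp_min) * fb
}

#' Fit a one-site binding model to an FP titration
#'
#' Nonlinear least squares over (Kd, FP_min, FP_max) with the exact
#' ligand-depletion one-site model, Levenberg-Marquardt steps and
#' multistart initial guesses for Kd (log-spaced around the model-free
#' half-signal concentration). Standard errors come from the covariance of
#' the converged fit.
#'
#' @param curve Tibble with `conc_uM`, `mP` (and optionally `replicate`).
#' @param tracer_conc Total tracer concentration in uM (default taken from
#'   a `tracer_conc` attribute on `curve`, else 0.2).
#' @param weights Optional observation weights.
#' @return Object of class `fp_fit` with [generics::tidy()] /
#'   [generics::glance()] methods. Non-convergence is reported via the
#'   `converged` flag rather than an error.
#' @export
fit_one_site <- function(curve, tracer_conc = NULL, weights = NULL) {
  stopifnot(all(c("conc_uM", "mP") %in% names(curve)))
  if (length(unique(curve$conc_uM)) < 5) {
    stop("need >= 5 distinct concentrations to fit")
  }
  tracer_conc <- tracer_conc %||% attr(curve, "tracer_conc") %||% 0.2
  lo <- min(curve$mP); hi <- max(curve$mP)
  half <- (lo + hi) / 2
  above <- curve$conc_uM[curve$mP >= half & curve$conc_uM > 0]
  ec50_guess <- if (length(above)) min(above) else
    stats::median(curve$conc_uM[curve$conc_uM > 0])
  starts <- unique(pmax(ec50_guess * c(1, 0.1, 10, 0.01, 100), 1e-4))
  best <- NULL
  for (kd0 in starts) {
    args <- list(
      mP ~ one_site_mp(conc_uM, tracer_conc, kd, fp_min, fp_max),
      data = curve,
      start = list(kd = kd0, fp_min = lo, fp_max = hi),
      lower = c(kd = 1e-6, fp_min = -Inf, fp_max = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(
      do.call(minpack.lm::nlsLM, args),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(converged = FALSE, model = "one_site", curve = curve,
           tracer_conc = tracer_conc, estimates = NULL),
      class = "fp_fit"
    ))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(est)))
  structure(
    list(
      converged = TRUE, model = "one_site", curve = curve,
      tracer_conc = tracer_conc, fit = fit,
      estimates = tibble::tibble(
        term = names(est), estimate = unname(est), std_error = unname(se)
      ),
      rss = best$rss
    ),
    class = "fp_fit"
  )
}

competition_mp <- function(conc2, tracer, comp1, kd1, kd2, fp_min,
                           fp_b1, fp_b2) {
  vapply(conc2, function(h) {
    eq <- competitive_equilibrium(tracer, comp1, h, kd1, kd2)
    fp_signal(eq, list(free = fp_min, bound1 = fp_b1, bound2 = fp_b2))
  }, numeric(1))
}

#' Fit a competition FP titration for the second dissociation constant
#'
#' The tracer is preincubated with competitor 1 at a fixed concentration
#' (known `kd1`) and titrated with competitor 2; `kd2` and the three state
#' plateaus are fitted through the full two-competitor equilibrium.
#' Alongside the mechanistic fit, the model-free apparent EC50 of the
#' titration is reported together with the Cheng-Prusoff prediction
#' \eqn{K_2 (1 + C/K_1)} for the non-depleting regime.
#'
#' @param curve Tibble with `conc_uM` (competitor 2), `mP`.
#' @param kd1 Known dissociation constant of the preincubated competitor
#'   (uM).
#' @param comp1_conc Fixed competitor-1 concentration (uM, default 3.125).
#' @param tracer_conc Tracer concentration (uM, default 0.2).
#' @param fp_free Optional known free-tracer polarization (mP). A
#'   competition titration never visits the fully free state (the tracer is
#'   preincubated with competitor 1), so the free plateau is poorly
#'   identified from the curve alone; supplying it from the companion
#'   direct titration sharpens the Kd2 estimate considerably.
#' @return `fp_fit` object (model `"competitive"`) with extra fields
#'   `apparent_ec50`, `cheng_prusoff_ec50`.
#' @export
fit_competition <- function(curve, kd1, comp1_conc = 3.125,
                            tracer_conc = NULL, fp_free = NULL) {
  stopifnot(all(c("conc_uM", "mP") %in% names(curve)))
  tracer_conc <- tracer_conc %||% attr(curve, "tracer_conc") %||% 0.2
  if (comp1_conc == 0) {
    out <- fit_one_site(curve, tracer_conc)
    out$model <- "competitive"
    out$comp1_conc <- 0
    return(out)
  }
  lo <- min(curve$mP); hi <- max(curve$mP)
  starts <- pmax(kd1 * c(0.1, 1, 10), 1e-4)
  best <- NULL
  for (kd0 in starts) {
    if (is.null(fp_free)) {
      args <- list(
        mP ~ competition_mp(conc_uM, tracer_conc, comp1_conc, kd1, kd2,
                            fp_min, fp_b1, fp_b2),
        data = curve,
        start = list(kd2 = kd0, fp_min = lo, fp_b1 = (lo + hi) / 2,
                     fp_b2 = hi),
        lower = c(kd2 = 1e-6, fp_min = -Inf, fp_b1 = -Inf, fp_b2 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      args <- list(
        mP ~ competition_mp(conc_uM, tracer_conc, comp1_conc, kd1, kd2,
                            fp_free, fp_b1, fp_b2),
        data = curve,
        start = list(kd2 = kd0, fp_b1 = (lo + hi) / 2, fp_b2 = hi),
        lower = c(kd2 = 1e-6, fp_b1 = -Inf, fp_b2 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(converged = FALSE, model = "competitive", curve = curve,
           tracer_conc = tracer_conc, comp1_conc = comp1_conc,
           estimates = NULL),
      class = "fp_fit"
    ))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(est)))
  kd2_hat <- est[["kd2"]]
  fp_min_hat <- if (is.null(fp_free)) est[["fp_min"]] else fp_free
  app <- apparent_ec50(function(h) {
    competition_mp(h, tracer_conc, comp1_conc, kd1, kd2_hat,
                   fp_min_hat, est[["fp_b1"]], est[["fp_b2"]])
  }, max(curve$conc_uM))
  structure(
    list(
      converged = TRUE, model = "competitive", curve = curve,
      tracer_conc = tracer_conc, comp1_conc = comp1_conc, fit = fit,
      estimates = tibble::tibble(
        term = names(est), estimate = unname(est), std_error = unname(se)
      ),
      rss = best$rss,
      apparent_ec50 = app,
      cheng_prusoff_ec50 = kd2_hat * (1 + comp1_conc / kd1)
    ),
    class = "fp_fit"
  )
}

# concentration at the half-way signal of a monotone titration model
apparent_ec50 <- function(signal_fn, top) {
  s0 <- signal_fn(0)
  s_inf <- signal_fn(top * 1e4)
  half <- (s0 + s_inf) / 2
  stats::uniroot(function(h) signal_fn(h) - half,
                 lower = 1e-9, upper = top * 1e4, tol = 1e-10)$root
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit> model: ", x$model,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' @rdname fit_one_site
#' @param x An `fp_fit` object.
#' @param ... Unused.
#' @method tidy fp_fit
#' @export
tidy.fp_fit <- function(x, ...) {
  if (is.null(x$estimates)) return(tibble::tibble())
  x$estimates
}

#' @rdname fit_one_site
#' @method glance fp_fit
#' @export
glance.fp_fit <- function(x, ...) {
  kd_term <- if (x$model == "one_site") "kd" else "kd2"
  kd <- if (x$converged) {
    x$estimates$estimate[x$estimates$term == kd_term]
  } else NA_real_
  tibble::tibble(
    model = x$model,
    kd_uM = kd,
    converged = x$converged,
    rss = x$rss %||% NA_real_,
    n_obs = nrow(x$curve)
  )
}

#' @rdname fit_one_site
#' @param object An `fp_fit` object.
#' @method autoplot fp_fit
#' @export
autoplot.fp_fit <- function(object, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$conc_uM,
                                           y = .data$mP)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "titrant (uM, log scale)", y = "polarization (mP)",
                  title = paste("FP titration,", object$model, "fit")) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- exp(seq(log(max(min(curve$conc_uM[curve$conc_uM > 0]), 1e-4)),
                    log(max(curve$conc_uM)), length.out = 100))
    pred <- stats::predict(object$fit,
                           newdata = data.frame(conc_uM = grid))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(conc_uM = grid, mP = pred),
      colour = "firebrick"
    )
  }
  p
}
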