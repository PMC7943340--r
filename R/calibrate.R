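# Moment calibration for the synthetic cohort generator.
#
# Behavior scores are bounded: weekly PA minutes and snack kilocalories are
# nonnegative, ProMAS sums live on 0..18 (oral) and 0..9 (insulin).  The
# generator draws a latent normal and pushes it through the score transform
# (censoring at 0, or rounding + clamping to the scale range).  Published
# marginals describe the *observed* scores, and treatment effects are defined
# in pooled-SD units of the *observed* change scores, so the latent
# parameters are calibrated numerically: a fixed common-random-number panel
# of standard normal draws makes every objective deterministic, then
# Nelder-Mead (baseline moments) and uniroot (change SD, effect shift) solve
# the moment equations.

score_transform <- function(behavior) {
  switch(behavior,
    pa      = function(x) pmax(0, x),
    snack   = function(x) pmax(0, x),
    oha     = function(x) pmin(18, pmax(0, round(x))),
    insulin = function(x) pmin(9, pmax(0, round(x))),
    stop("unknown behavior: ", behavior)
  )
}

cal_panel <- function(n = 100000L) {
  # fixed internal draws, independent of user seeds
  with_preserved_seed({
    set.seed(987654321L)
    list(z = rnorm(n),        # baseline latent
         w = rnorm(n),        # change latent (nurse + residual, standardized)
         z2 = rnorm(n))
  })
}

# latent (mu, sigma) such that g(mu + sigma*Z) has the target mean and SD
calibrate_baseline <- function(target_mean, target_sd, g, panel) {
  z <- panel$z
  obj <- function(par) {
    y <- g(par[1] + exp(par[2]) * z)
    (mean(y) - target_mean)^2 / max(target_mean, 1)^2 +
      (stats::sd(y) - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# latent change scale c such that SD(g(X + c*W) - g(X)) hits the target
# change SD, where W has variance (1 + tau2) from the shared nurse intercept
calibrate_change_scale <- function(base, target_change_sd, g, tau2, panel) {
  x <- base[["mu"]] + base[["sigma"]] * panel$z
  w <- panel$w * sqrt(1 + tau2)
  f <- function(cc) stats::sd(g(x + cc * w) - g(x)) - target_change_sd
  stats::uniroot(f, c(1e-6, 6 * target_change_sd), extendInt = "upX",
                 tol = 1e-8)$root
}

# latent mean shift s such that the oriented observed change in a shifted arm
# exceeds an unshifted arm by `target_d` pooled change-SDs
calibrate_effect_shift <- function(base, cscale, orient, target_d, g, tau2,
                                   panel) {
  if (target_d == 0) return(0)
  x <- base[["mu"]] + base[["sigma"]] * panel$z
  w <- cscale * sqrt(1 + tau2) * panel$w
  d_ctl <- orient * (g(x + w) - g(x))
  f <- function(s) {
    d_trt <- orient * (g(x + orient * s + w) - g(x))
    sp <- sqrt((stats::var(d_trt) + stats::var(d_ctl)) / 2)
    (mean(d_trt) - mean(d_ctl)) / sp - target_d
  }
  lim <- 6 * cscale * (1 + tau2)
  if (target_d > 0)
    stats::uniroot(f, c(0, lim), extendInt = "upX", tol = 1e-8)$root
  else
    stats::uniroot(f, c(-lim, 0), extendInt = "upX", tol = 1e-8)$root
}

# Linearized loading of the shared latent on the observed change:
# slope of the projection of the observed change on the latent change draw.
# The censoring/clamping transform passes only part of the shared nurse
# intercept through to the observed score, so the intercept variance must
# be inflated accordingly to hit the target composite ICC.
change_slope <- function(base, cscale, g, tau2, panel) {
  x <- base[["mu"]] + base[["sigma"]] * panel$z
  w <- panel$w * sqrt(1 + tau2)
  dobs <- g(x + cscale * w) - g(x)
  stats::cov(dobs, w) / stats::var(w)
}

# Nurse-intercept variance on the standardized latent change scale that
# reproduces the target composite ICC, given the per-behavior standardized
# loadings lam (slope / pooled change SD) and the applicability mixture.
solve_tau2 <- function(icc, lam, applicability) {
  if (icc == 0) return(0)
  classes <- list(list(p = applicability[["oha_only"]],
                       b = c("pa", "snack", "oha")),
                  list(p = applicability[["insulin_only"]],
                       b = c("pa", "snack", "insulin")),
                  list(p = applicability[["both"]], b = BEHAVIORS))
  num_k <- num_q <- num_w <- 0
  for (cl in classes) {
    l <- lam[cl$b]
    num_k <- num_k + cl$p * length(l)
    num_q <- num_q + cl$p * sum(l)^2
    num_w <- num_w + cl$p * (sum(l)^2 - sum(l^2))
  }
  tau2 <- icc * num_k / (num_q - icc * num_w)
  if (!is.finite(tau2) || tau2 < 0)
    stop_param("icc", "not attainable with these score distributions")
  tau2
}

#' Calibrate the latent generator for a parameter set
#'
#' Solves, once per [cohort_params()] object, for the latent normal
#' parameters that make the generated observed scores match the requested
#' baseline means/SDs, change-score SDs, composite ICC and per-behavior
#' standardized treatment effects after censoring/clamping.
#' [generate_cohort()] calls this automatically; pre-computing it is useful
#' when many cohorts are generated from one parameter set (e.g. in
#' [simulate_power()]).
#'
#' @param params a [cohort_params()] object.
#' @param n_panel size of the internal common-random-number panel.
#' @return an object of class `cohort_calibration`: per behavior the latent
#'   baseline `mu`/`sigma`, latent change scale, standardized loading
#'   `lambda`, latent effect shift; plus the calibrated nurse-intercept
#'   variance `tau2` on the standardized latent change scale.
#' @export
calibrate_generator <- function(params, n_panel = 100000L) {
  stopifnot(inherits(params, "cohort_params"))
  panel <- cal_panel(n_panel)
  tau2 <- params$tau2   # analytic start

  bases <- lapply(BEHAVIORS, function(b) {
    bl <- params$behavior_baselines[[b]]
    calibrate_baseline(bl[["mean"]], bl[["sd"]], score_transform(b), panel)
  })
  names(bases) <- BEHAVIORS

  # the censoring attenuates the shared intercept; two fixed-point rounds
  # on tau2 are ample (the loadings depend on tau2 only through a
  # sqrt(1 + tau2) factor in the change scale)
  for (round in 1:2) {
    cs <- lam <- numeric(4); names(cs) <- names(lam) <- BEHAVIORS
    for (b in BEHAVIORS) {
      g <- score_transform(b)
      cs[b] <- calibrate_change_scale(bases[[b]], params$change_sds[[b]], g,
                                      tau2, panel)
      lam[b] <- change_slope(bases[[b]], cs[b], g, tau2, panel) /
        params$change_sds[[b]]
    }
    tau2 <- solve_tau2(params$icc, lam, params$applicability)
  }

  out <- lapply(BEHAVIORS, function(b) {
    g <- score_transform(b)
    sh <- calibrate_effect_shift(bases[[b]], cs[[b]], ORIENT[[b]],
                                 params$true_effects[[b]], g, tau2, panel)
    list(mu = bases[[b]][["mu"]], sigma = bases[[b]][["sigma"]],
         change_scale = cs[[b]], lambda = lam[[b]], effect_shift = sh)
  })
  names(out) <- BEHAVIORS
  structure(list(behaviors = out, tau2 = tau2, n_panel = n_panel),
            class = "cohort_calibration")
}

# Recompute only the per-behavior effect shifts for new true_effects,
# reusing a calibration's baseline/change solutions.
recalibrate_effects <- function(calibration, params) {
  panel <- cal_panel(calibration$n_panel)
  for (b in BEHAVIORS) {
    cb <- calibration$behaviors[[b]]
    base <- c(mu = cb$mu, sigma = cb$sigma)
    calibration$behaviors[[b]]$effect_shift <-
      calibrate_effect_shift(base, cb$change_scale, ORIENT[[b]],
                             params$true_effects[[b]], score_transform(b),
                             calibration$tau2, panel)
  }
  calibration
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat("Latent generator calibration (tau2 =", signif(x$tau2, 4), ")\n")
  for (b in names(x$behaviors)) {
    cb <- x$behaviors[[b]]
    cat(sprintf("  %-8s mu=%.2f sigma=%.2f change_scale=%.2f shift=%.3f\n",
                b, cb$mu, cb$sigma, cb$change_scale, cb$effect_shift))
  }
  invisible(x)
}
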