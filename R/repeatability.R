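## Mixed-model repeatability (intraclass correlation) with
## parametric-bootstrap confidence intervals and Monte Carlo permutation
## p-values, plus permutation inference for fixed-effect slopes.

.icc_from_fit <- function(fit, group) {
  v <- fit$varcomp
  if (fit$spec$family == "gaussian") {
    unname(v[group] / (v[group] + v["residual"]))
  } else {
    ## latent-scale repeatability for the logit link
    unname(v[group] / (v[group] + pi^2 / 3))
  }
}

#' Mixed-model repeatability with permutation p-value and bootstrap CI
#'
#' Repeatability (intraclass correlation) of a variable measured repeatedly
#' per individual, after adjusting for the fixed terms in `spec`:
#' for Gaussian responses `R = s2_ind / (s2_ind + s2_res)`; for
#' binomial-logit responses the latent-scale version
#' `R = s2_ind / (s2_ind + pi^2/3)`. The p-value comes from a Monte Carlo
#' permutation test that shuffles the individual-identity labels across
#' observations (destroying grouping while preserving the response and
#' fixed design), refits, and uses `p = (#{R_perm >= R_obs} + 1)/(n_perm + 1)`.
#' The 95% CI comes from a parametric bootstrap: responses are simulated
#' from the fitted model and the estimator re-applied.
#'
#' @param spec A [model_spec()]; `spec$random[1]` is the individual
#'   identity whose variance defines R.
#' @param data Data frame with repeated measures.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param n_boot Number of parametric-bootstrap refits for the CI; 0 skips
#'   the CI.
#' @param seed Optional RNG seed.
#' @return A `repeatability_result`: `R`, `ci95`, `p_perm`,
#'   `n_permutations`, `scale` (`"original"` or `"latent"`), `fit`.
#' @export
repeatability <- function(spec, data, n_perm = 10000, n_boot = 1000,
                          seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  group <- spec$random[1]
  tab <- table(data[[group]])
  if (all(tab < 2L))
    stop("repeatability undefined: every individual observed only once")
  fit <- .fit_any(spec, data)
  R_obs <- .icc_from_fit(fit, group)

  refit_R <- function(d) {
    f <- tryCatch(suppressWarnings(.fit_any(spec, d)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else .icc_from_fit(f, group)
  }

  R_perm <- numeric(0)
  if (n_perm > 0) {
    R_perm <- vapply(seq_len(n_perm), function(i) {
      d <- data
      d[[group]] <- sample(d[[group]])
      refit_R(d)
    }, numeric(1))
    R_perm <- R_perm[is.finite(R_perm)]
  }
  p_perm <- if (length(R_perm))
    (sum(R_perm >= R_obs) + 1) / (length(R_perm) + 1) else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ## bootstrap responses are simulated on the model (transformed) scale,
    ## so the refit must not re-apply the transform; R is scale-invariant
    spec_boot <- spec
    spec_boot$transform <- "none"
    refit_boot <- function(d) {
      f <- tryCatch(suppressWarnings(.fit_any(spec_boot, d)),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else .icc_from_fit(f, group)
    }
    R_boot <- vapply(seq_len(n_boot), function(i) {
      d <- data
      d[[spec$response]] <- .simulate_response(fit, data)
      refit_boot(d)
    }, numeric(1))
    R_boot <- R_boot[is.finite(R_boot)]
    ci <- unname(stats::quantile(R_boot, c(0.025, 0.975)))
  }
  structure(list(R = R_obs, ci95 = ci, p_perm = p_perm,
                 n_permutations = length(R_perm),
                 scale = if (spec$family == "gaussian") "original" else "latent",
                 fit = fit),
            class = "repeatability_result")
}

## Simulate a new response from a fitted mixed model (new random effects
## and residuals), on the same scale the model was fitted on.
.simulate_response <- function(fit, data) {
  d <- fit$design
  Xb <- as.numeric(d$X %*% fit$beta)
  eta <- Xb
  for (i in seq_along(fit$spec$random)) {
    g <- d$groups[[i]]
    s2 <- fit$varcomp[fit$spec$random[i]]
    eta <- eta + stats::rnorm(nlevels(g), 0, sqrt(s2))[as.integer(g)]
  }
  if (fit$spec$family == "gaussian")
    eta + stats::rnorm(length(eta), 0, sqrt(fit$varcomp["residual"]))
  else
    stats::rbinom(length(eta), 1, stats::plogis(eta))
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> R = %.3f (95%% CI %.3f-%.3f), p_perm = %s (%d perms, %s scale)\n",
              x$R, x$ci95[1], x$ci95[2],
              format.pval(x$p_perm, digits = 3), x$n_permutations, x$scale))
  invisible(x)
}

#' Permutation p-value for a fixed-effect slope
#'
#' Two-sided Monte Carlo permutation test for one fixed term of a mixed
#' model: the response vector is permuted across rows (the design held
#' fixed), the model refitted, and the absolute slope compared with the
#' observed one; `p = (#{|b_perm| >= |b_obs|} + 1)/(n_perm + 1)`.
#'
#' @param spec A [model_spec()] containing `term` among its fixed effects.
#' @param data Data frame.
#' @param term Name of the fixed term to test.
#' @param n_perm Number of permutations; below 100 a warning is issued.
#' @param seed Optional RNG seed.
#' @return List with `p`, `beta_obs`, `n_perm`, and the observed fit.
#' @export
permutation_pvalue_fixed_effect <- function(spec, data, term, n_perm = 1000,
                                            seed = NULL) {
  if (!term %in% spec$fixed) stop("`term` is not among the model's fixed effects")
  if (n_perm < 100) warning("fewer than 100 permutations; p-value is coarse")
  if (!is.null(seed)) set.seed(seed)
  fit <- .fit_any(spec, data)
  b_obs <- fit$beta[term]
  b_perm <- vapply(seq_len(n_perm), function(i) {
    d <- data
    d[[spec$response]] <- sample(d[[spec$response]])
    f <- tryCatch(suppressWarnings(.fit_any(spec, d)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$beta[term]
  }, numeric(1))
  b_perm <- b_perm[is.finite(b_perm)]
  list(p = (sum(abs(b_perm) >= abs(b_obs)) + 1) / (length(b_perm) + 1),
       beta_obs = unname(b_obs), n_perm = length(b_perm), fit = fit)
}

#' The nine behaviour-to-metabolic-rate association models
#'
#' Fits each of the three behaviours (probability to enter the arena,
#' distance travelled, % time exploration) as a single predictor of each of
#' the three metabolic responses (RMR, maximum and integral stress
#' response) in separate linear mixed models with an individual random
#' intercept -- nine models in total, deliberately without any further
#' covariates so the marginal (potentially confounded) association is
#' estimated. Stress responses are variance-stabilised (square-root /
#' log after positivising offsets) before scaling; all continuous
#' variables are standardized so slopes are comparable effect sizes.
#'
#' @param data Merged session table with behaviour and metabolic columns.
#' @param behaviours,responses Column names (defaults match the generator).
#' @param n_perm Permutations for each slope's p-value; `0` for the (much
#'   faster) normal-approximation p.
#' @param offsets `"paper"` for the fixed offsets 9.76 (max stress) and
#'   25.07 (integral stress), or `"data"` for `|min| + 0.01`.
#' @param seed Optional RNG seed.
#' @return Data frame with 9 rows: `response`, `behaviour`, `beta`, `se`,
#'   `p`, `n_perm`.
#' @export
association_models <- function(data,
                               behaviours = c("entry", "distance", "exploration"),
                               responses = c("rmr", "stress_max", "stress_integral"),
                               n_perm = 1000, offsets = c("paper", "data"),
                               seed = NULL) {
  offsets <- match.arg(offsets)
  if (!is.null(seed)) set.seed(seed)
  off <- function(resp) {
    if (offsets == "data") return(NULL)
    switch(resp, stress_max = 9.76, stress_integral = 25.07, NULL)
  }
  tr <- function(resp) switch(resp, stress_max = "sqrt_offset",
                              stress_integral = "log_offset", "none")
  out <- expand.grid(response = responses, behaviour = behaviours,
                     stringsAsFactors = FALSE)
  out$beta <- out$se <- out$p <- NA_real_
  out$n_perm <- 0L
  for (i in seq_len(nrow(out))) {
    spec <- model_spec(out$response[i], fixed = out$behaviour[i],
                       random = "id", family = "gaussian",
                       transform = tr(out$response[i]),
                       offset = off(out$response[i]))
    if (n_perm > 0) {
      pt <- permutation_pvalue_fixed_effect(spec, data, out$behaviour[i],
                                            n_perm = n_perm)
      out$beta[i] <- pt$beta_obs
      out$se[i] <- unname(pt$fit$se[out$behaviour[i]])
      out$p[i] <- pt$p
      out$n_perm[i] <- pt$n_perm
    } else {
      fit <- fit_lmm(spec, data)
      out$beta[i] <- unname(fit$beta[out$behaviour[i]])
      out$se[i] <- unname(fit$se[out$behaviour[i]])
      out$p[i] <- unname(fit$p[out$behaviour[i]])
    }
  }
  out[c("response", "behaviour", "beta", "se", "p", "n_perm")]
}
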