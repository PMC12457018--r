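## Random-intercept mixed models. Gaussian models with a single random
## intercept are fitted by direct optimisation of the profiled REML
## criterion over the variance ratio (fast enough for Monte Carlo
## permutation at 10^4 refits); models with two crossed intercepts and all
## binomial-logit models go through lme4 behind the same interface.

#' Specify a random-intercept mixed model
#'
#' @param response Response variable name.
#' @param fixed Character vector of fixed-effect covariate names (may be
#'   empty; an intercept is always included).
#' @param random Grouping-variable names for random intercepts (1 or 2).
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param transform Response transform: `"none"`, `"sqrt_offset"`
#'   (`sqrt(y + a)`) or `"log_offset"` (`log(y + a)`).
#' @param offset Offset `a` for the transform; `NULL` means data-derived
#'   as `|min(y)| + 0.01` so the transformed argument is strictly positive.
#' @param scale_continuous Standardise the (transformed) response and all
#'   continuous covariates to zero mean / unit SD, so slopes are
#'   standardized estimates. Covariates with only two distinct values
#'   (binary or -1/+1 codes) are left unscaled.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed = character(), random = "id",
                       family = c("gaussian", "binomial"),
                       transform = c("none", "sqrt_offset", "log_offset"),
                       offset = NULL, scale_continuous = TRUE) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (length(random) < 1L || length(random) > 2L)
    stop("1 or 2 random-intercept grouping variables are supported")
  structure(list(response = response, fixed = fixed, random = random,
                 family = family, transform = transform, offset = offset,
                 scale_continuous = scale_continuous),
            class = "model_spec")
}

.apply_transform <- function(y, transform, offset) {
  if (transform == "none") return(list(y = y, offset = NA_real_))
  if (is.null(offset)) offset <- abs(min(y)) + 0.01
  arg <- y + offset
  if (any(arg <= 0))
    stop("transform offset leaves non-positive arguments; increase `offset`")
  y2 <- switch(transform, sqrt_offset = sqrt(arg), log_offset = log(arg))
  list(y = y2, offset = offset)
}

.is_binary <- function(x) length(unique(x[!is.na(x)])) <= 2L

## Build response vector and fixed-effect design matrix from a spec.
.build_design <- function(spec, data) {
  used <- c(spec$response, spec$fixed, spec$random)
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("columns missing from data: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[used])
  if (!all(cc)) stop("missing values in model columns (", sum(!cc), " rows)")
  y <- data[[spec$response]]
  tr <- .apply_transform(y, spec$transform, spec$offset)
  y <- tr$y
  if (spec$scale_continuous && spec$family == "gaussian" && !.is_binary(y))
    y <- as.numeric(scale(y))
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in spec$fixed) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) {
      mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(factor(x))[-1])
      X <- cbind(X, mm)
    } else {
      if (spec$scale_continuous && !.is_binary(x)) x <- as.numeric(scale(x))
      X <- cbind(X, structure(matrix(x), dimnames = list(NULL, v)))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(y = y, X = X, groups = lapply(data[spec$random], function(g) factor(g)),
       offset_used = tr$offset)
}

## Profiled REML for y = X b + Z u + e with a single random intercept.
## lambda = sigma_u^2 / sigma_e^2 is profiled out by 1-D optimisation;
## V^-1 is applied through group sums (Woodbury), so each evaluation is
## O(n p^2).
.reml_one_re <- function(y, X, g) {
  g <- factor(g)
  n <- length(y); p <- ncol(X)
  ng <- as.numeric(table(g))
  Sy <- rowsum(y, g); SX <- rowsum(X, g)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  crit <- function(loglam) {
    lam <- exp(loglam)
    w <- lam / (1 + lam * ng)
    XtVX <- XtX - crossprod(SX * sqrt(w))
    XtVy <- Xty - crossprod(SX, w * Sy)
    ytVy <- yty - sum(w * Sy^2)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- backsolve(ch, forwardsolve(t(ch), XtVy))
    rss <- max(ytVy - sum(XtVy * b), 1e-12)
    sum(log1p(lam * ng)) + 2 * sum(log(diag(ch))) +
      (n - p) * log(rss)
  }
  opt <- stats::optimize(crit, c(-16, 12), tol = 1e-10)
  ## check the zero-variance boundary explicitly
  if (crit(-16) <= opt$objective + 1e-8 && opt$minimum > -15.9)
    opt <- list(minimum = -Inf, objective = crit(-16))
  lam <- if (is.finite(opt$minimum)) exp(opt$minimum) else 0
  w <- lam / (1 + lam * ng)
  XtVX <- XtX - crossprod(SX * sqrt(w))
  XtVy <- Xty - crossprod(SX, w * Sy)
  ytVy <- yty - sum(w * Sy^2)
  b <- solve(XtVX, XtVy)
  rss <- max(ytVy - sum(XtVy * b), 1e-12)
  s2e <- rss / (n - p)
  s2u <- lam * s2e
  vcov_b <- s2e * solve(XtVX)
  resid_fix <- y - X %*% b
  Sr <- rowsum(resid_fix, g)
  u <- w * Sr  # BLUPs
  fitted <- as.numeric(X %*% b + u[as.integer(g)])
  reml <- -0.5 * (sum(log1p(lam * ng)) + determinant(XtVX)$modulus +
                    (n - p) * (1 + log(2 * pi * s2e)))
  list(beta = stats::setNames(as.numeric(b), colnames(X)),
       se = stats::setNames(sqrt(diag(vcov_b)), colnames(X)),
       varcomp = c(group = s2u, residual = s2e),
       loglik = as.numeric(reml), fitted = fitted,
       residuals = y - fitted, lambda = lam)
}

#' Fit a Gaussian linear mixed model (random intercepts)
#'
#' With one grouping factor the model is fitted by the package's own
#' profiled-REML optimiser over the variance ratio; with two crossed
#' intercepts it is fitted by [lme4::lmer()] (REML). Both return the same
#' `mixed_fit` structure with standardized slopes when the spec requests
#' scaling.
#'
#' @param spec A [model_spec()] with `family = "gaussian"`.
#' @param data Data frame holding all model columns (no missing values).
#' @return A `mixed_fit`: `beta`, `se`, `p` (normal approximation),
#'   `varcomp` (per-group and residual variances), `loglik`, `fitted`,
#'   `residuals`, plus the spec and engine used.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "gaussian")
  d <- .build_design(spec, data)
  for (g in d$groups)
    if (nlevels(g) < 2L) stop("need >= 2 groups per random factor")
  if (length(d$groups) == 1L) {
    f <- .reml_one_re(d$y, d$X, d$groups[[1]])
    vc <- stats::setNames(f$varcomp, c(spec$random, "residual"))
    out <- list(beta = f$beta, se = f$se, varcomp = vc, loglik = f$loglik,
                fitted = f$fitted, residuals = f$residuals,
                engine = "profiled-reml", fit = NULL)
  } else {
    dd <- as.data.frame(d$X[, -1, drop = FALSE])
    nm <- colnames(d$X)[-1]
    names(dd) <- nm
    dd$.y <- d$y
    for (i in seq_along(d$groups)) dd[[paste0(".g", i)]] <- d$groups[[i]]
    fml <- stats::reformulate(c(nm, sprintf("(1 | .g%d)", seq_along(d$groups))),
                              response = ".y")
    fit <- lme4::lmer(fml, data = dd, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- vc$vcov
    gi <- suppressWarnings(as.integer(sub("^\\.g", "", vc$grp)))
    names(v) <- ifelse(vc$grp == "Residual", "residual", spec$random[gi])
    out <- list(beta = lme4::fixef(fit),
                se = sqrt(diag(as.matrix(stats::vcov(fit)))),
                varcomp = v, loglik = as.numeric(stats::logLik(fit)),
                fitted = stats::fitted(fit), residuals = stats::residuals(fit),
                engine = "lme4", fit = fit)
  }
  out$p <- 2 * stats::pnorm(-abs(out$beta / out$se))
  out$spec <- spec
  out$n <- length(d$y)
  out$design <- d
  class(out) <- "mixed_fit"
  out
}

#' Fit a binomial-logit mixed model (random intercepts)
#'
#' Laplace-approximated maximum likelihood via [lme4::glmer()] with one or
#' two crossed random intercepts. Latent-scale variance components are
#' reported; the logit-link variance pi^2/3 is recorded alongside.
#'
#' @inheritParams fit_lmm
#' @return A `mixed_fit` (see [fit_lmm()]); `varcomp` holds the
#'   latent-scale group variances plus `link = pi^2/3`.
#' @export
fit_binomial_glmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "binomial")
  d <- .build_design(spec, data)
  if (!all(d$y %in% c(0, 1))) stop("binomial response must be binary 0/1")
  dd <- as.data.frame(d$X[, -1, drop = FALSE])
  names(dd) <- colnames(d$X)[-1]
  dd$.y <- d$y
  for (i in seq_along(d$groups)) dd[[paste0(".g", i)]] <- d$groups[[i]]
  fml <- stats::reformulate(c(names(dd)[names(dd) != ".y" &
                                          !startsWith(names(dd), ".g")],
                              sprintf("(1 | .g%d)", seq_along(d$groups))),
                            response = ".y")
  fit <- suppressMessages(lme4::glmer(
    fml, data = dd, family = stats::binomial(),
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore")))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ## true complete separation: the fixed linear predictor alone classifies
  ## every observation with near certainty (distinct from large random
  ## effect variances on quasi-separated grouped data, which are legitimate)
  eta_fix <- as.numeric(d$X %*% beta)
  if (length(beta) > 1 && all(abs(eta_fix) > 4) &&
      all((eta_fix > 0) == (d$y == 1))) {
    bad <- names(beta[-1])[which.max(abs(beta[-1]))]
    stop("apparent complete separation on covariate(s): ",
         paste(bad, collapse = ", "))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, spec$random[
    suppressWarnings(as.integer(sub("^\\.g", "", vc$grp)))])
  out <- list(beta = beta, se = se,
              p = 2 * stats::pnorm(-abs(beta / se)),
              varcomp = c(v, link = pi^2 / 3),
              loglik = as.numeric(stats::logLik(fit)),
              fitted = stats::fitted(fit),
              residuals = d$y - stats::fitted(fit),
              engine = "lme4-laplace", fit = fit, spec = spec,
              n = length(d$y), design = d)
  class(out) <- "mixed_fit"
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> ", x$spec$family, " ", x$spec$response, " ~ ",
      paste(x$spec$fixed, collapse = " + "),
      " + (1|", paste(x$spec$random, collapse = ") + (1|"), ")  [",
      x$engine, ", n = ", x$n, "]\n", sep = "")
  tab <- cbind(beta = x$beta, se = x$se, p = x$p)
  print(round(tab, 4))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' @export
fitted.mixed_fit <- function(object, ...) object$fitted

#' @export
residuals.mixed_fit <- function(object, ...) object$residuals

#' @export
logLik.mixed_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + length(object$varcomp),
            class = "logLik")
}

## Internal dispatcher used by permutation loops.
.fit_any <- function(spec, data) {
  if (spec$family == "gaussian") fit_lmm(spec, data) else
    fit_binomial_glmm(spec, data)
}
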