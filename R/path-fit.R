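## Piecewise SEM: component mixed models over a DAG, standardized path
## coefficients, d-separation tests and Fisher's C.

.var_or_zero <- function(x) if (length(x) > 1) stats::var(x) else 0

## Drop variables without variation in the data (e.g. a constant age-class
## code when only one age class was sampled); returns the kept set.
.drop_degenerate <- function(vars, data, what) {
  if (!length(vars)) return(vars)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("column(s) missing from data: ", paste(miss, collapse = ", "))
  degen <- vapply(vars, function(v) length(unique(data[[v]])) < 2L, logical(1))
  if (any(degen))
    warning("dropping constant ", what, ": ",
            paste(vars[degen], collapse = ", "), call. = FALSE)
  vars[!degen]
}

## Fit one endogenous node's component model; returns the mixed_fit plus
## standardized coefficients for each parent.
.fit_component <- function(dag, node, data, random) {
  pa <- .drop_degenerate(.parents(dag, node), data, "predictor(s)")
  fam <- unname(dag$nodes[node])
  spec <- model_spec(node, fixed = pa, random = random, family = fam)
  fit <- .fit_any(spec, data)
  keep <- pa
  beta <- fit$beta[keep]; se <- fit$se[keep]; p <- fit$p[keep]
  if (fam == "binomial") {
    ## latent-theoretic standardization: slopes (on pre-scaled predictors)
    ## divided by the total latent SD = sqrt(fixed + random + pi^2/3)
    lat_sd <- sqrt(.var_or_zero(as.numeric(fit$design$X %*% fit$beta)) +
                     sum(fit$varcomp))  # varcomp already includes link
    beta <- beta / lat_sd
    se <- se / lat_sd
  }
  ## marginal R2: fixed-effects variance over total; varcomp already
  ## carries the residual (gaussian) or link (binomial) variance
  vf <- .var_or_zero(as.numeric(fit$design$X %*% fit$beta))
  r2 <- vf / (vf + sum(fit$varcomp))
  list(fit = fit, node = node,
       coef = data.frame(from = keep, to = node, beta = unname(beta),
                         se = unname(se), p = unname(p), family = fam,
                         stringsAsFactors = FALSE),
       marginal_r2 = unname(r2))
}

## Test one d-separation claim by adding the independent variable to the
## dependent's regression on the conditioning set.
.test_claim <- function(claim, dag, data, random) {
  cond <- .drop_degenerate(claim$cond, data, "conditioning variable(s)")
  if (length(unique(data[[claim$x]])) < 2L) return(NA_real_)
  spec <- model_spec(claim$y, fixed = c(cond, claim$x), random = random,
                     family = claim$family)
  fit <- .fit_any(spec, data)
  unname(fit$p[claim$x])
}

#' Fisher's C statistic from independence-claim p-values
#'
#' `C = -2 sum(log p_i)` compared against a chi-squared distribution with
#' `2k` degrees of freedom; with an empty basis set (saturated model)
#' `C = 0`, `df = 0` and the p-value is defined as 1.
#'
#' @param p Vector of claim p-values.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
fishers_c <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) return(list(statistic = 0, df = 0L, p_value = 1))
  C <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
  df <- 2L * length(p)
  list(statistic = C, df = df,
       p_value = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Each endogenous node of the DAG is fitted by a random-intercept mixed
#' model of its family (Gaussian LMM or binomial-logit GLMM), with
#' individual identity and the number of previously experienced tests as
#' random intercepts. Continuous variables are standardized internally so
#' slopes are standardized estimates; two-level factors are expected as
#' -1/+1 codes and left unscaled; binomial-node slopes are standardized on
#' the latent scale (adding the logit link variance pi^2/3). Global fit is
#' assessed through the d-separation basis set and Fisher's C; marginal
#' R-squared (fixed-effects variance over total) is reported per
#' endogenous node, and the declared correlated errors are estimated as
#' residual correlations (excluded from the basis set).
#'
#' @param dag A [dag_spec()], e.g. from [build_dag()].
#' @param data Analysis-ready session table (one row per individual x
#'   session; stress responses already variance-stabilised).
#' @param random Random-intercept grouping columns (default
#'   `c("id", "prior_tests")`).
#' @param test_dsep Run the d-separation tests (set `FALSE` to fit only the
#'   component models, e.g. in simulation loops that only need
#'   coefficients).
#' @return A `path_model_result`: `coefficients` (standardized, with SE and
#'   p), `fisher_c`, `fisher_df`, `fisher_p`, `basis_claims`,
#'   `marginal_r2`, `correlated_errors`, `components`.
#' @export
fit_path_model <- function(dag, data, random = c("id", "prior_tests"),
                           test_dsep = TRUE) {
  stopifnot(inherits(dag, "dag_spec"))
  endo <- intersect(.topo_order(dag), .endogenous(dag))
  comps <- lapply(endo, .fit_component, dag = dag, data = data,
                  random = random)
  names(comps) <- endo
  coefs <- do.call(rbind, lapply(comps, `[[`, "coef"))
  rownames(coefs) <- NULL
  r2 <- vapply(comps, `[[`, numeric(1), "marginal_r2")

  claims <- list(); pvals <- numeric(0)
  fc <- list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  if (test_dsep) {
    claims <- basis_set(dag)
    pvals <- vapply(claims, .test_claim, numeric(1), dag = dag, data = data,
                    random = random)
    fc <- fishers_c(pvals)
  }
  claim_tab <- if (length(claims)) data.frame(
    x = vapply(claims, `[[`, character(1), "x"),
    y = vapply(claims, `[[`, character(1), "y"),
    cond = vapply(claims, function(cl) paste(cl$cond, collapse = "+"),
                  character(1)),
    p = pvals, stringsAsFactors = FALSE)
  else data.frame(x = character(), y = character(), cond = character(),
                  p = numeric())

  ce <- dag$correlated_errors
  ce$rho <- ce$p <- NA_real_
  for (i in seq_len(nrow(ce))) {
    ra <- .node_residuals(comps, ce$a[i], data)
    rb <- .node_residuals(comps, ce$b[i], data)
    if (!is.null(ra) && !is.null(rb)) {
      ct <- stats::cor.test(ra, rb)
      ce$rho[i] <- unname(ct$estimate); ce$p[i] <- ct$p.value
    }
  }

  structure(list(coefficients = coefs, fisher_c = fc$statistic,
                 fisher_df = fc$df, fisher_p = fc$p_value,
                 basis_claims = claim_tab, marginal_r2 = r2,
                 correlated_errors = ce, components = comps, dag = dag),
            class = "path_model_result")
}

## Fixed-effects residuals of an endogenous node on its response scale;
## exogenous nodes get centred raw values.
.node_residuals <- function(comps, node, data) {
  if (node %in% names(comps)) {
    fit <- comps[[node]]$fit
    xb <- as.numeric(fit$design$X %*% fit$beta)
    if (fit$spec$family == "binomial")
      fit$design$y - stats::plogis(xb)
    else fit$design$y - xb
  } else if (is.numeric(data[[node]])) {
    as.numeric(scale(data[[node]], scale = FALSE))
  } else NULL
}

#' @export
print.path_model_result <- function(x, ...) {
  cat("<path_model_result> ", length(x$components),
      " component model(s)\n", sep = "")
  print(transform(x$coefficients, beta = round(beta, 3), se = round(se, 3),
                  p = signif(p, 3)))
  if (is.finite(x$fisher_c))
    cat(sprintf("Fisher's C = %.2f, df = %d, p = %.3f\n",
                x$fisher_c, x$fisher_df, x$fisher_p))
  cat("marginal R2:", paste(names(x$marginal_r2),
                            round(x$marginal_r2, 3), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Extract one standardized path coefficient
#'
#' @param result A `path_model_result`.
#' @param from,to Edge endpoints (column names).
#' @return The standardized slope (numeric scalar, `NA` if absent).
#' @export
path_coef <- function(result, from, to) {
  i <- result$coefficients$from == from & result$coefficients$to == to
  if (!any(i)) return(NA_real_)
  result$coefficients$beta[which(i)[1]]
}

#' Fit both causal-direction variants and compare birth-date effects
#'
#' Fits the default graph (behaviours upstream of the metabolic response)
#' and the inverted one (metabolic response upstream of the behaviours) and
#' reports whether the sign and significance pattern of the birth-date
#' effects agrees between the two.
#'
#' @param data Analysis-ready session table.
#' @param response Metabolic response column.
#' @param alpha Significance threshold for the agreement flag.
#' @param ... Passed to [build_dag()] / [fit_path_model()].
#' @param test_dsep Passed to [fit_path_model()].
#' @return List with both `path_model_result`s, a comparison `table` of the
#'   birth-date edges, and an `agreement` flag.
#' @export
compare_direction_variants <- function(data, response = "rmr", alpha = 0.05,
                                       test_dsep = TRUE, ...) {
  d1 <- build_dag(response = response, direction = "behaviour_to_mr", ...)
  d2 <- build_dag(response = response, direction = "mr_to_behaviour", ...)
  f1 <- fit_path_model(d1, data, test_dsep = test_dsep)
  f2 <- fit_path_model(d2, data, test_dsep = test_dsep)
  birth <- intersect("birth_date_numeric", names(d1$nodes))
  if (!length(birth)) birth <- d1$edges$from[1]
  targets <- unique(d1$edges$to[d1$edges$from == birth])
  cmp <- do.call(rbind, lapply(targets, function(to) {
    i1 <- which(f1$coefficients$from == birth & f1$coefficients$to == to)[1]
    i2 <- which(f2$coefficients$from == birth & f2$coefficients$to == to)[1]
    data.frame(edge = paste(birth, "->", to),
               beta_default = f1$coefficients$beta[i1],
               beta_inverted = f2$coefficients$beta[i2],
               sig_default = f1$coefficients$p[i1] < alpha,
               sig_inverted = f2$coefficients$p[i2] < alpha)
  }))
  cmp$agree <- sign(cmp$beta_default) == sign(cmp$beta_inverted) &
    cmp$sig_default == cmp$sig_inverted
  list(default = f1, inverted = f2, table = cmp,
       agreement = all(cmp$agree))
}
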