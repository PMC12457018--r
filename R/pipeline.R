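## Desk-scale orchestration of the whole study: simulate (or ingest) data,
## process respirometry traces, derive birth dates, and run the
## repeatability, association and path analyses.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic dataset) or `"ingest"`
#'   (read a bundle directory written by [write_bundle()]).
#' @param generator A [generator_config()] (simulate mode).
#' @param ingest_dir Bundle directory (ingest mode).
#' @param use_traces In simulate mode, synthesise respirometry traces and
#'   re-derive the metabolic variables from them (the full measurement
#'   route); `FALSE` analyses the generator's session-level values
#'   directly.
#' @param n_perm Permutations for Gaussian permutation tests (>= 100).
#' @param n_perm_binomial Permutations for the binomial repeatability
#'   (each requires a GLMM refit, so a smaller count is the default).
#' @param n_boot Parametric-bootstrap refits for repeatability CIs.
#' @param offsets Transform offsets for the stress responses, `"paper"`
#'   or `"data"` (see [prepare_analysis_data()]).
#' @param out_dir Optional output directory for CSV/JSON results.
#' @param rng_seed Seed for every stochastic step of the run.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            generator = generator_config(),
                            ingest_dir = NULL, use_traces = TRUE,
                            n_perm = 1000, n_perm_binomial = 200,
                            n_boot = 500, offsets = "paper",
                            out_dir = NULL, rng_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(rng_seed))
    stop("`rng_seed` must be set in simulate mode")
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (mode == "ingest" && is.null(ingest_dir))
    stop("`ingest_dir` required in ingest mode")
  structure(as.list(environment()), class = "pipeline_config")
}

.config_hash <- function(x) {
  f <- tempfile()
  writeLines(as.character(jsonlite::toJSON(x, force = TRUE, digits = NA)), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

## Replace session-level metabolic columns by the values measured from the
## respirometry traces.
.measure_from_traces <- function(cohort, traces) {
  key <- sprintf("%s_%d", cohort$id, cohort$session)
  for (i in seq_len(nrow(cohort))) {
    tr <- traces[[key[i]]]
    if (is.null(tr)) next
    s <- suppressWarnings(summarize_session(tr, cohort$body_mass[i]))
    cohort$rmr_raw[i] <- s$rmr_raw
    cohort$rmr[i] <- s$rmr
    cohort$stress_max[i] <- s$stress_max
    cohort$stress_integral[i] <- s$stress_integral
  }
  cohort
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or ingestion), respirometry trace
#' processing into per-session RMR and stress metrics, Gompertz birth-date
#' estimation, the session filter (only sessions with both behavioural and
#' metabolic data are analysed), short- and long-term repeatability of all
#' six traits, the nine marginal behaviour-metabolism association models,
#' and the three path models (one per metabolic response).
#'
#' Short-term repeatability uses the first two test sessions (young
#' adults); long-term repeatability uses all sessions.
#'
#' @param config A [pipeline_config()].
#' @return A `study_report`: repeatability and association tables, the
#'   three `path_model_result`s, exclusion counts, provenance (seed,
#'   config hash), and the analysis-ready data.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$rng_seed)
  ## --- data -------------------------------------------------------------
  if (config$mode == "simulate") {
    if (config$use_traces) {
      bundle <- generate_dataset(config$generator)
      cohort <- .measure_from_traces(bundle$cohort, bundle$traces)
    } else {
      bundle <- NULL
      cohort <- generate_cohort(config$generator)
    }
  } else {
    bundle <- read_bundle(config$ingest_dir)
    cohort <- .measure_from_traces(bundle$cohort, bundle$traces)
  }
  cohort <- add_birth_dates(cohort)
  data <- prepare_analysis_data(cohort, offsets = config$offsets)

  ## --- repeatability ----------------------------------------------------
  vars <- c(entry = "binomial", distance = "gaussian",
            exploration = "gaussian", rmr = "gaussian",
            stress_max = "gaussian", stress_integral = "gaussian")
  horizons <- list(short_term = data[data$session <= 2, ],
                   long_term = data)
  rep_tab <- do.call(rbind, lapply(names(horizons), function(h) {
    d <- horizons[[h]]
    do.call(rbind, lapply(names(vars), function(v) {
      sp <- model_spec(v, fixed = "prior_tests", random = "id",
                       family = vars[[v]])
      np <- if (vars[[v]] == "binomial") config$n_perm_binomial else
        config$n_perm
      r <- tryCatch(
        suppressWarnings(repeatability(sp, d, n_perm = np,
                                       n_boot = config$n_boot)),
        error = function(e) NULL)
      if (is.null(r))
        return(data.frame(horizon = h, variable = v, R = NA, ci_lo = NA,
                          ci_hi = NA, p_perm = NA, n_perm = 0L,
                          n_individuals = length(unique(d$id)),
                          n_measurements = nrow(d)))
      data.frame(horizon = h, variable = v, R = r$R, ci_lo = r$ci95[1],
                 ci_hi = r$ci95[2], p_perm = r$p_perm,
                 n_perm = r$n_permutations,
                 n_individuals = length(unique(d$id)),
                 n_measurements = nrow(d))
    }))
  }))

  ## --- nine association models (deliberately unadjusted) ----------------
  ## these transform the stress responses themselves, so they get the
  ## raw-unit filtered table rather than the pre-transformed one
  raw <- filter_complete_sessions(cohort)$data
  assoc <- association_models(raw, n_perm = config$n_perm,
                              offsets = config$offsets)

  ## --- path models ------------------------------------------------------
  paths <- lapply(c(rmr = "rmr", stress_max = "stress_max",
                    stress_integral = "stress_integral"), function(resp) {
    suppressWarnings(fit_path_model(build_dag(resp), data))
  })

  report <- structure(list(
    repeatability = rep_tab, association = assoc, paths = paths,
    excluded = attr(data, "excluded"),
    transform_offsets = attr(data, "offsets"),
    n_sessions_analysed = nrow(data),
    n_individuals = length(unique(data$id)),
    provenance = list(rng_seed = config$rng_seed,
                      config_hash = .config_hash(unclass(config$generator)),
                      r_version = as.character(getRversion())),
    data = data, config = config), class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$n_individuals, " individuals, ",
      x$n_sessions_analysed, " analysed sessions (",
      sum(x$excluded), " excluded)\n", sep = "")
  cat("\nRepeatability (R with 95% CI and permutation p):\n")
  print(transform(x$repeatability, R = round(R, 3), ci_lo = round(ci_lo, 3),
                  ci_hi = round(ci_hi, 3)), row.names = FALSE)
  cat("\nMarginal behaviour-metabolism associations (9 LMMs):\n")
  print(transform(x$association, beta = round(beta, 3), se = round(se, 3)),
        row.names = FALSE)
  for (nm in names(x$paths)) {
    cat("\nPath model, response =", nm, "\n")
    print(x$paths[[nm]])
  }
  invisible(x)
}

#' Write a study report as CSV tables and a JSON bundle
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$repeatability,
                   file.path(dir, "repeatability.csv"), row.names = FALSE)
  utils::write.csv(report$association,
                   file.path(dir, "association.csv"), row.names = FALSE)
  coefs <- do.call(rbind, lapply(names(report$paths), function(nm)
    cbind(response = nm, report$paths[[nm]]$coefficients)))
  utils::write.csv(coefs, file.path(dir, "path_coefficients.csv"),
                   row.names = FALSE)
  fit <- lapply(report$paths, function(p)
    list(fisher_c = p$fisher_c, df = p$fisher_df, p = p$fisher_p,
         marginal_r2 = as.list(p$marginal_r2)))
  jsonlite::write_json(
    list(path_fit = fit, excluded = as.list(report$excluded),
         n_sessions_analysed = report$n_sessions_analysed,
         n_individuals = report$n_individuals,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Robustness suite: coarsened birth dates and inverted causal direction
#'
#' Re-runs each of the three path models under three perturbations: birth
#' dates coarsened to 14-day bins, to 28-day bins, and the
#' inverted-direction graph (metabolic response upstream of behaviours).
#' For each variant it reports whether the sign and significance of every
#' birth-date effect agrees with the main analysis.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param alpha Significance threshold.
#' @return Data frame with one row per (response, variant) and an
#'   `agreement` flag, plus the refitted models in an attribute.
#' @export
robustness_suite <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "study_report"))
  data <- report$data
  out <- list(); fits <- list()
  for (resp in names(report$paths)) {
    main <- report$paths[[resp]]
    for (variant in c("birth_14d", "birth_28d", "inverted")) {
      if (variant == "inverted") {
        fit <- suppressWarnings(
          fit_path_model(build_dag(resp, direction = "mr_to_behaviour"),
                         data))
      } else {
        d2 <- data
        col <- sub("birth", "birth_date", variant)
        d2$birth_date_numeric <- d2[[col]]
        if (length(unique(d2$birth_date_numeric)) < 2L)
          stop("degenerate coarsened birth date (single bin) for variant ",
               variant)
        fit <- suppressWarnings(fit_path_model(build_dag(resp), d2))
      }
      cmp <- merge(
        main$coefficients[main$coefficients$from == "birth_date_numeric",
                          c("to", "beta", "p")],
        fit$coefficients[fit$coefficients$from == "birth_date_numeric",
                         c("to", "beta", "p")],
        by = "to", suffixes = c("_main", "_variant"))
      agree <- all(sign(cmp$beta_main) == sign(cmp$beta_variant) &
                     (cmp$p_main < alpha) == (cmp$p_variant < alpha))
      out[[length(out) + 1]] <- data.frame(
        response = resp, variant = variant, agreement = agree)
      fits[[paste(resp, variant, sep = ".")]] <- fit
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fits") <- fits
  res
}
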