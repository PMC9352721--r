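# Random-intercept linear mixed models of phenometric DOY on log(GDD),
# overwinter strategy and life-history traits, with AIC selection and
# marginal/conditional pseudo-R2.

#' Build a model frame of matched phenometrics, thermal sums and traits
#'
#' Only species-cell-year units with phenometrics from both streams enter the
#' frame (the paired table from [match_paired_units()] enforces this); the
#' response is one stream's DOY estimate at one percentile. `log_gdd` is the
#' natural log of the cell-year GDD; rows with incomplete trait data are
#' dropped with a message stating the count.
#'
#' @param pairs paired phenometrics from [match_paired_units()].
#' @param gdd tibble `cell_id`, `year`, `gdd` (must be positive).
#' @param traits species trait tibble.
#' @param percentile 10 or 50.
#' @param source `"survey"` or `"incidental"` — which stream's estimate is
#'   the response.
#' @param log_base base of the GDD logarithm (natural log by default).
#' @return tibble with `response`, `log_gdd`, trait covariates and
#'   `species_id`, ready for [fit_random_intercept_lmm()].
#' @export
build_model_frame <- function(pairs, gdd, traits, percentile = 10,
                              source = c("survey", "incidental"),
                              log_base = exp(1)) {
  source <- match.arg(source)
  assert_columns(gdd, c("cell_id", "year", "gdd"), "gdd")
  pp <- pairs[pairs$percentile == percentile, , drop = FALSE]
  resp_col <- paste0("doy_estimate_", source)
  assert_columns(pp, c("species_id", "cell_id", "year", resp_col), "pairs")
  frame <- pp |>
    dplyr::inner_join(gdd[, c("cell_id", "year", "gdd")],
                      by = c("cell_id", "year"))
  if (any(frame$gdd <= 0)) {
    stop("non-positive GDD for unit(s): cannot take log", call. = FALSE)
  }
  frame$log_gdd <- log(frame$gdd, base = log_base)
  frame$response <- frame[[resp_col]]
  frame <- dplyr::left_join(frame, traits, by = "species_id")
  trait_cols <- intersect(
    c("overwinter_class", "voltinism", "host_breadth", "locally_common",
      "wing_size", "mobility", "canopy_assoc", "egg_cluster",
      "detectability", "confusability"), names(frame))
  keep_cols <- c("species_id", "cell_id", "year", "response", "log_gdd",
                 "gdd", trait_cols)
  frame <- frame[, keep_cols]
  complete <- stats::complete.cases(frame)
  if (any(!complete)) {
    message(sprintf("dropping %d row(s) with incomplete trait data",
                    sum(!complete)))
    frame <- frame[complete, , drop = FALSE]
  }
  if ("overwinter_class" %in% names(frame)) {
    frame$overwinter_class <- factor(frame$overwinter_class,
                                     levels = overwinter_classes)
    frame$overwinter_class <- droplevels(frame$overwinter_class)
  }
  tibble::as_tibble(frame)
}

#' Fit a random-intercept linear mixed model
#'
#' Gaussian identity-link model with a species random intercept, fit by
#' REML (default, for reported coefficients) or ML (for AIC comparison)
#' through [lmerTest::lmer()], which supplies Satterthwaite-approximate
#' degrees of freedom and p-values. The default fixed structure has no
#' global intercept: one intercept per overwinter class plus the log-GDD
#' slope.
#'
#' @param frame tibble from [build_model_frame()].
#' @param formula_spec model formula; the random part must be a species
#'   random intercept (further variance components are allowed in candidate
#'   models).
#' @param method `"REML"` or `"ML"`.
#' @return an `lmm_fit` list: `coefficients` tibble (term, estimate, se, df,
#'   p_value), `varcor` (named variance components + `residual`), `logLik`,
#'   `AIC`, `n_obs`, `n_species`, `r2_marginal`, `r2_conditional`, `method`,
#'   and the underlying `fit`.
#' @export
fit_random_intercept_lmm <- function(frame,
                                     formula_spec = response ~ 0 +
                                       overwinter_class + log_gdd +
                                       (1 | species_id),
                                     method = c("REML", "ML")) {
  method <- match.arg(method)
  formula_spec <- as.formula(formula_spec)
  if (dplyr::n_distinct(frame$species_id) < 2) {
    stop("need >= 2 species to fit a species random intercept", call. = FALSE)
  }

  # degenerate case: constant response has zero residual variance, outside
  # the mixed-model parameter space
  if (sd(frame$response) == 0) {
    fx <- lme4::nobars(formula_spec)
    X <- stats::model.matrix(stats::update(fx, NULL ~ .), data = frame)
    beta <- setNames(rep(0, ncol(X)), colnames(X))
    icpt <- grepl("(Intercept)|overwinter_class", names(beta))
    beta[icpt] <- frame$response[1]
    co <- tibble::tibble(term = names(beta), estimate = unname(beta),
                         se = 0, df = NA_real_, p_value = NA_real_)
    return(structure(list(coefficients = co,
                          varcor = c(species_id = 0, residual = 0),
                          logLik = NA_real_, AIC = NA_real_,
                          n_obs = nrow(frame),
                          n_species = dplyr::n_distinct(frame$species_id),
                          r2_marginal = NA_real_, r2_conditional = NA_real_,
                          method = method, fit = NULL, formula = formula_spec),
                     class = "lmm_fit"))
  }

  # singular fixed design -> name the aliased columns up front
  fx <- lme4::nobars(formula_spec)
  X <- stats::model.matrix(stats::update(fx, NULL ~ .), data = frame)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  # boundary fits (variance ~ 0) are legitimate here; muffle the optimizer's
  # near-zero-eigenvalue chatter but let real convergence failures through
  fit <- withCallingHandlers(
    lmerTest::lmer(formula_spec, data = frame,
                   REML = (method == "REML"),
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("eigenvalue close to zero", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  smry <- suppressWarnings(summary(fit))
  cm <- smry$coefficients
  co <- tibble::tibble(term = rownames(cm),
                       estimate = cm[, "Estimate"],
                       se = cm[, "Std. Error"],
                       df = if ("df" %in% colnames(cm)) cm[, "df"]
                            else NA_real_,
                       p_value = if ("Pr(>|t|)" %in% colnames(cm))
                         cm[, "Pr(>|t|)"] else NA_real_)
  vc <- lme4::VarCorr(fit)
  comps <- vapply(vc, function(v) v[1, 1], 0)
  varcor <- c(comps, residual = stats::sigma(fit)^2)
  r2 <- nakagawa_r2(fit)
  structure(list(coefficients = co, varcor = varcor,
                 logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 n_obs = nobs(fit),
                 n_species = dplyr::n_distinct(frame$species_id),
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 method = method, fit = fit, formula = formula_spec),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s), n = %d obs / %d species\n",
              x$method, x$n_obs, x$n_species))
  cat(sprintf("AIC %.1f | marginal R2 %.3f | conditional R2 %.3f\n",
              x$AIC, x$r2_marginal, x$r2_conditional))
  print(x$coefficients)
  invisible(x)
}

#' Marginal and conditional pseudo-R2 for a mixed model
#'
#' Variance-component decomposition for Gaussian identity-link mixed models:
#' marginal R2 is the fixed-effect variance over the total (fixed + random
#' intercepts + residual), conditional R2 additionally credits the random
#' intercepts. The fixed-effect variance is the variance of the fixed-effect
#' linear predictor over the data.
#'
#' @param fit a `merMod`/`lmerModLmerTest` object or an `lmm_fit`.
#' @return named numeric: `r2_marginal`, `r2_conditional`.
#' @seealso [nakagawa_r2_components()] for the plug-in formula on known
#'   variance components.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "lmm_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "merMod"))
  var_fixed <- var(as.numeric(predict(fit, re.form = NA)))
  vc <- lme4::VarCorr(fit)
  var_random <- sum(vapply(vc, function(v) v[1, 1], 0))
  var_resid <- stats::sigma(fit)^2
  nakagawa_r2_components(var_fixed, var_random, var_resid)
}

#' Pseudo-R2 from known variance components
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param var_random summed random-effect (intercept) variances.
#' @param var_resid residual variance.
#' @return named numeric: `r2_marginal`, `r2_conditional`.
#' @export
nakagawa_r2_components <- function(var_fixed, var_random, var_resid) {
  total <- var_fixed + var_random + var_resid
  if (total <= 0) stop("zero total variance", call. = FALSE)
  c(r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total)
}

#' Select among candidate mixed models by AIC
#'
#' All candidates are fit by maximum likelihood on identical rows (an error
#' otherwise), compared by AIC with ties broken toward fewer parameters, and
#' the winner refit by REML for reported coefficients.
#'
#' @param frame model frame (complete cases; all candidates must use only
#'   its columns).
#' @param candidates named list of model formulas (>= 1).
#' @return list: `best` (`lmm_fit`, REML refit), `aic_table` (tibble with
#'   model, df, AIC, delta_AIC, ordered).
#' @export
select_by_aic <- function(frame, candidates) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("m", seq_along(candidates))
  }
  fits <- purrr::map(candidates, function(f) {
    fit_random_intercept_lmm(frame, f, method = "ML")
  })
  ns <- vapply(fits, function(f) f$n_obs, 0)
  if (length(unique(ns)) > 1) {
    stop("candidates were fit on differing row sets (n = ",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  }
  dfs <- vapply(fits, function(f) {
    attr(logLik(f$fit), "df")
  }, 0)
  aics <- vapply(fits, function(f) f$AIC, 0)
  ord <- order(aics, dfs)  # ties -> fewer parameters
  tab <- tibble::tibble(model = names(candidates)[ord],
                        df = unname(dfs[ord]), AIC = unname(aics[ord]),
                        delta_AIC = unname(aics[ord] - min(aics)))
  best_name <- tab$model[1]
  best <- fit_random_intercept_lmm(frame, candidates[[best_name]],
                                   method = "REML")
  list(best = best, best_name = best_name, aic_table = tab)
}

#' Default candidate model set
#'
#' Mirrors the structure searched in practice: a stage-intercept base model,
#' with and without log-GDD, its interaction with overwinter class, and
#' single-trait extensions.
#'
#' @param include_interaction include the GDD x overwinter interaction
#'   candidate.
#' @return named list of formulas.
#' @export
default_candidates <- function(include_interaction = TRUE) {
  cands <- list(
    stage_only = response ~ 0 + overwinter_class + (1 | species_id),
    stage_gdd = response ~ 0 + overwinter_class + log_gdd + (1 | species_id),
    stage_gdd_common = response ~ 0 + overwinter_class + log_gdd +
      locally_common + (1 | species_id),
    stage_gdd_host = response ~ 0 + overwinter_class + log_gdd +
      host_breadth + (1 | species_id)
  )
  if (include_interaction) {
    cands$stage_x_gdd <- response ~ 0 + overwinter_class +
      overwinter_class:log_gdd + (1 | species_id)
  }
  cands
}
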