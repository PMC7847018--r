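## Statistical layer: group comparisons, factorial ANOVA with estimated
## marginal means and Tukey contrasts, and backward-stepwise regression of
## transmembrane clearance on circuit covariates.

#' Pooled two-sample t-test
#'
#' Classical two-sided Student t-test with pooled variance. Degenerate
#' inputs are resolved by convention rather than error: zero pooled variance
#' with equal means gives t = 0, p = 1; with unequal means t = +/-Inf, p = 0.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `mean_x`, `mean_y`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs >= 2 values.")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  s2p <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  diff <- mean(x) - mean(y)
  if (s2p == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    t <- diff / sqrt(s2p * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(t), df)
  }
  tibble::tibble(statistic = t, df = df, p.value = p,
                 mean_x = mean(x), mean_y = mean(y))
}

#' Factorial ANOVA with marginal means and Tukey contrasts
#'
#' Least-squares factorial analysis of a response (typically transmembrane
#' clearance) on coded circuit factors. Factors are effect-coded
#' (sum-to-zero contrasts) internally; Type II sums of squares are used so
#' that the one unbalanced comparison in the study design (point of dilution
#' tested only at one flow rate) does not contaminate main-effect tests.
#' Estimated marginal means with t-based confidence intervals are computed
#' over the full factor grid, and Tukey HSD pairwise comparisons (studentized
#' range distribution, residual mean square of the fitted model as error
#' term) are reported per factor.
#'
#' @param data Data frame of per-experiment results.
#' @param response Name of the response column.
#' @param factors Character vector of factor columns.
#' @param interactions Highest interaction order to fit (default: all).
#' @param conf_level Confidence level for marginal means. Default 0.95.
#' @return Object of class `crrt_anova`: list with `model`, `anova`
#'   (term, sumsq, df, statistic, p.value), `emmeans` (cell means with CIs),
#'   `tukey` (pairwise contrasts per factor), `r2`, `adj_r2`. Use [tidy()]
#'   for the effect table and [glance()] for fit statistics.
#' @export
factorial_anova <- function(data, response, factors,
                            interactions = length(factors),
                            conf_level = 0.95) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  d <- tibble::as_tibble(data)[, c(response, factors)]
  d[factors] <- lapply(d[factors], function(x) factor(x))
  interactions <- max(1L, min(interactions, length(factors)))
  rhs <- if (length(factors) == 1L) factors else
    paste0("(", paste(factors, collapse = " + "), ")^", interactions)
  fml <- stats::as.formula(paste(response, "~", rhs))
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- lm(fml, data = d, contrasts = contr)
  if (stats::df.residual(fit) < 1) {
    abort(paste0("Model is saturated (no residual df); drop the order-",
                 interactions, " interaction."))
  }
  degenerate <- var(d[[response]]) == 0
  maybe_quiet <- if (degenerate) suppressWarnings else identity
  s <- maybe_quiet(summary(fit))
  if (degenerate) {
    # constant response: every effect is zero by convention
    trms <- attr(stats::terms(fit), "term.labels")
    at <- tibble::tibble(term = trms, sumsq = 0,
                         df = NA_integer_, statistic = 0, p.value = 1)
  } else {
    a2 <- car::Anova(fit, type = 2)
    at <- tibble::tibble(
      term = rownames(a2),
      sumsq = a2$`Sum Sq`,
      df = a2$Df,
      statistic = a2$`F value`,
      p.value = a2$`Pr(>F)`
    )
    at <- dplyr::filter(at, .data$term != "Residuals")
  }
  emm <- maybe_quiet(emmeans::emmeans(fit, specs = factors,
                                      level = conf_level))
  emm_tbl <- tibble::as_tibble(summary(emm, level = conf_level))
  tukey <- purrr::map_dfr(factors, function(f) {
    if (nlevels(d[[f]]) < 2) return(NULL)
    pr <- maybe_quiet(summary(emmeans::contrast(
      emmeans::emmeans(fit, specs = f),
      method = "pairwise", adjust = "tukey")))
    dplyr::mutate(tibble::as_tibble(pr), factor = f, .before = 1)
  })
  structure(list(
    model = fit, anova = at, emmeans = emm_tbl, tukey = tukey,
    r2 = if (degenerate) 0 else s$r.squared,
    adj_r2 = if (degenerate) 0 else s$adj.r.squared,
    response = response, factors = factors
  ), class = "crrt_anova")
}

#' @exportS3Method generics::tidy
tidy.crrt_anova <- function(x, ...) x$anova

#' @exportS3Method generics::glance
glance.crrt_anova <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
                 df.residual = stats::df.residual(x$model),
                 nobs = stats::nobs(x$model))
}

#' @export
print.crrt_anova <- function(x, ...) {
  cat("Factorial ANOVA:", x$response, "~",
      paste(x$factors, collapse = " x "), "\n")
  print(x$anova)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Add coded regression covariates to a per-experiment result table
#'
#' Appends the numeric covariate coding used by the regression layer:
#' `filter_code` (HF1400 = 1, M150 = 2), `flow` (the effluent flow, L/h),
#' `mode_code` (CVVH = 1, CVVHD = 2) and `dilution` (the pre-filter
#' replacement fraction; 0 for CVVHD, which has no replacement fluid).
#'
#' @param data Result tibble carrying `mode`, `filter`,
#'   `effluent_flow_L_h`, `dilution_split` columns (e.g. from
#'   [clearance_auc()]).
#' @return `data` with the four coded columns appended.
#' @export
code_covariates <- function(data) {
  stopifnot(all(c("mode", "filter", "effluent_flow_L_h", "dilution_split")
                %in% names(data)))
  dplyr::mutate(
    tibble::as_tibble(data),
    filter_code = filter_code(.data$filter),
    flow = .data$effluent_flow_L_h,
    mode_code = dplyr::if_else(.data$mode == "CVVH", 1, 2),
    dilution = dplyr::coalesce(.data$dilution_split, 0)
  )
}

#' Backward-stepwise linear regression
#'
#' Fits the response on all candidate covariates (dummy/reference coding, so
#' coefficients read directly as per-unit effects), then repeatedly removes
#' the covariate with the largest p-value above `alpha` and refits, stopping
#' when every retained covariate has p <= `alpha`. Ties in p-value are
#' broken by removing the covariate listed last in `candidates`, making the
#' procedure deterministic. The final fit is reported with 95% confidence
#' intervals, adjusted R-squared and collinearity diagnostics (VIF and
#' tolerance = 1/VIF).
#'
#' @param data Data frame of per-experiment results.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate covariate columns
#'   (numeric coded; e.g. filter 1/2, flow in L/h).
#' @param alpha Retention threshold on the covariate p-value. Default 0.05.
#' @param conf_level Confidence level for intervals. Default 0.95.
#' @return Object of class `crrt_stepfit`: list with `model` (the final
#'   [lm]), `retained`, `dropped`, `steps` (removal log), `coefficients`
#'   (term, estimate, conf.low, conf.high, p.value), `diagnostics`
#'   (VIF/tolerance), `r2`, `adj_r2`. Use [tidy()] / [glance()].
#' @export
backward_stepwise <- function(data, response, candidates, alpha = 0.05,
                              conf_level = 0.95) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(candidates %in% names(data)))
  if (nrow(data) < length(candidates) + 2) {
    abort("Need at least `length(candidates) + 2` observations.")
  }
  d <- tibble::as_tibble(data)
  current <- candidates
  steps <- list()
  refit <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    lm(stats::as.formula(paste(response, "~", rhs)), data = d)
  }
  term_p <- function(fit, terms) {
    ct <- summary(fit)$coefficients
    p <- setNames(rep(NA_real_, length(terms)), terms)
    hit <- intersect(terms, rownames(ct))
    p[hit] <- ct[hit, "Pr(>|t|)"]
    # perfect fits give 0/0 t-statistics: a term carrying the fit (nonzero
    # estimate) is kept, one contributing nothing is first out
    if (any(is.nan(p)) && summary(fit)$sigma < 1e-10) {
      est <- ct[intersect(terms, rownames(ct)), "Estimate"]
      nan_terms <- names(p)[is.nan(p)]
      p[nan_terms] <- ifelse(abs(est[nan_terms]) > 1e-8, 0, Inf)
    }
    # aliased (dropped) coefficients carry no information: remove first
    p[is.na(p)] <- Inf
    p
  }
  fit <- refit(current)
  repeat {
    if (!length(current)) break
    p <- term_p(fit, current)
    worst <- max(p)
    if (worst <= alpha) break
    tied <- which(p >= worst - 1e-12)
    drop_term <- current[max(tied)]  # ties: last in candidate order
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, removed = drop_term,
      p.value = unname(p[drop_term]))
    current <- setdiff(current, drop_term)
    fit <- refit(current)
  }
  if (!length(current)) {
    warn("No covariate met the retention threshold; returning intercept-only fit.")
  }
  s <- summary(fit)
  ci <- confint(fit, level = conf_level)
  ct <- s$coefficients
  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
  diagnostics <- if (length(current) >= 2) {
    v <- car::vif(fit)
    tibble::tibble(term = names(v), vif = unname(v), tolerance = 1 / unname(v))
  } else {
    tibble::tibble(term = current, vif = NA_real_, tolerance = NA_real_)
  }
  structure(list(
    model = fit, retained = current, dropped = setdiff(candidates, current),
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), removed = character(),
                     p.value = double()),
    coefficients = coefs, diagnostics = diagnostics,
    r2 = s$r.squared, adj_r2 = s$adj.r.squared,
    alpha = alpha, response = response, candidates = candidates
  ), class = "crrt_stepfit")
}

#' @exportS3Method generics::tidy
tidy.crrt_stepfit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.crrt_stepfit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
                 sigma = summary(x$model)$sigma,
                 nobs = stats::nobs(x$model),
                 n.retained = length(x$retained))
}

#' @export
print.crrt_stepfit <- function(x, ...) {
  cat("Backward-stepwise fit:", x$response, "~",
      if (length(x$retained)) paste(x$retained, collapse = " + ") else "1",
      "\n")
  print(x$coefficients)
  cat(sprintf("adjusted R2 = %.3f (alpha = %g; dropped: %s)\n", x$adj_r2,
              x$alpha,
              if (length(x$dropped)) paste(x$dropped, collapse = ", ")
              else "none"))
  invisible(x)
}
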