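new_risk_estimates <- function(df, measure, reference, provenance,
                               p0 = NULL, counts = NULL) {
  structure(df,
            measure = measure, reference = reference,
            provenance = provenance, p0 = p0, counts = counts,
            class = c("risk_estimates", class(df)))
}

#' @export
print.risk_estimates <- function(x, ...) {
  cat(toupper(attr(x, "measure")), "estimates vs", attr(x, "reference"),
      "(", attr(x, "provenance"), ")\n")
  NextMethod()
  invisible(x)
}

#' Construct a set of relative-risk or odds-ratio estimates
#'
#' A small container used throughout the package: one row per non-reference
#' exposure level, with a point estimate and 95% confidence bounds, plus
#' attributes recording the effect measure, the reference level and the
#' provenance of the estimates. Used both for estimates computed from data
#' and for published estimates entered directly.
#'
#' @param genotype Character vector of non-reference exposure levels.
#' @param estimate,lower,upper Positive point estimates and 95% CI bounds;
#'   bounds must bracket the point estimate.
#' @param measure `"rr"` or `"or"`.
#' @param reference Reference level label (its implicit estimate is 1).
#' @param provenance Free-text provenance tag, e.g. `"crude"`,
#'   `"log-binomial"`, `"published"`.
#' @return A tibble of class `risk_estimates`.
#' @export
risk_estimates <- function(genotype, estimate, lower = NA_real_,
                           upper = NA_real_, measure = c("rr", "or"),
                           reference = "e2/e2", provenance = "published") {
  measure <- match.arg(measure)
  if (any(estimate <= 0, na.rm = TRUE)) {
    stop("relative estimates must be positive", call. = FALSE)
  }
  ok <- is.na(lower) | is.na(upper) | (lower <= estimate & estimate <= upper)
  if (!all(ok)) {
    stop("confidence bounds must bracket the point estimate", call. = FALSE)
  }
  df <- tibble::tibble(genotype = as.character(genotype),
                       estimate = as.numeric(estimate),
                       lower = as.numeric(lower),
                       upper = as.numeric(upper))
  new_risk_estimates(df, measure, reference, provenance)
}

#' Crude risk ratios from a cohort-design count table
#'
#' Point estimate \eqn{RR_i = (a_i/n_i) / (a_r/n_r)} for each exposure level
#' against the reference, with Wald confidence intervals on the log scale
#' (\eqn{SE^2 = 1/a_i - 1/n_i + 1/a_r - 1/n_r}).
#'
#' @param counts A [genotype_counts()] table with cohort design.
#' @param reference Reference level (default `"e2/e2"`).
#' @param conf_level Confidence level for the Wald interval.
#' @param correction If `TRUE`, add 0.5 to every case count and 1 to every
#'   total when any case cell is zero (Haldane-Anscombe style); off by
#'   default so zeros surface as errors rather than silently shifted
#'   estimates.
#' @return A `risk_estimates` set with measure `"rr"` and provenance
#'   `"crude"`.
#' @examples
#' a4 <- genotype_counts(c("e2/e2", "carrier"), cases = c(1, 1202),
#'                       totals = c(25, 4390))
#' crude_rr(a4)
#' @export
crude_rr <- function(counts, reference = "e2/e2", conf_level = 0.95,
                     correction = FALSE) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (attr(counts, "design") != "cohort") {
    stop("crude_rr() needs a cohort-design table (cases and totals); ",
         "use crude_or() for case-control counts", call. = FALSE)
  }
  if (!reference %in% counts$genotype) {
    stop("reference level ", reference, " not in the count table",
         call. = FALSE)
  }
  a <- counts$cases
  n <- counts$totals
  if (any(a == 0)) {
    if (correction) {
      a <- a + 0.5
      n <- n + 1
    } else {
      stop("zero case count for level(s) ",
           paste(counts$genotype[counts$cases == 0], collapse = ", "),
           "; risk ratio undefined (set correction = TRUE to apply a ",
           "continuity correction)", call. = FALSE)
    }
  }
  i_ref <- match(reference, counts$genotype)
  risk <- a / n
  rr <- risk / risk[i_ref]
  se <- sqrt(1 / a - 1 / n + 1 / a[i_ref] - 1 / n[i_ref])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- seq_along(rr) != i_ref
  df <- tibble::tibble(
    genotype = counts$genotype[keep],
    estimate = rr[keep],
    lower = exp(log(rr[keep]) - z * se[keep]),
    upper = exp(log(rr[keep]) + z * se[keep])
  )
  new_risk_estimates(df, "rr", reference, "crude", counts = counts)
}

#' Crude odds ratios from a case-control count table
#'
#' Point estimate \eqn{OR_i = (a_i/a_r) / (b_i/b_r)} for each level against
#' the reference, with Wald log-scale confidence intervals
#' (\eqn{SE^2 = 1/a_i + 1/b_i + 1/a_r + 1/b_r}).
#'
#' @inheritParams crude_rr
#' @param correction If `TRUE`, add 0.5 to all four cells of any 2x2 slice
#'   containing a zero (Haldane-Anscombe); off by default.
#' @return A `risk_estimates` set with measure `"or"` and provenance
#'   `"crude"`.
#' @export
crude_or <- function(counts, reference = "e2/e2", conf_level = 0.95,
                     correction = FALSE) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (attr(counts, "design") != "case-control") {
    stop("crude_or() needs a case-control table (cases and controls); ",
         "use crude_rr() for cohort counts", call. = FALSE)
  }
  if (!reference %in% counts$genotype) {
    stop("reference level ", reference, " not in the count table",
         call. = FALSE)
  }
  i_ref <- match(reference, counts$genotype)
  a_r <- counts$cases[i_ref]
  b_r <- counts$controls[i_ref]
  keep <- which(counts$genotype != reference)
  est <- lower <- upper <- numeric(length(keep))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (j in seq_along(keep)) {
    i <- keep[j]
    cells <- c(cases = counts$cases[i], controls = counts$controls[i],
               ref_cases = a_r, ref_controls = b_r)
    if (any(cells == 0)) {
      if (!correction) {
        zero <- names(cells)[cells == 0][1]
        stop("zero cell (", zero, ") in the 2x2 slice for ",
             counts$genotype[i], " vs ", reference,
             "; set correction = TRUE for a Haldane-Anscombe correction",
             call. = FALSE)
      }
      cells <- cells + 0.5
    }
    or <- (cells[["cases"]] / cells[["ref_cases"]]) /
      (cells[["controls"]] / cells[["ref_controls"]])
    se <- sqrt(sum(1 / cells))
    est[j] <- or
    lower[j] <- exp(log(or) - z * se)
    upper[j] <- exp(log(or) + z * se)
  }
  df <- tibble::tibble(genotype = counts$genotype[keep], estimate = est,
                       lower = lower, upper = upper)
  new_risk_estimates(df, "or", reference, "crude", counts = counts)
}

#' Re-orient an odds-ratio set to a new reference level
#'
#' Published odds ratios are often expressed against the most common
#' genotype (e3/e3); attributable-fraction work needs them against the
#' lowest-risk level (e2/e2). When the underlying count table is attached
#' (estimates produced by [crude_or()]), the re-oriented set is recomputed
#' exactly from the counts, including its standard errors. Otherwise the
#' point estimates are divided by the new reference's estimate and the
#' confidence bounds are divided likewise — a documented approximation that
#' ignores the covariance between the two log-odds ratios.
#'
#' @param s A `risk_estimates` set with measure `"or"`.
#' @param new_reference The level to re-reference against; must be the
#'   current reference or one of the listed levels.
#' @return A re-oriented `risk_estimates` set; the old reference appears as
#'   a level with estimate \eqn{1/OR_{new}}.
#' @export
reorient_or <- function(s, new_reference) {
  stopifnot(inherits(s, "risk_estimates"))
  if (attr(s, "measure") != "or") {
    stop("reorient_or() expects an odds-ratio set", call. = FALSE)
  }
  old_ref <- attr(s, "reference")
  if (new_reference == old_ref) return(s)
  if (!new_reference %in% s$genotype) {
    stop("new reference ", new_reference, " absent from the estimate set",
         call. = FALSE)
  }
  counts <- attr(s, "counts")
  if (!is.null(counts)) {
    return(crude_or(counts, reference = new_reference))
  }
  i <- match(new_reference, s$genotype)
  pivot <- s$estimate[i]
  df <- tibble::tibble(
    genotype = c(s$genotype[-i], old_ref),
    estimate = c(s$estimate[-i], 1) / pivot,
    lower = c(s$lower[-i], 1) / s$upper[i],
    upper = c(s$upper[-i], 1) / s$lower[i]
  )
  new_risk_estimates(df, "or", new_reference,
                     paste0(attr(s, "provenance"), "+reoriented"))
}

#' Convert an odds ratio to a risk ratio given the reference-group risk
#'
#' Uses the standard conversion \eqn{RR = OR / (1 - p_0 + p_0 \cdot OR)},
#' where \eqn{p_0} is the outcome probability in the reference group. For
#' \eqn{OR > 1} the result always lies between 1 and the OR, approaching the
#' OR as the outcome becomes rare.
#'
#' @param or Positive odds ratio(s); vectorised.
#' @param p0 Baseline outcome probability in the reference group, in (0,1).
#' @return Risk ratio(s) of the same length as `or`.
#' @examples
#' or_to_rr(236.74, p0 = 0.01)
#' @export
or_to_rr <- function(or, p0) {
  if (any(or <= 0, na.rm = TRUE)) stop("odds ratios must be positive",
                                       call. = FALSE)
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must be a single probability in (0, 1)", call. = FALSE)
  }
  or / (1 - p0 + p0 * or)
}

#' Convert an odds-ratio set to risk ratios
#'
#' Applies [or_to_rr()] identically to the point estimate and both
#' confidence bounds of every level, mirroring the plug-in treatment of
#' confidence intervals used downstream for attributable fractions.
#'
#' @param s A `risk_estimates` set with measure `"or"`.
#' @param p0 Baseline outcome probability in the reference group.
#' @return A `risk_estimates` set with measure `"rr"` and provenance
#'   recording the conversion and the `p0` used.
#' @export
convert_or_set <- function(s, p0) {
  stopifnot(inherits(s, "risk_estimates"))
  if (attr(s, "measure") != "or") {
    stop("convert_or_set() expects an odds-ratio set", call. = FALSE)
  }
  df <- tibble::tibble(
    genotype = s$genotype,
    estimate = or_to_rr(s$estimate, p0),
    lower = or_to_rr(s$lower, p0),
    upper = or_to_rr(s$upper, p0)
  )
  new_risk_estimates(df, "rr", attr(s, "reference"),
                     paste0("converted-from-or(p0=", format(p0), ")"),
                     p0 = p0)
}

build_model_frame <- function(cohort, covariates, reference) {
  stopifnot(all(c("genotype", "outcome") %in% names(cohort)))
  cohort <- cohort[!is.na(cohort$genotype), , drop = FALSE]
  if (!all(cohort$outcome %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (all(cohort$outcome == 0) || all(cohort$outcome == 1)) {
    stop("degenerate outcome: all subjects share the same outcome value; ",
         "no relative risk is estimable", call. = FALSE)
  }
  g <- factor(as.character(cohort$genotype))
  if (!reference %in% levels(g)) {
    stop("reference level ", reference, " absent from the cohort",
         call. = FALSE)
  }
  cohort$genotype <- stats::relevel(g, ref = reference)
  rhs <- paste(c("genotype", covariates), collapse = " + ")
  list(formula = stats::as.formula(paste("outcome ~", rhs)), data = cohort)
}

extract_genotype_effects <- function(fit, reference, measure, provenance,
                                     conf_level = 0.95) {
  cf <- summary(fit)$coefficients
  idx <- grep("^genotype", rownames(cf))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  df <- tibble::tibble(
    genotype = sub("^genotype", "", rownames(cf)[idx]),
    estimate = exp(cf[idx, "Estimate"]),
    lower = exp(cf[idx, "Estimate"] - z * cf[idx, "Std. Error"]),
    upper = exp(cf[idx, "Estimate"] + z * cf[idx, "Std. Error"])
  )
  new_risk_estimates(df, measure, reference, provenance)
}

#' Log-binomial regression: relative risks from individual-level data
#'
#' Fits a generalised linear model with binomial outcome and log link, whose
#' exponentiated genotype coefficients are risk ratios against the reference
#' genotype. Fitting uses iteratively reweighted least squares with step
#' halving; log-binomial models are prone to non-convergence when fitted
#' probabilities approach one (typically for e4/e4 strata with high baseline
#' risk), in which case this function stops with a diagnostic recommending
#' the logistic-regression + odds-ratio-conversion path ([fit_logistic()]
#' then [convert_or_set()]) rather than silently switching — the choice of
#' effect measure is an analyst decision.
#'
#' @param cohort Data frame with columns `genotype`, `outcome` (0/1) and any
#'   covariates.
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("age", "sex")`), or `NULL` for a genotype-only model.
#' @param reference Reference genotype level.
#' @param conf_level Confidence level for Wald intervals.
#' @return A `risk_estimates` set (measure `"rr"`, provenance
#'   `"log-binomial"`).
#' @export
fit_log_binomial <- function(cohort, covariates = NULL, reference = "e2/e2",
                             conf_level = 0.95) {
  mf <- build_model_frame(cohort, covariates, reference)
  n_terms <- length(attr(stats::terms(mf$formula), "term.labels"))
  p_bar <- mean(mf$data$outcome)
  n_coef <- 1 + (nlevels(mf$data$genotype) - 1) +
    if (is.null(covariates)) 0 else {
      sum(vapply(covariates, function(v) {
        x <- mf$data[[v]]
        if (is.factor(x) || is.character(x)) length(unique(x)) - 1L else 1L
      }, integer(1)))
    }
  start <- c(log(p_bar), rep(0, n_coef - 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm(mf$formula, data = mf$data,
                                family = stats::binomial(link = "log"),
                                start = start,
                                control = stats::glm.control(maxit = 100))),
    error = function(e) e
  )
  if (inherits(fit, "error") || !isTRUE(fit$converged)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      "IRLS did not converge"
    stop("log-binomial model failed to converge (", msg, "); fitted ",
         "probabilities near 1 are the usual cause. Consider fit_logistic() ",
         "followed by convert_or_set() with an assumed baseline risk.",
         call. = FALSE)
  }
  extract_genotype_effects(fit, reference, "rr", "log-binomial", conf_level)
}

#' Logistic regression: odds ratios from individual-level data
#'
#' The logit-link counterpart of [fit_log_binomial()], for case-control
#' samples or cohorts where the log-binomial model does not converge.
#' Exponentiated genotype coefficients are odds ratios against the reference;
#' convert them to risk ratios with [convert_or_set()] before attributable-
#' fraction work.
#'
#' @inheritParams fit_log_binomial
#' @return A `risk_estimates` set (measure `"or"`, provenance `"logistic"`).
#' @export
fit_logistic <- function(cohort, covariates = NULL, reference = "e2/e2",
                         conf_level = 0.95) {
  mf <- build_model_frame(cohort, covariates, reference)
  fit <- tryCatch(
    suppressWarnings(stats::glm(mf$formula, data = mf$data,
                                family = stats::binomial(),
                                control = stats::glm.control(maxit = 100))),
    error = function(e) e
  )
  if (inherits(fit, "error") || !isTRUE(fit$converged)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      "IRLS did not converge"
    stop("logistic model failed to converge (", msg, ")", call. = FALSE)
  }
  extract_genotype_effects(fit, reference, "or", "logistic", conf_level)
}
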