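#' Fisher r-to-z transform
#'
#' `atanh(r)`, the variance-stabilising transform for Pearson correlations.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be strictly below 1")
  atanh(r)
}

#' Compare two independent correlations (Fisher z-test, Cohen's q)
#'
#' Test statistic
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a standard
#' normal two-sided p-value, and effect size `q = |atanh(r1) - atanh(r2)|`
#' (independent of n).
#'
#' @param r1,r2 the two correlations (|r| < 1).
#' @param n1,n2 their sample sizes (> 3).
#' @return list with `Z`, `p`, `q`, `z1`, `z2`.
#' @export
compare_correlations <- function(r1, r2, n1, n2 = n1) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  Z <- (z1 - z2) / se
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), q = abs(z1 - z2),
       z1 = z1, z2 = z2)
}

#' Dependent-correlations variant (shared variable)
#'
#' Steiger-style test for two correlations sharing one variable and one
#' sample; offered as an alternative, not the default, for the contrast of
#' component-reference correlations.
#'
#' @param r1,r2 correlations of the shared variable with each reference.
#' @param r12 correlation between the two references.
#' @param n common sample size (> 3).
#' @return list with `Z`, `p`, `q`.
#' @export
compare_correlations_dependent <- function(r1, r2, r12, n) {
  if (n <= 3) stop("sample size must exceed 3")
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  rbar <- (r1 + r2) / 2
  cov_term <- (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
                 (1 - 2 * rbar^2 - r12^2)) / (1 - rbar^2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), q = abs(z1 - z2))
}

#' Correlate component time courses with reference functions
#'
#' Pearson correlation of every component synchronization time course with
#' every reference function, with a two-sided p-value from the t distribution
#' on `n - 2` degrees of freedom and Bonferroni adjustment over `m_tests`.
#'
#' @param time_courses time x components matrix (or `ica_result`).
#' @param references time x conditions matrix with column names.
#' @param m_tests number of tests for Bonferroni; defaults to
#'   `ncol(references) * ncol(time_courses)`.
#' @param components optional subset of component indices (e.g. retained
#'   components only).
#' @return data.frame with one row per (component, condition):
#'   `component`, `condition`, `r`, `p_raw`, `p_bonferroni`, `n`.
#' @export
component_condition_correlations <- function(time_courses, references,
                                             m_tests = NULL,
                                             components = NULL) {
  if (inherits(time_courses, "ica_result"))
    time_courses <- time_courses$time_courses
  tc <- as.matrix(time_courses)
  rf <- as.matrix(references)
  if (nrow(tc) != nrow(rf)) stop("time courses and references differ in length")
  n <- nrow(tc)
  if (n < 4) stop("need at least 4 time points")
  if (is.null(components)) components <- seq_len(ncol(tc))
  if (is.null(m_tests)) m_tests <- ncol(rf) * length(components)
  sds <- apply(tc[, components, drop = FALSE], 2, stats::sd)
  if (any(sds == 0) || any(apply(rf, 2, stats::sd) == 0))
    stop("zero-variance series supplied to correlation")
  rows <- expand.grid(component = components,
                      condition = colnames(rf),
                      stringsAsFactors = FALSE)
  r <- mapply(function(k, cond) stats::cor(tc[, k], rf[, cond]),
              rows$component, rows$condition)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(rows, r = r, p_raw = p,
             p_bonferroni = pmin(1, m_tests * p), n = n,
             stringsAsFactors = FALSE)
}

#' Condition-specificity contrasts for one component
#'
#' Fisher z contrasts between a component's correlations with two reference
#' conditions (e.g. pain vs matched control), using the independent-samples
#' form of [compare_correlations()].
#'
#' @param assoc output of [component_condition_correlations()].
#' @param component component id.
#' @param condition_a,condition_b condition labels to contrast.
#' @return one-row data.frame: `component`, `condition_a`, `condition_b`,
#'   `r_a`, `r_b`, `z_a`, `z_b`, `Z`, `p`, `q`, `n`.
#' @export
condition_contrast <- function(assoc, component, condition_a, condition_b) {
  pick <- function(cond) {
    row <- assoc[assoc$component == component & assoc$condition == cond, ]
    if (nrow(row) != 1) stop("no unique association row for ", cond)
    row
  }
  a <- pick(condition_a); b <- pick(condition_b)
  cc <- compare_correlations(a$r, b$r, a$n, b$n)
  data.frame(component = component,
             condition_a = condition_a, condition_b = condition_b,
             r_a = a$r, r_b = b$r, z_a = cc$z1, z_b = cc$z2,
             Z = cc$Z, p = cc$p, q = cc$q, n = a$n)
}
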