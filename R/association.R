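#' Average repeated measures over waves
#'
#' Instrument sum-scores collected at several assessment waves are averaged
#' over all waves with an observed value; a participant missing every wave
#' stays missing.
#'
#' @param values_by_wave Numeric matrix or data frame (participants x
#'   waves), or a single numeric vector treated as one participant's waves.
#' @return Numeric vector of per-participant means (`NA` where all waves
#'   are missing).
#' @examples
#' aggregate_repeated_measures(c(10, 20, NA)) # 15
#' @export
aggregate_repeated_measures <- function(values_by_wave) {
  if (is.data.frame(values_by_wave))
    values_by_wave <- as.matrix(values_by_wave)
  if (!is.matrix(values_by_wave))
    values_by_wave <- matrix(as.numeric(values_by_wave), nrow = 1L)
  out <- rowMeans(values_by_wave, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Covariate-adjusted association of one exposure with one outcome
#'
#' Ordinary least squares of the outcome on the exposure plus covariates on
#' complete cases. Reports the unstandardized coefficient `b` with its 95%
#' confidence interval, the fully standardized coefficient `beta`
#' (re-fitting with every variable z-scored, binary covariates and
#' exposures included, the convention of common statistical packages), and
#' the two-sided p value for the exposure term.
#'
#' @param data Data frame holding all variables.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "female", "education_years")`; may be empty).
#' @param full_standardization If `FALSE`, `beta` standardizes outcome and
#'   continuous variables but leaves binary exposures on their 0/1 scale
#'   (the partially standardized alternative).
#' @return One-row data frame of class `association_result`: `outcome`,
#'   `exposure`, `b`, `ci_low`, `ci_high`, `beta`, `p_raw`, `n_used`.
#' @export
fit_adjusted <- function(data, outcome, exposure,
                         covariates = c("age", "female", "education_years"),
                         full_standardization = TRUE) {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[vars]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 10L)
    stop("fewer than 10 complete cases for ", outcome, " ~ ", exposure,
         call. = FALSE)
  if (length(unique(d[[exposure]])) < 2L)
    stop("exposure '", exposure, "' is constant on complete cases",
         call. = FALSE)
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(vars))
    stop("rank-deficient model for ", outcome, " ~ ", exposure,
         call. = FALSE)
  cf <- summary(fit)$coefficients
  term <- sprintf("`%s`", exposure)
  if (!term %in% rownames(cf)) term <- exposure
  ci <- stats::confint(fit, term, level = 0.95)

  zd <- d
  is_binary <- function(x) all(x %in% c(0, 1))
  for (v in vars) {
    if (!full_standardization && v != outcome && is_binary(zd[[v]])) next
    zd[[v]] <- as.numeric(scale(zd[[v]]))
  }
  zfit <- stats::lm(fml, data = zd)
  beta <- unname(stats::coef(zfit)[term])

  structure(data.frame(outcome = outcome, exposure = exposure,
                       b = unname(cf[term, "Estimate"]),
                       ci_low = ci[1L], ci_high = ci[2L],
                       beta = beta,
                       p_raw = unname(cf[term, "Pr(>|t|)"]),
                       n_used = n, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("association_result", "data.frame"))
}

#' Residualize the FLS on the dichotomous FH indicator
#'
#' Saves the residuals of an ordinary least-squares regression of FLS on FH
#' (intercept included): the component of continuous familial loading
#' orthogonal to the dichotomous indicator.
#'
#' @param fls Numeric vector of familial loading scores.
#' @param fh 0/1 vector; both levels must be present.
#' @return Residual vector (mean 0, exactly uncorrelated with `fh`).
#' @examples
#' residualize(c(1, 2, 3, 4), c(0, 0, 1, 1)) # -0.5 0.5 -0.5 0.5
#' @export
residualize <- function(fls, fh) {
  fls <- as.numeric(fls); fh <- as.numeric(fh)
  stopifnot(length(fls) == length(fh), !anyNA(fls), !anyNA(fh))
  if (length(unique(fh)) < 2L)
    stop("'fh' has a single level: residualization undefined", call. = FALSE)
  unname(stats::resid(stats::lm(fls ~ fh)))
}

#' Point-biserial and Pearson correlations
#'
#' `point_biserial()` is the Pearson product-moment correlation between a
#' 0/1 variable and a continuous variable; `pearson_cor()` the standard
#' Pearson correlation between two continuous variables.
#'
#' @param binary 0/1 vector with both levels present.
#' @param continuous,x,y Numeric vectors.
#' @return Correlation in \[-1, 1\].
#' @examples
#' point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4)) # 2/sqrt(5)
#' @export
point_biserial <- function(binary, continuous) {
  binary <- as.numeric(binary); continuous <- as.numeric(continuous)
  stopifnot(length(binary) == length(continuous),
            !anyNA(binary), !anyNA(continuous))
  if (length(binary) < 3L) stop("need n >= 3", call. = FALSE)
  if (!all(binary %in% c(0, 1)))
    stop("'binary' must be coded 0/1", call. = FALSE)
  if (length(unique(binary)) < 2L || stats::sd(continuous) == 0)
    stop("degenerate input: a variable is constant", call. = FALSE)
  stats::cor(binary, continuous)
}

#' @rdname point_biserial
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance (df = n1 + n2 - 2), the variant
#' whose degrees of freedom equal N - 2 for two groups partitioning a
#' sample — e.g. comparing FLS between FH+ and FH- participants. The sign
#' follows the group order (`x` minus `y`).
#'
#' @param x,y Numeric vectors, each with at least two observations.
#' @return List with `t`, `df`, `p`, and a `degenerate` flag set when the
#'   pooled variance is zero (infinite t).
#' @export
pooled_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(!anyNA(x), !anyNA(y))
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need n >= 2", call. = FALSE)
  df <- length(x) + length(y) - 2L
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1). The
#' uncorrected statistic is the one that reproduces published values
#' computed from raw counts in standard statistical packages.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @examples
#' chi_square_2x2(matrix(c(191, 57, 949, 476), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("'counts' must be a 2x2 matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: chi-square undefined", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at rate `q`: order the m p values ascending, find the
#' largest k with `p(k) <= k * q / m`, and reject the k smallest. Adjusted
#' p values use the standard monotone cumulative minimum; raw p values are
#' kept alongside for reporting.
#'
#' @param p_values Numeric vector of raw p values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return List with `reject` (logical, original order), `p_adjusted`,
#'   and the input `p_raw`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, p_raw = p)
}

#' Full association pipeline
#'
#' For every outcome, fits three covariate-adjusted models — exposure FLS,
#' exposure FH, and exposure residualized FLS (FLS residualized on FH) —
#' and applies Benjamini-Hochberg control over the exposure p values.
#' Also returns the correlation summary: point-biserial r between FH and
#' FLS, the pooled-variance t test of FLS by FH group, per-FH-group FLS
#' mean/sd and an overlap fraction, and (when a `prs` column is present)
#' the Pearson r between FLS and the polygenic-score stand-in.
#'
#' @param participants Participant-level data frame with `fh`, `fls`,
#'   covariates, and outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @param covariates Covariate column names.
#' @param bh_family `"per_exposure"` (default: one BH family per exposure
#'   block across outcomes) or `"global"` (one family over all models).
#' @param q False discovery rate (default 0.05).
#' @param full_standardization Passed to [fit_adjusted()].
#' @return List of class `association_analysis` with `results` (data
#'   frame, 3 rows per outcome: `b`, `ci_low`, `ci_high`, `beta`,
#'   `p_raw`, `bh_reject`, `n_used`) and `correlations`.
#' @export
run_full_analysis <- function(participants, outcomes,
                              covariates = c("age", "female",
                                             "education_years"),
                              bh_family = c("per_exposure", "global"),
                              q = 0.05, full_standardization = TRUE) {
  bh_family <- match.arg(bh_family)
  stopifnot(is.data.frame(participants),
            all(c("fh", "fls") %in% names(participants)),
            all(outcomes %in% names(participants)))
  d <- participants
  d$fls_resid <- residualize(d$fls, d$fh)
  exposures <- c("fls", "fh", "fls_resid")
  rows <- lapply(outcomes, function(oc)
    do.call(rbind, lapply(exposures, function(ex)
      fit_adjusted(d, oc, ex, covariates,
                   full_standardization = full_standardization))))
  results <- do.call(rbind, rows)
  class(results) <- "data.frame"

  if (bh_family == "global") {
    results$bh_reject <- bh_fdr(results$p_raw, q)$reject
  } else {
    results$bh_reject <- NA
    for (ex in exposures) {
      i <- results$exposure == ex
      results$bh_reject[i] <- bh_fdr(results$p_raw[i], q)$reject
    }
  }

  fls_pos <- d$fls[d$fh == 1]; fls_neg <- d$fls[d$fh == 0]
  tt <- pooled_t_test(fls_neg, fls_pos) # FH- minus FH+: negative t expected
  overlap <- mean(fls_neg >= min(fls_pos)) # FH- mass inside the FH+ range
  correlations <- list(
    r_fh_fls = point_biserial(d$fh, d$fls),
    t_fls_by_fh = tt,
    fls_by_fh = data.frame(
      fh = c(0, 1),
      mean = c(mean(fls_neg), mean(fls_pos)),
      sd = c(stats::sd(fls_neg), stats::sd(fls_pos)),
      n = c(length(fls_neg), length(fls_pos))),
    overlap_fraction = overlap,
    r_fls_prs = if ("prs" %in% names(d)) pearson_cor(d$fls, d$prs) else NA_real_)

  structure(list(results = results, correlations = correlations,
                 bh_family = bh_family, q = q),
            class = "association_analysis")
}

#' @export
print.association_analysis <- function(x, ...) {
  cat(sprintf("Association analysis: %d models (%d outcomes x 3 exposures)\n",
              nrow(x$results), nrow(x$results) / 3L))
  cat(sprintf("  BH family: %s at q = %g | r(FH, FLS) = %.3f | t(%d) = %.2f\n",
              x$bh_family, x$q, x$correlations$r_fh_fls,
              x$correlations$t_fls_by_fh$df, x$correlations$t_fls_by_fh$t))
  print(format(x$results, digits = 3), row.names = FALSE)
  invisible(x)
}
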