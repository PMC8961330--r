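#' Fraction of the first-onset risk window traversed
#'
#' Under the uniform-onset construction, cumulative onset risk by age `x`
#' for a person with lifetime prevalence `p` is `p * u(x)` with
#' `u(x) = clamp((x - d) / (c - d), 0, 1)`: the share of the first-onset
#' window `[d, c]` already lived through.
#'
#' @param age Numeric vector of ages in years (non-negative).
#' @param params An [fls_parameters()] object.
#' @return Values in \[0, 1\].
#' @examples
#' onset_fraction(c(5, 35, 65)) # 0, 0.5, 1 at defaults
#' @export
onset_fraction <- function(age, params = fls_parameters()) {
  stopifnot(inherits(params, "fls_parameters"))
  age <- as.numeric(age)
  if (anyNA(age) || any(age < 0))
    stop("ages must be non-negative and non-missing", call. = FALSE)
  pmin(pmax((age - params$d_lower) / (params$c_upper - params$d_lower), 0), 1)
}

#' Per-relative likelihood ratios
#'
#' Each relative contributes a likelihood ratio comparing the hypothesis
#' that the participant carries familial risk (relatives' lifetime
#' prevalence `a`) against the hypothesis that they do not (prevalence
#' `b`), given the relative's observed affection status at age `x`.
#'
#' With cumulative risk `p * u(x)` the affected-relative ratio
#' `a*u / (b*u)` is age-free and equals `a/b` wherever `u > 0`; for an
#' affection recorded before the window opens (`age <= d`) the same `a/b`
#' is returned with a data-consistency warning, since an onset should not
#' yet have occurred. The unaffected-relative ratio is
#' `(1 - a*u(x)) / (1 - b*u(x))`: 1 at `u = 0` (no evidence yet),
#' decreasing to `(1-a)/(1-b)` once the window is fully traversed.
#'
#' @inheritParams onset_fraction
#' @return Positive likelihood ratios, one per age.
#' @examples
#' lr_affected(40)         # 0.50 / 0.134 = 3.731
#' lr_unaffected(65)       # (1 - 0.50) / (1 - 0.134) = 0.577
#' @export
lr_affected <- function(age, params = fls_parameters()) {
  u <- onset_fraction(age, params) # validates age and params
  if (any(u == 0))
    warning(sum(u == 0), " relative(s) recorded affected at or below the ",
            "lower window age ", params$d_lower,
            ": check data consistency", call. = FALSE)
  rep(params$a / params$b, length(u))
}

#' @rdname lr_affected
#' @export
lr_unaffected <- function(age, params = fls_parameters()) {
  u <- onset_fraction(age, params)
  (1 - params$a * u) / (1 - params$b * u)
}

#' Familial loading score for one family
#'
#' Multiplies the likelihood ratios of all of a participant's first-degree
#' relatives — affected and unaffected — into one overall ratio and takes
#' its common logarithm. The computation accumulates `log10` terms rather
#' than the raw product, so long pedigrees cannot overflow or underflow;
#' an empty family yields the empty product, FLS = 0.
#'
#' @param age_years Numeric vector of relatives' observation ages.
#' @param affected Logical vector of relatives' affected statuses.
#' @param params An [fls_parameters()] object.
#' @return A list of class `fls_result` with elements `fls` (common-log
#'   scale), `per_relative_log_lr`, and `overall_lr` (= `10^fls`, for
#'   audit).
#' @examples
#' compute_fls(50, TRUE)                      # log10(0.50/0.134)
#' compute_fls(c(50, 65), c(TRUE, FALSE))
#' @export
compute_fls <- function(age_years, affected, params = fls_parameters()) {
  affected <- as.logical(affected)
  age_years <- as.numeric(age_years)
  if (length(age_years) != length(affected))
    stop("'age_years' and 'affected' must have equal length", call. = FALSE)
  if (anyNA(affected))
    stop("unresolved affected status for relative(s): ",
         paste(which(is.na(affected)), collapse = ", "), call. = FALSE)
  if (anyNA(age_years))
    stop("missing age for relative(s): ",
         paste(which(is.na(age_years)), collapse = ", "), call. = FALSE)
  lr <- numeric(length(affected))
  if (any(affected))
    lr[affected] <- lr_affected(age_years[affected], params)
  if (any(!affected))
    lr[!affected] <- lr_unaffected(age_years[!affected], params)
  log_lr <- log10(lr)
  structure(list(fls = sum(log_lr),
                 per_relative_log_lr = log_lr,
                 overall_lr = 10^sum(log_lr)),
            class = "fls_result")
}

#' @export
print.fls_result <- function(x, ...) {
  cat(sprintf("FLS = %.4f  (overall LR = %.4f, %d relative(s))\n",
              x$fls, x$overall_lr, length(x$per_relative_log_lr)))
  invisible(x)
}

#' Score every family in a relative-level table
#'
#' Computes, per proband, the dichotomous family-history indicator and the
#' continuous familial loading score from a relative-level table, along
#' with family size and the number of affected relatives. Probands listed
#' with zero relatives (or supplied via `proband_ids`) receive FH = 0 and
#' FLS = 0.
#'
#' @param relatives Relative-level data frame (see [validate_relatives()]).
#' @param params An [fls_parameters()] object.
#' @param proband_ids Optional vector of proband identifiers to score even
#'   when absent from `relatives` (scored as empty families).
#' @return Data frame with columns `proband_id`, `fh` (0/1), `fls`,
#'   `n_relatives`, `n_affected`.
#' @export
score_families <- function(relatives, params = fls_parameters(),
                           proband_ids = NULL) {
  relatives <- validate_relatives(relatives)
  ids <- unique(c(as.character(relatives$proband_id),
                  as.character(proband_ids)))
  idx <- split(seq_len(nrow(relatives)),
               factor(as.character(relatives$proband_id), levels = ids))
  res <- lapply(ids, function(id) {
    i <- idx[[id]]
    aff <- relatives$affected[i]
    fh <- if (length(i)) any(aff) else FALSE
    fls <- if (length(i))
      compute_fls(relatives$age_years[i], aff, params)$fls else 0
    data.frame(proband_id = id, fh = as.integer(fh), fls = fls,
               n_relatives = length(i), n_affected = sum(aff),
               stringsAsFactors = FALSE)
  })
  empties <- sum(vapply(idx, length, 1L) == 0L)
  if (empties)
    warning(empties, " proband(s) with no relatives scored FH- / FLS = 0",
            call. = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
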