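#' Classify a first-degree relative as affected
#'
#' A relative is considered affected by depression and/or anxiety only when
#' both Family Tree Inventory criteria are met: (i) at least one endorsement
#' on the presence of depressive/anxiety episodes, core symptoms, or
#' restrictions, and (ii) at least one endorsement on receiving treatment or
#' being admitted to a hospital/psychiatric ward for that disorder. Only the
#' two aggregate flags matter; which specific sub-question was endorsed does
#' not.
#'
#' @param endorsement_symptoms Logical vector: any symptom-type question
#'   endorsed (episode / core symptoms / restrictions).
#' @param endorsement_treatment Logical vector: any treatment-type question
#'   endorsed (treatment / hospital or psychiatric-ward admission).
#' @param relative_id Optional identifiers used in error messages when a flag
#'   is missing.
#' @return Logical vector: affected status per relative.
#' @examples
#' classify_relative(TRUE, TRUE)   # TRUE
#' classify_relative(TRUE, FALSE)  # FALSE: treatment criterion unmet
#' @export
classify_relative <- function(endorsement_symptoms, endorsement_treatment,
                              relative_id = NULL) {
  s <- as.logical(endorsement_symptoms)
  t <- as.logical(endorsement_treatment)
  if (length(s) != length(t))
    stop("endorsement flag vectors must have equal length", call. = FALSE)
  bad <- which(is.na(s) | is.na(t))
  if (length(bad)) {
    who <- if (!is.null(relative_id)) paste(relative_id[bad], collapse = ", ")
           else paste("position", paste(bad, collapse = ", "))
    stop("missing endorsement flag for relative(s): ", who, call. = FALSE)
  }
  s & t
}

.relative_required_cols <- c("proband_id", "relation", "age_years",
                             "endorsement_symptoms", "endorsement_treatment")

#' Validate a relative-level table
#'
#' Checks the schema and invariants of a relative-level data frame: one row
#' per first-degree relative, with columns `proband_id`, `relation`
#' ("parent" or "sibling"), `age_years` (observation age, or age at death if
#' deceased), the two endorsement flags, and optionally a pre-resolved
#' `affected` column. When endorsement flags are present, a supplied
#' `affected` column must agree with [classify_relative()]; when `affected`
#' is absent it is derived. Per-question endorsement columns (prefixes
#' `symptom_` / `treatment_`) are OR-reduced into the aggregate flags first.
#'
#' @param relatives Data frame of relatives.
#' @param max_age Ages above this are rejected as data errors. Default 120.
#' @param impute_missing_age If `TRUE`, missing relative ages are replaced by
#'   the mean age within the same relation class, with a warning; the default
#'   (`FALSE`) treats a missing age as a hard error, matching the exclusion
#'   (rather than imputation) of incomplete family interviews.
#' @return The validated data frame with a resolved logical `affected`
#'   column, invisibly classed `relative_table`.
#' @export
validate_relatives <- function(relatives, max_age = 120,
                               impute_missing_age = FALSE) {
  if (!is.data.frame(relatives))
    stop("'relatives' must be a data frame", call. = FALSE)
  relatives <- as.data.frame(relatives)

  # OR-reduce optional per-question columns into the aggregate flags
  for (crit in c("symptom", "treatment")) {
    sub <- grep(paste0("^", crit, "_"), names(relatives), value = TRUE)
    agg <- paste0("endorsement_", ifelse(crit == "symptom", "symptoms",
                                         "treatment"))
    if (length(sub) && !agg %in% names(relatives)) {
      m <- as.matrix(relatives[sub]) > 0
      relatives[[agg]] <- apply(m, 1L, any)
    }
  }

  has_flags <- all(c("endorsement_symptoms", "endorsement_treatment") %in%
                     names(relatives))
  need <- setdiff(.relative_required_cols, names(relatives))
  if (!has_flags && "affected" %in% names(relatives))
    need <- setdiff(need, c("endorsement_symptoms", "endorsement_treatment"))
  if (length(need))
    stop("relative table is missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)

  rel <- as.character(relatives$relation)
  bad_rel <- which(!rel %in% c("parent", "sibling"))
  if (length(bad_rel))
    stop("invalid relation (must be 'parent' or 'sibling') at row(s): ",
         paste(utils::head(bad_rel, 5L), collapse = ", "), call. = FALSE)
  relatives$relation <- rel

  age <- as.numeric(relatives$age_years)
  if (anyNA(age)) {
    if (impute_missing_age) {
      for (r in unique(rel)) {
        idx <- which(rel == r & is.na(age))
        if (length(idx)) {
          fill <- mean(age[rel == r], na.rm = TRUE)
          if (!is.finite(fill))
            stop("cannot impute age for relation '", r,
                 "': no observed ages", call. = FALSE)
          age[idx] <- fill
          warning(sprintf(
            "imputed %d missing %s age(s) with relation mean %.1f",
            length(idx), r, fill), call. = FALSE)
        }
      }
    } else {
      stop("missing age_years at row(s): ",
           paste(utils::head(which(is.na(age)), 5L), collapse = ", "),
           "; set impute_missing_age = TRUE to impute relation means",
           call. = FALSE)
    }
  }
  if (any(age < 0 | age > max_age))
    stop("age_years outside [0, ", max_age, "] at row(s): ",
         paste(utils::head(which(age < 0 | age > max_age), 5L),
               collapse = ", "), call. = FALSE)
  relatives$age_years <- age

  if (has_flags) {
    derived <- classify_relative(relatives$endorsement_symptoms,
                                 relatives$endorsement_treatment,
                                 relative_id = rownames(relatives))
    if ("affected" %in% names(relatives)) {
      aff <- as.logical(relatives$affected)
      mism <- which(!is.na(aff) & aff != derived)
      if (length(mism))
        stop("'affected' contradicts the endorsement flags at row(s): ",
             paste(utils::head(mism, 5L), collapse = ", "), call. = FALSE)
    }
    relatives$affected <- derived
  } else {
    aff <- as.logical(relatives$affected)
    if (anyNA(aff))
      stop("unresolved affected status at row(s): ",
           paste(utils::head(which(is.na(aff)), 5L), collapse = ", "),
           call. = FALSE)
    relatives$affected <- aff
  }
  class(relatives) <- c("relative_table", "data.frame")
  invisible(relatives)
}

#' Dichotomous family-history indicator
#'
#' A participant is FH+ when one or more of their first-degree relatives is
#' classified affected. A participant with no interviewed relatives is FH-
#' (vacuous disjunction) and a warning is issued.
#'
#' @param affected Logical vector of resolved affected statuses for one
#'   participant's relatives; may be empty.
#' @return `TRUE` iff at least one relative is affected.
#' @examples
#' family_history(c(TRUE, FALSE)) # TRUE
#' family_history(logical(0))     # FALSE, with a warning
#' @export
family_history <- function(affected) {
  affected <- as.logical(affected)
  if (anyNA(affected))
    stop("unresolved affected status: family history undefined", call. = FALSE)
  if (length(affected) == 0L) {
    warning("empty family: family history set to FH-", call. = FALSE)
    return(FALSE)
  }
  any(affected)
}

#' Read / write relative-level CSV
#'
#' The interchange format is a UTF-8 CSV with a header row and columns
#' `proband_id`, `relation`, `age_years`, `endorsement_symptoms`,
#' `endorsement_treatment` and optionally `affected`; booleans are coded
#' 0/1. Reading validates the table and resolves affected status.
#'
#' @param path File path.
#' @return `read_relatives()`: a validated `relative_table` data frame.
#' @export
read_relatives <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- try(validate_relatives(df), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("schema error in ", path, ": ",
         conditionMessage(attr(out, "condition")), call. = FALSE)
  out
}

#' @rdname read_relatives
#' @param relatives A validated relative-level data frame.
#' @export
write_relatives <- function(relatives, path) {
  relatives <- validate_relatives(relatives)
  out <- relatives[intersect(c(.relative_required_cols, "affected"),
                             names(relatives))]
  for (col in c("endorsement_symptoms", "endorsement_treatment", "affected"))
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-relative classification report
#'
#' Produces a plain-text log listing, for each relative, the endorsement
#' flags and the resulting affected classification — an audit trail for the
#' two-criterion rule.
#'
#' @param relatives A relative-level data frame (validated if needed).
#' @return Character vector of report lines, invisibly; printed if
#'   `verbose = TRUE`.
#' @param verbose Print the report to the console.
#' @export
classification_report <- function(relatives, verbose = FALSE) {
  relatives <- validate_relatives(relatives)
  has_flags <- all(c("endorsement_symptoms", "endorsement_treatment") %in%
                     names(relatives))
  lines <- vapply(seq_len(nrow(relatives)), function(i) {
    r <- relatives[i, ]
    det <- if (has_flags)
      sprintf("symptoms=%d treatment=%d", as.integer(r$endorsement_symptoms),
              as.integer(r$endorsement_treatment))
    else "status supplied directly"
    sprintf("proband %s | %s, age %.0f | %s -> %s",
            r$proband_id, r$relation, r$age_years, det,
            if (r$affected) "AFFECTED" else "unaffected")
  }, character(1L))
  if (verbose) cat(lines, sep = "\n")
  invisible(lines)
}
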