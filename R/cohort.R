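# Cohort metadata and the feature table written by the pipeline.

maneuver_classes <- c("voluntary_cough", "throat_clearing", "reflexive_cough")
microphone_kinds <- c("free_standing", "skin_contact")
induction_methods <- c("none", "urge_to_cough", "suppressed")

#' Construct and validate a cohort table
#'
#' One row per recorded maneuver token: which file, which subject, which
#' maneuver class, which microphone channel, how the cough was induced (for
#' reflexive coughs), and the token index within subject and class. Mirrors
#' a study design in which each subject produces several voluntary coughs and
#' throat clearings and a small number of induced reflexive coughs.
#'
#' @param df data.frame with columns `file_id`, `subject`, `class`,
#'   `microphone`, `induction`, `token`.
#' @return The validated data.frame with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  required <- c("file_id", "subject", "class", "microphone", "induction", "token")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$class), maneuver_classes)
  if (length(bad))
    stop("unknown maneuver class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$microphone), microphone_kinds)
  if (length(bad))
    stop("unknown microphone kind: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$induction), induction_methods)
  if (length(bad))
    stop("unknown induction method: ", paste(bad, collapse = ", "))
  key <- paste(df$subject, df$class, df$microphone, df$token, sep = "\r")
  if (anyDuplicated(key))
    stop("(subject, class, microphone, token) rows are not unique")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Write a feature table to CSV
#'
#' All records must share one schema (identical column names in identical
#' order); values round-trip through [read_feature_table()] to at least
#' 12 significant digits.
#'
#' @param records a data.frame (one row per segment) or a list of such
#'   one-row data.frames sharing a schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records)) {
      schemas <- lapply(records, names)
      if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]])))
        stop("records have heterogeneous schemas")
      df <- do.call(rbind, lapply(records, as.data.frame))
    } else {
      df <- data.frame()
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = which(!num))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a cohort table as CSV
#' @param ct a [cohort_table()].
#' @param path CSV path.
#' @return `path` invisibly for the writer; a validated `cohort_table` for
#'   the reader.
#' @export
write_cohort_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
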