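#' @keywords internal
"_PACKAGE"

# Canonical vocabularies for the construct fields and terminal status.
.fixation_levels   <- c("cemented", "uncemented")
.bearing_levels    <- c("fixed", "mobile")
.constraint_levels <- c("CR", "PS")
.status_levels     <- c("revision", "death", "censored")
.gender_levels     <- c("F", "M", "unknown")

#' Registry CSV column schema
#'
#' Column names, in order, of the registry interchange CSV: one row per
#' primary procedure with its construct identity, optional demographics,
#' follow-up time in years and terminal status.
#'
#' @return Character vector of the nine column names.
#' @export
registry_schema <- function() {
  c("procedure_id", "brand", "fixation", "bearing", "constraint",
    "gender", "age_at_primary", "time_years", "status")
}

.canon <- function(x) tolower(trimws(as.character(x)))

.canon_enum <- function(x, levels, field, case = c("lower", "upper")) {
  case <- match.arg(case)
  xc <- .canon(x)
  key <- if (case == "upper") toupper(xc) else xc
  ok <- key %in% levels
  key[!ok] <- NA_character_
  key
}

#' Construct a validated registry
#'
#' Builds a `tkr_registry` from per-procedure vectors, canonicalising the
#' enum fields (case and surrounding whitespace are ignored on input) and
#' enforcing the row invariants: unique procedure identifiers,
#' non-negative follow-up times and a terminal status of `revision`
#' (first linked revision), `death` or `censored`. Deaths are kept
#' distinct from plain censoring in the schema although estimation treats
#' both as censoring events.
#'
#' @param procedure_id Unique identifier per primary procedure.
#' @param brand Prosthesis brand label.
#' @param fixation `"cemented"` or `"uncemented"`.
#' @param bearing `"fixed"` or `"mobile"`.
#' @param constraint `"CR"` (cruciate retaining) or `"PS"`
#'   (posterior stabilised).
#' @param gender `"F"`, `"M"` or `"unknown"` (default).
#' @param age_at_primary Age in years at the primary procedure; `NA`
#'   where unknown.
#' @param time_years Follow-up from primary to terminal status, in years.
#' @param status `"revision"`, `"death"` or `"censored"`.
#' @param lock_time Optional informational data-lock marker.
#'
#' @return A data frame of class `tkr_registry` with one row per
#'   procedure and a `construct` label column.
#' @export
tkr_registry <- function(procedure_id, brand, fixation, bearing, constraint,
                         gender = "unknown", age_at_primary = NA_real_,
                         time_years, status, lock_time = NULL) {
  n <- length(procedure_id)
  df <- data.frame(
    procedure_id = as.character(procedure_id),
    brand = trimws(as.character(rep_len(brand, n))),
    fixation = .canon_enum(rep_len(fixation, n), .fixation_levels, "fixation"),
    bearing = .canon_enum(rep_len(bearing, n), .bearing_levels, "bearing"),
    constraint = .canon_enum(rep_len(constraint, n), .constraint_levels,
                             "constraint", case = "upper"),
    gender = .canon_enum(rep_len(gender, n), tolower(.gender_levels), "gender"),
    age_at_primary = suppressWarnings(as.numeric(rep_len(age_at_primary, n))),
    time_years = suppressWarnings(as.numeric(rep_len(time_years, n))),
    status = .canon_enum(rep_len(status, n), .status_levels, "status"),
    stringsAsFactors = FALSE
  )
  # gender is stored in its display case (F/M/unknown)
  df$gender <- c(f = "F", m = "M", unknown = "unknown")[df$gender]

  bad <- .validate_registry_rows(df)
  if (length(bad$messages) > 0L) {
    stop("invalid registry rows:\n  ", paste(bad$messages, collapse = "\n  "),
         call. = FALSE)
  }
  df$construct <- construct_label(df$brand, df$fixation, df$bearing,
                                  df$constraint)
  structure(df, class = c("tkr_registry", "data.frame"),
            lock_time = lock_time)
}

# Returns row-level validation messages (empty when the registry is valid).
.validate_registry_rows <- function(df) {
  msgs <- character(0)
  flag <- function(idx, what) {
    if (any(idx)) {
      rows <- which(idx)
      shown <- paste(utils::head(rows, 10L), collapse = ", ")
      if (length(rows) > 10L) shown <- paste0(shown, ", ...")
      msgs <<- c(msgs, sprintf("%s (rows %s)", what, shown))
    }
  }
  flag(is.na(df$procedure_id) | df$procedure_id == "", "missing procedure_id")
  flag(duplicated(df$procedure_id), "duplicate procedure_id")
  flag(df$brand == "" | is.na(df$brand), "missing brand")
  flag(is.na(df$fixation), "fixation not one of cemented/uncemented")
  flag(is.na(df$bearing), "bearing not one of fixed/mobile")
  flag(is.na(df$constraint), "constraint not one of CR/PS")
  flag(is.na(df$gender), "gender not one of F/M/unknown")
  flag(is.na(df$time_years) | df$time_years < 0,
       "time_years missing or negative")
  flag(is.na(df$status), "status not one of revision/death/censored")
  list(messages = msgs)
}

#' Deterministic construct label
#'
#' Renders the four-field construct identity as a single label,
#' `brand/Bearing/Fixation/Constraint` (e.g. `"Duracon/Fixed/Cemented/CR"`).
#' Equal construct fields always render to the same label, so the label can
#' be used as a grouping key.
#'
#' @param brand,fixation,bearing,constraint Construct identity fields.
#' @return Character vector of labels.
#' @export
construct_label <- function(brand, fixation, bearing, constraint) {
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  paste(trimws(brand), cap(.canon(bearing)), cap(.canon(fixation)),
        toupper(trimws(constraint)), sep = "/")
}

#' Read a registry CSV
#'
#' Parses a registry interchange CSV (see [registry_schema()]) into a
#' validated [tkr_registry()]. Enum fields are canonicalised for case and
#' whitespace; malformed rows abort the read with their row numbers.
#'
#' @param path Path to a CSV file with the exact schema header.
#' @return A `tkr_registry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(registry_schema(), names(df))
  if (length(missing_cols) > 0L) {
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(empty_registry())
  age <- ifelse(trimws(df$age_at_primary) == "", NA_character_,
                df$age_at_primary)
  gender <- ifelse(trimws(df$gender) == "", "unknown", df$gender)
  tkr_registry(
    procedure_id = df$procedure_id,
    brand = df$brand, fixation = df$fixation, bearing = df$bearing,
    constraint = df$constraint, gender = gender,
    age_at_primary = as.numeric(age),
    time_years = as.numeric(df$time_years), status = df$status
  )
}

#' An empty registry
#'
#' @return A zero-row `tkr_registry` with the full column set.
#' @export
empty_registry <- function() {
  df <- data.frame(
    procedure_id = character(0), brand = character(0),
    fixation = character(0), bearing = character(0),
    constraint = character(0), gender = character(0),
    age_at_primary = numeric(0), time_years = numeric(0),
    status = character(0), construct = character(0),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("tkr_registry", "data.frame"), lock_time = NULL)
}

#' Write a registry CSV
#'
#' Writes the interchange CSV; optional missing ages become empty cells.
#' `read_registry(write_registry(r, f))` reproduces every field.
#'
#' @param registry A `tkr_registry`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "tkr_registry"))
  out <- as.data.frame(registry)[, registry_schema(), drop = FALSE]
  out$age_at_primary <- ifelse(is.na(out$age_at_primary), "",
                               format(out$age_at_primary, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Partition a registry by construct
#'
#' Splits the records into one group per distinct four-field construct
#' identity; every record falls in exactly one group.
#'
#' @param registry A `tkr_registry`.
#' @return Named list of data frames, keyed by construct label.
#' @export
group_by_construct <- function(registry) {
  stopifnot(inherits(registry, "tkr_registry"))
  if (nrow(registry) == 0L) return(structure(list(), names = character(0)))
  split(as.data.frame(registry), registry$construct)
}

#' @export
print.tkr_registry <- function(x, ...) {
  cat(sprintf("TKR registry: %d procedures, %d constructs\n",
              nrow(x), length(unique(x$construct))))
  if (nrow(x) > 0L) {
    tab <- table(x$status)
    cat("  status: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  follow-up: %.2f-%.2f years\n",
                min(x$time_years), max(x$time_years)))
  }
  invisible(x)
}
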