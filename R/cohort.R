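## Canonical longitudinal-cohort table layout and subject-series container.

#' Visit labels used throughout the package
#'
#' `base` is the preoperative visit (t = 0); `1pv`, `3pv`, `6pv` the nominal
#' 1-, 3- and 6-month postoperative visits; `FUpv` the final follow-up
#' (typically 12-29 months after surgery).
#' @export
VISIT_LABELS <- c("base", "1pv", "3pv", "6pv", "FUpv")

#' RNFL sector codes
#'
#' `G` global average plus the six circumpapillary sectors: temporal superior
#' (TS), temporal (T), temporal inferior (TI), nasal superior (NS), nasal (N)
#' and nasal inferior (NI).
#' @export
SECTOR_CODES <- c("G", "TS", "T", "TI", "NS", "N", "NI")

#' Measurement parameters understood by the rate machinery
#' @export
PARAMETERS <- c("IOP", "LCD", paste0("RNFL.", SECTOR_CODES))

COHORT_COLUMNS <- c("subject_id", "visit_label", "t_months", "iop_mmHg",
                    paste0("rnfl_", SECTOR_CODES), "lcd_um", "age_years",
                    "cct_um", "al_mm", "vf_md_db", "vf_psd_db", "surgery",
                    "n_meds")

#' Map a parameter name to its cohort-table column
#' @param parameter one of [PARAMETERS] (case-insensitive; `"rnfl_G"` style
#'   column names are also accepted).
#' @return column name in the canonical cohort table.
#' @export
parameter_column <- function(parameter) {
  key <- toupper(gsub("_", ".", parameter))
  map <- c(IOP = "iop_mmHg", LCD = "lcd_um",
           stats::setNames(paste0("rnfl_", SECTOR_CODES),
                           paste0("RNFL.", toupper(SECTOR_CODES))))
  col <- map[[key]]
  if (is.null(col)) stop("unknown parameter: ", parameter,
                         " (expected one of ", paste(PARAMETERS, collapse = ", "), ")")
  col
}

new_subject_series <- function(visits) {
  visits <- visits[order(visits$t_months), , drop = FALSE]
  rownames(visits) <- NULL
  sid <- visits$subject_id[1L]
  if (anyDuplicated(visits$visit_label))
    stop("subject ", sid, ": duplicate visit labels")
  bad <- setdiff(visits$visit_label, VISIT_LABELS)
  if (length(bad))
    stop("subject ", sid, ": unknown visit label(s) ", paste(bad, collapse = ", "))
  if (any(diff(visits$t_months) <= 0))
    stop("subject ", sid, ": t_months are not strictly increasing")
  canon <- match(visits$visit_label, VISIT_LABELS)
  if (any(diff(canon) <= 0))
    stop("subject ", sid,
         ": visit labels out of order relative to t_months (non-monotone schedule)")
  if ("base" %in% visits$visit_label &&
      visits$t_months[visits$visit_label == "base"] != 0)
    stop("subject ", sid, ": baseline visit must have t_months = 0")
  if (any(visits$t_months < 0))
    stop("subject ", sid, ": t_months must be >= 0")
  fu <- visits$t_months[visits$visit_label == "FUpv"]
  if (length(fu) && (fu < 12 || fu > 29))
    warning("subject ", sid, ": FUpv at ", fu,
            " months, outside the usual 12-29 month window", call. = FALSE)
  structure(list(subject_id = sid, visits = visits,
                 complete = stats::setNames(VISIT_LABELS %in% visits$visit_label,
                                            VISIT_LABELS)),
            class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("Subject '%s': %d visits (%s)%s\n", x$subject_id,
              nrow(x$visits), paste(x$visits$visit_label, collapse = ", "),
              if (all(x$complete)) "" else " [incomplete]"))
  invisible(x)
}

#' Build a cohort object from a long visit table
#'
#' @param data data.frame in the canonical cohort layout (see
#'   [read_cohort()] for the exact header).  Row and column order are
#'   irrelevant; missing optional columns are filled with `NA`.
#' @return An object of class `lcd_cohort`: a list of `subject_series`, with
#'   the canonical table retrievable via [cohort_frame()].
#' @export
as_lcd_cohort <- function(data) {
  if (inherits(data, "lcd_cohort")) return(data)
  if (inherits(data, "subject_series"))
    return(structure(list(data), class = "lcd_cohort"))
  data <- as.data.frame(data)
  missing_req <- setdiff(c("subject_id", "visit_label", "t_months"),
                         names(data))
  if (length(missing_req))
    stop("cohort table misses required column(s): ",
         paste(missing_req, collapse = ", "))
  for (col in setdiff(COHORT_COLUMNS, names(data)))
    data[[col]] <- if (col %in% c("surgery", "visit_label", "subject_id"))
      NA_character_ else NA_real_
  data <- data[, COHORT_COLUMNS]
  data$subject_id <- as.character(data$subject_id)
  data$visit_label <- as.character(data$visit_label)
  num_cols <- setdiff(COHORT_COLUMNS,
                      c("subject_id", "visit_label", "surgery"))
  for (col in num_cols) data[[col]] <- as.numeric(data[[col]])
  key <- paste(data$subject_id, data$visit_label)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit_label) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  series <- lapply(split(data, data$subject_id), new_subject_series)
  series <- series[order(names(series))]
  structure(unname(series), class = "lcd_cohort")
}

#' @export
print.lcd_cohort <- function(x, ...) {
  n_complete <- sum(vapply(x, function(s) all(s$complete), logical(1)))
  cat(sprintf("Longitudinal cohort: %d subjects (%d with all %d visits)\n",
              length(x), n_complete, length(VISIT_LABELS)))
  invisible(x)
}

#' Flatten a cohort back to the canonical long table
#' @param cohort an `lcd_cohort` (or anything [as_lcd_cohort()] accepts).
#' @return data.frame, one row per subject-visit, ordered by subject then
#'   time.
#' @export
cohort_frame <- function(cohort) {
  cohort <- as_lcd_cohort(cohort)
  out <- do.call(rbind, lapply(cohort, `[[`, "visits"))
  rownames(out) <- NULL
  out
}

#' Extract one subject's value of a parameter at a visit
#' @keywords internal
visit_value <- function(series, parameter, visit) {
  col <- parameter_column(parameter)
  i <- match(visit, series$visits$visit_label)
  if (is.na(i)) return(NA_real_)
  series$visits[[col]][i]
}

#' Read a longitudinal cohort CSV
#'
#' Expects the canonical header
#' `subject_id,visit_label,t_months,iop_mmHg,rnfl_G,rnfl_TS,rnfl_T,rnfl_TI,`
#' `rnfl_NS,rnfl_N,rnfl_NI,lcd_um,age_years,cct_um,al_mm,vf_md_db,vf_psd_db,`
#' `surgery,n_meds`; empty cells are missing values.  Row order is
#' irrelevant; visits are sorted by time within subject.  Subjects missing
#' visits (e.g. lost to follow-up) are kept and flagged incomplete.
#'
#' @param path CSV path.
#' @return An `lcd_cohort` object.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  as_lcd_cohort(data)
}

#' Write a cohort to the canonical CSV layout
#' @param cohort an `lcd_cohort` or canonical data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort_frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Ingest a supplementary spreadsheet (XLSX) as a cohort
#'
#' Reads an XLSX sheet whose layout is described by a user-supplied column
#' mapping, since deposited spreadsheets rarely follow the canonical header.
#' The mapping takes canonical column names to the sheet's column names
#' (`c(subject_id = "Patient", lcd_um = "LCD [um]", ...)`), or the path of a
#' `key=value` / JSON file with the same content.  Unmapped sheet columns are
#' reported via a message; unmapped *required* columns are an error listing
#' the sheet's candidate column names.
#'
#' @param path XLSX (or CSV) file path.
#' @param mapping named character vector, or path to a mapping file.
#' @param sheet sheet index or name (XLSX only).
#' @return An `lcd_cohort`; empty sheet gives an empty cohort with a warning.
#' @export
ingest_supplementary <- function(path, mapping, sheet = 1) {
  if (!file.exists(path)) stop("supplementary file not found: ", path)
  mapping <- read_column_mapping(mapping)
  raw <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
  } else {
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  check.names = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("supplementary sheet is empty", call. = FALSE)
    return(structure(list(), class = "lcd_cohort"))
  }
  required <- c("subject_id", "visit_label", "t_months")
  miss <- setdiff(required, names(mapping))
  miss <- union(miss, names(mapping)[!(mapping %in% names(raw))])
  miss <- intersect(miss, required)
  if (length(miss))
    stop("cannot map required column(s) ", paste(miss, collapse = ", "),
         "; sheet columns are: ", paste(names(raw), collapse = ", "))
  mapping <- mapping[mapping %in% names(raw)]
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  unmapped <- setdiff(names(raw), unname(mapping))
  if (length(unmapped))
    message("unmapped sheet column(s) ignored: ",
            paste(unmapped, collapse = ", "))
  as_lcd_cohort(out)
}

read_column_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping) &&
      is.null(names(mapping))) {
    txt <- readLines(mapping, warn = FALSE)
    if (any(grepl("^\\s*\\{", txt))) {
      m <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
      mapping <- unlist(m)
    } else {
      txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
      kv <- strsplit(txt, "=", fixed = TRUE)
      mapping <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                                 trimws(vapply(kv, `[`, "", 1L)))
    }
  }
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("mapping must be a named character vector or a mapping file")
  bad <- setdiff(names(mapping), COHORT_COLUMNS)
  if (length(bad))
    stop("mapping refers to unknown canonical column(s): ",
         paste(bad, collapse = ", "))
  mapping
}
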