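# Delimited-table I/O.  Canonical interchange is long-format delimited text
# (comma for .csv, tab otherwise), UTF-8, header required, '.' decimal point.

.sc_sep <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

.sc_read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, header = TRUE, sep = .sc_sep(path), quote = "\"",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

.sc_require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
}

#' Read water profiles from delimited tables
#'
#' Reads the canonical long-format inputs: one table of depth samples with
#' columns `subject_id`, `depth_um`, `water_masspct` (one row per depth
#' sample) and one table of TEWL measurements with columns `subject_id`,
#' `tewl` and optionally `group_label`.  Field separator is inferred from the
#' file extension (`.csv` comma, anything else tab).
#'
#' Every subject present in the water table must have a TEWL value; a missing
#' TEWL is an error naming the subject.  Subjects present in only one of the
#' two tables are reported via `message()`.
#'
#' @param source Path to the water concentration table.
#' @param tewl_source Path to the TEWL table.
#' @return A named list of [water_profile()] objects (names = subject ids),
#'   in the order subjects first appear in `source`.
#' @export
read_water_profiles <- function(source, tewl_source) {
  wt <- .sc_read_table(source)
  tt <- .sc_read_table(tewl_source)
  .sc_require_cols(wt, c("subject_id", "depth_um", "water_masspct"), source)
  .sc_require_cols(tt, c("subject_id", "tewl"), tewl_source)
  wt$subject_id <- as.character(wt$subject_id)
  tt$subject_id <- as.character(tt$subject_id)
  if (anyDuplicated(tt$subject_id))
    stop("duplicated subject_id in TEWL table: ",
         paste(unique(tt$subject_id[duplicated(tt$subject_id)]), collapse = ", "))

  subjects <- unique(wt$subject_id)
  only_water <- setdiff(subjects, tt$subject_id)
  only_tewl <- setdiff(tt$subject_id, subjects)
  if (length(only_tewl))
    message("subjects with TEWL but no water profile (skipped): ",
            paste(only_tewl, collapse = ", "))
  if (length(only_water))
    stop("missing TEWL for subject(s): ", paste(only_water, collapse = ", "))

  profiles <- vector("list", length(subjects))
  names(profiles) <- subjects
  for (s in subjects) {
    rows <- wt[wt$subject_id == s, , drop = FALSE]
    rows <- rows[order(rows$depth_um), , drop = FALSE]
    trow <- tt[tt$subject_id == s, , drop = FALSE]
    gl <- if ("group_label" %in% names(trow)) trow$group_label[1L] else NULL
    profiles[[s]] <- water_profile(s, rows$depth_um, rows$water_masspct,
                                   trow$tewl[1L], group_label = gl)
  }
  profiles
}

#' Write a pipeline product as a delimited table
#'
#' Accepts any of the pipeline's tabular products — a data frame, a single
#' profile-like object, or a list of them — converts via `as.data.frame()`
#' (stacking list elements row-wise), and writes delimited text with a header
#' row.  Numbers are written at full `as.character()` precision (15
#' significant digits), so a write/read round trip preserves values to at
#' least 12 significant digits.  An empty list writes a header-only file when
#' `template` names the columns.
#'
#' @param x Data frame, object with an `as.data.frame` method, or list of such.
#' @param destination Output path; separator inferred from the extension.
#' @param template Optional character vector of column names used when `x` is
#'   an empty list (header-only output).
#' @return `destination`, invisibly.
#' @export
write_profile_table <- function(x, destination, template = NULL) {
  df <- if (is.data.frame(x)) {
    x
  } else if (is.list(x) && !is.object(x)) {
    if (length(x) == 0L) {
      if (is.null(template))
        stop("empty product list needs a 'template' of column names")
      as.data.frame(setNames(rep(list(numeric(0)), length(template)), template))
    } else {
      do.call(rbind, lapply(x, as.data.frame))
    }
  } else {
    as.data.frame(x)
  }
  dir <- dirname(destination)
  if (!dir.exists(dir)) stop("unwritable destination: directory ", dir,
                             " does not exist")
  ok <- tryCatch({
    write.table(df, destination, sep = .sc_sep(destination), quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("unwritable destination ", destination, ": ",
                              conditionMessage(e)))
  invisible(destination)
}

#' Read back a table written by [write_profile_table()]
#'
#' @param path Path to a delimited table with a header row.
#' @return A data frame.
#' @export
read_profile_table <- function(path) .sc_read_table(path)
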