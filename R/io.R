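#' Read a summary-statistics table
#'
#' Reads a delimited text file with a header row containing a
#' `feature_id` column and exactly one statistic representation:
#' `z`, or (`beta`, `se`), or (`chisq`, `df`).  Optional `chromosome`
#' and `position` columns are carried through for plotting.  Validation
#' errors (duplicate identifiers, non-positive standard errors,
#' non-numeric cells) are reported with the offending line number
#' (1-based, counting the header as line 1).
#'
#' @param path file path.
#' @param dialect `"tsv"` (default, tab-separated) or `"csv"`.
#' @return a `data.frame` of class `summary_stats` with attribute
#'   `stat_type` in `c("z", "beta_se", "chisq_df")`.
#' @export
read_summary_stats <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = TRUE,
                           stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(tbl))
    stop("missing required column 'feature_id' in ", path)
  validate_summary_stats(tbl, path)
}

validate_summary_stats <- function(tbl, path = "<data>") {
  dup <- duplicated(tbl$feature_id)
  if (any(dup))
    stop("duplicated feature_id '", tbl$feature_id[dup][1], "' at line ",
         which(dup)[1] + 1L, " of ", path)
  reps <- list(z = "z", beta_se = c("beta", "se"), chisq_df = c("chisq", "df"))
  present <- vapply(reps, function(cols) all(cols %in% names(tbl)), logical(1))
  if (sum(present) != 1L)
    stop("expected exactly one statistic representation among ",
         "{z}, {beta, se}, {chisq, df}; found ",
         if (any(present)) paste(names(reps)[present], collapse = " and ")
         else "none", " in ", path)
  stat_type <- names(reps)[present]
  numeric_cols <- intersect(c(reps[[stat_type]], "position"), names(tbl))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- is.na(v) | (col != "position" & !is.finite(v))
    if (any(bad))
      stop("non-numeric or missing value in column '", col, "' at line ",
           which(bad)[1] + 1L, " of ", path)
    tbl[[col]] <- v
  }
  if (stat_type == "beta_se" && any(tbl$se <= 0))
    stop("non-positive se at line ", which(tbl$se <= 0)[1] + 1L, " of ", path)
  if (stat_type == "chisq_df" && any(tbl$chisq < 0))
    stop("negative chisq at line ", which(tbl$chisq < 0)[1] + 1L, " of ", path)
  attr(tbl, "stat_type") <- stat_type
  class(tbl) <- c("summary_stats", "data.frame")
  tbl
}

#' Extract z-scores from a summary-statistics table
#'
#' Converts whichever statistic representation the table carries to the
#' z-scale: `z` as is, `beta/se` as the Wald ratio, and `chisq` with
#' `df` through [transform_to_z].
#'
#' @param tbl a `summary_stats` table from [read_summary_stats].
#' @return a [zscores] object with feature identifiers attached.
#' @export
summary_stats_z <- function(tbl) {
  st <- attr(tbl, "stat_type")
  if (is.null(st)) stop("not a validated summary_stats table")
  z <- switch(st,
              z = tbl$z,
              beta_se = tbl$beta / tbl$se,
              chisq_df = {
                out <- numeric(nrow(tbl))
                for (d in unique(tbl$df)) {
                  i <- tbl$df == d
                  out[i] <- chisq_to_z(tbl$chisq[i], d)
                }
                out
              })
  zscores(z, feature_ids = tbl$feature_id)
}

#' Write a table as canonical TSV
#'
#' Tab-separated, header row, UTF-8, `.` decimal separator, full
#' double precision (values survive a write/read round trip to 1e-12
#' and better).
#'
#' @param tbl data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
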