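# Tabular I/O. CSV is the sole table format; the participant column schema
# is defined once here (and in the generator) and documented in
# read_participants().

#' Read / write participant tables
#'
#' CSV with header, decimal point, UTF-8. Columns: `id`, `group`
#' (`case`/`control`), `age` (years), `height_m`, `weight_kg`, regional fat
#' masses `fm_legs`, `fm_arms`, `fm_trunk`, `fm_android`, `fm_gynoid`,
#' `fm_head`, `fm_total` (kg), the analogous `lm_*` lean masses,
#' `bone_mass_total` (kg, total body excluding head), `bone_area_cm2`,
#' optional regional bone columns `bm_android`/`bm_gynoid`, and `type`
#' (I-V) / `stage` (1-4), present iff the row is a case. Records are
#' validated on read ([validate_participants()]); malformed rows are
#' reported with their ids, missing columns by name. `write_participants()`
#' writes at full double precision so a write/read round trip reproduces
#' every value.
#'
#' @param path CSV file path.
#' @param records Participant data frame.
#' @return `read_participants()`: validated data frame.
#'   `write_participants()`: `path`, invisibly.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(.participant_columns, c("bm_android", "bm_gynoid"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("participant file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  num_cols <- setdiff(names(df)[names(df) %in% .participant_columns],
                      c("id", "group", "type"))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(coerced))
      if (length(bad)) {
        stop("non-numeric value(s) in column '", cc, "' at data row(s) ",
             paste(head(bad, 5), collapse = ", "))
      }
      df[[cc]] <- coerced
    }
  }
  df$id <- as.character(df$id)
  df$type <- as.character(df$type)
  df$type[df$type %in% c("", "NA")] <- NA_character_
  df$stage <- as.integer(df$stage)
  validate_participants(df)
  df
}

#' @rdname read_participants
#' @export
write_participants <- function(records, path) {
  validate_participants(records)
  out <- records
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]])) {
      out[[cc]] <- format(out[[cc]], digits = 17, trim = TRUE,
                          scientific = FALSE)
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
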