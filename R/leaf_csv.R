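# leaf-record CSV dialect: comma-delimited, header mandatory, decimal
# point, empty field = missing measurement

LEAF_CSV_COLUMNS <- c("plant_id", "species", "genotype", "tln", "position",
                      "blade_length_mm", "blade_width_mm")

#' Read a leaf-measurement CSV
#'
#' Reads and validates the leaf-record CSV dialect: required columns
#' \code{plant_id, species, genotype, tln, position, blade_length_mm,
#' blade_width_mm}; species restricted to maize / sorghum / pearl_millet;
#' \code{tln} and \code{position} integers with \code{1 <= position <=
#' tln}; sizes positive mm or empty (missing). Offending rows are reported
#' with their file line numbers; in strict mode (default) any offence
#' aborts, in lenient mode offending rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @param strict abort on invalid rows (\code{TRUE}) or skip them
#'   (\code{FALSE}).
#' @return A validated data.frame of leaf records.
#' @export
read_leaf_csv <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop(sprintf("read_leaf_csv: file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(LEAF_CSV_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("read_leaf_csv: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[LEAF_CSV_COLUMNS]
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  out <- data.frame(plant_id = df$plant_id, species = df$species,
                    genotype = df$genotype,
                    tln = num(df$tln), position = num(df$position),
                    blade_length_mm = num(df$blade_length_mm),
                    blade_width_mm = num(df$blade_width_mm))

  line <- seq_len(nrow(out)) + 1L  # header is line 1
  problems <- character(0)
  bad <- rep(FALSE, nrow(out))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    if (any(cond))
      problems <<- c(problems,
                     sprintf("line %d: %s", line[cond], msg))
    bad <<- bad | cond
  }
  flag(!(out$species %in% SPECIES_IDS),
       "species must be one of maize, sorghum, pearl_millet")
  flag(is.na(out$tln) | out$tln != round(out$tln) | out$tln < 1,
       "tln must be a positive integer")
  flag(is.na(out$position) | out$position != round(out$position) |
         out$position < 1, "position must be a positive integer")
  flag(!is.na(out$tln) & !is.na(out$position) & out$position > out$tln,
       "position exceeds tln")
  flag(!is.na(out$blade_length_mm) & out$blade_length_mm <= 0,
       "blade_length_mm must be > 0 or empty")
  flag(!is.na(out$blade_width_mm) & out$blade_width_mm <= 0,
       "blade_width_mm must be > 0 or empty")

  if (length(problems)) {
    msg <- paste(problems, collapse = "\n  ")
    if (strict)
      stop(sprintf("read_leaf_csv: %d invalid row(s):\n  %s",
                   sum(bad), msg), call. = FALSE)
    warning(sprintf("read_leaf_csv: skipped %d invalid row(s):\n  %s",
                    sum(bad), msg), call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$tln <- as.integer(out$tln)
  out$position <- as.integer(out$position)
  rownames(out) <- NULL
  out
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "", format(signif(x, digits), trim = TRUE,
                              scientific = FALSE))
}

#' Write leaf records or a predicted profile as CSV
#'
#' Numeric measurement columns are written with 4 significant digits and
#' missing values as empty fields; rows are sorted so output is
#' byte-stable.
#'
#' @param records leaf-record data.frame (see [read_leaf_csv()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_leaf_csv <- function(records, path) {
  records <- as.data.frame(records)[LEAF_CSV_COLUMNS]
  records <- records[order(records$plant_id, records$position), , drop = FALSE]
  records$blade_length_mm <- fmt_num(records$blade_length_mm)
  records$blade_width_mm <- fmt_num(records$blade_width_mm)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_leaf_csv
#' @param profile a [predict_profile()] result.
#' @param units \code{"mm"} (default) or \code{"cm"}; centimetre output is
#'   a display rescaling only (cm for lengths, cm^2 for areas).
#' @export
write_profile_csv <- function(profile, path, units = c("mm", "cm")) {
  units <- match.arg(units)
  out <- as.data.frame(profile)
  if (units == "cm") {
    out$length_mm <- out$length_mm / 10
    out$width_mm <- out$width_mm / 10
    out$area_mm2 <- out$area_mm2 / 100
    names(out)[match(c("length_mm", "width_mm", "area_mm2"), names(out))] <-
      c("length_cm", "width_cm", "area_cm2")
  }
  num <- vapply(out, is.numeric, logical(1)) & !(names(out) %in% c("tln", "position"))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
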