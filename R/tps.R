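#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by common digitizing tools: each record is a
#' line `LM=<k>` followed by `<k>` whitespace-separated `x y` coordinate lines
#' and an optional `ID=<name>` line. `IMAGE=`/`SCALE=` and other `KEY=value`
#' lines are ignored. Both one-specimen-per-file and multi-specimen files are
#' supported.
#'
#' @param path path to a TPS file.
#' @param n_landmarks required landmark count per record (default 14, the
#'   hindwing template); `NULL` accepts any count. A record whose declared
#'   `LM=` count disagrees with this is an error.
#' @param variant optional variant label attached to every returned specimen.
#' @return a list of [landmark_set()] objects.
#' @export
read_tps <- function(path, n_landmarks = 14L, variant = NA_character_) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty TPS file: ", path)

  out <- list()
  i <- 1L
  record <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      stop("malformed TPS file: expected 'LM=' at line ", i)
    }
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    record <- record + 1L
    if (!is.null(n_landmarks) && k != n_landmarks) {
      stop("record ", record, " declares LM=", k, " landmarks; expected ",
           n_landmarks)
    }
    if (i + k > length(lines)) {
      stop("record ", record, ": fewer coordinate lines than LM=", k)
    }
    coord_lines <- lines[(i + 1L):(i + k)]
    bad <- !grepl("^[-+0-9.eE]+\\s+[-+0-9.eE]+$", coord_lines)
    if (any(bad)) {
      stop("record ", record, ": LM=", k,
           " but coordinate line ", which(bad)[1], " does not parse")
    }
    coords <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    i <- i + k + 1L
    id <- paste0("specimen_", record)
    while (i <= length(lines) && grepl("^[A-Za-z]+\\s*=", lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      }
      i <- i + 1L
    }
    out[[record]] <- landmark_set(id, variant, coords)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: one `LM=`/coordinates/`ID=` block per specimen,
#' coordinates at full precision so a write/read round trip is bit-exact.
#'
#' @param specimens a list of [landmark_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(specimens, path) {
  blocks <- vapply(specimens, function(s) {
    paste(c(sprintf("LM=%d", nrow(s$coords)),
            sprintf("%.17g %.17g", s$coords[, 1], s$coords[, 2]),
            sprintf("ID=%s", s$specimen_id)),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Write and read wing measurement tables
#'
#' Plain CSV with columns `specimen_id, variant, length_mm, width_mm,
#' area_mm2`.
#'
#' @param measurements a data frame as returned by [generate_measurements()].
#' @param path CSV path.
#' @return `write_measurements()`: `path` invisibly; `read_measurements()`:
#'   the measurement data frame.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("specimen_id", "variant", "length_mm", "width_mm", "area_mm2")
  stopifnot(all(cols %in% names(measurements)))
  write.csv(measurements[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("specimen_id", "variant", "length_mm", "width_mm", "area_mm2")
  if (!all(cols %in% names(df))) {
    stop("measurement CSV must have columns: ", paste(cols, collapse = ", "))
  }
  df
}
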