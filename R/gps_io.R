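#' Read and write GPS fix tables
#'
#' The on-disk dialect is a plain CSV with columns
#' `animal_id, herd, timestamp, x, y` (ISO-8601 UTC timestamps, projected
#' meters). `read_gps_csv()` also accepts real-data exports carrying at
#' least `animal_id, timestamp, x, y` (a missing `herd` column is filled
#' with `"unknown"`). Rows with unparsable timestamps or non-numeric
#' coordinates are dropped and reported with their file line numbers;
#' duplicate `(animal_id, timestamp)` rows keep the first occurrence. Fixes
#' are re-sorted by timestamp within animal on read.
#'
#' @param fixes data.frame with `animal_id, herd, timestamp, x, y`.
#' @param path file path.
#' @return `read_gps_csv()` returns the fix data.frame with an `issues`
#'   attribute: a data.frame of `(line, problem)` for every rejected or
#'   repaired row (empty when the file is clean).
#' @export
write_gps_csv <- function(fixes, path) {
  stopifnot(all(c("animal_id", "herd", "timestamp", "x", "y") %in%
                  names(fixes)))
  out <- data.frame(
    animal_id = fixes$animal_id,
    herd = fixes$herd,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = sprintf("%.3f", fixes$x),
    y = sprintf("%.3f", fixes$y)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gps_csv
#' @export
read_gps_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(raw))) {
    stop("GPS CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"herd" %in% names(raw)) raw$herd <- "unknown"
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  # per-row parsing: unparsable rows become NA instead of failing the read
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(raw$timestamp[need], fmt, tz = "UTC"))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))

  issues <- data.frame(line = integer(0), problem = character(0))
  bad_ts <- is.na(ts) & !is.na(raw$timestamp)
  bad_xy <- is.na(x) | is.na(y)
  if (any(bad_ts)) {
    issues <- rbind(issues, data.frame(line = line[bad_ts],
                                       problem = "unparsable timestamp"))
  }
  if (any(bad_xy & !bad_ts)) {
    issues <- rbind(issues,
                    data.frame(line = line[bad_xy & !bad_ts],
                               problem = "non-numeric coordinate"))
  }
  keep <- !bad_ts & !bad_xy
  fixes <- data.frame(animal_id = raw$animal_id[keep], herd = raw$herd[keep],
                      timestamp = ts[keep], x = x[keep], y = y[keep])
  line <- line[keep]

  ord <- order(fixes$animal_id, fixes$timestamp, line)
  fixes <- fixes[ord, ]
  line <- line[ord]
  dup <- duplicated(fixes[, c("animal_id", "timestamp")])
  if (any(dup)) {
    issues <- rbind(issues,
                    data.frame(line = line[dup],
                               problem = "duplicate (animal_id, timestamp); first kept"))
    fixes <- fixes[!dup, ]
  }
  rownames(fixes) <- NULL
  attr(fixes, "issues") <- issues[order(issues$line), , drop = FALSE]
  fixes
}
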