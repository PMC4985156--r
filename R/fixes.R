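#' Write GPS fixes as delimited text
#'
#' Writes the standard fix table `id,timestamp_utc,lon,lat,speed_kmh` with
#' ISO-8601 UTC timestamps and WGS84 decimal degrees.
#'
#' @param fixes Data frame with columns `id`, `timestamp` (POSIXct),
#'   `lon`, `lat`, `speed_kmh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  stopifnot(all(c("id", "timestamp", "lon", "lat", "speed_kmh") %in%
                  names(fixes)))
  out <- data.frame(
    id = fixes$id,
    timestamp_utc = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lon = sprintf("%.6f", fixes$lon),
    lat = sprintf("%.6f", fixes$lat),
    speed_kmh = sprintf("%.2f", fixes$speed_kmh))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate GPS fixes
#'
#' Reads a `id,timestamp_utc,lon,lat,speed_kmh` table, performing the
#' plausibility checks applied to raw logger data: malformed rows are logged
#' and skipped, fixes are sorted per individual, duplicate timestamps are
#' collapsed (first kept), and any fix whose implied ground speed from the
#' previously retained fix exceeds `max_speed` is dropped.
#'
#' @param path Input file.
#' @param max_speed Maximum plausible ground speed (km/h, default 150).
#' @return Named list of per-individual fix data frames (columns
#'   `id`, `timestamp`, `lon`, `lat`, `speed_kmh`), each of class
#'   `fix_series`, with a per-individual drop report in attribute
#'   `"report"` of the list.
#' @export
read_fixes <- function(path, max_speed = 150) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty fix file: ", path)
  need <- c("id", "timestamp_utc", "lon", "lat", "speed_kmh")
  if (!all(need %in% names(raw)))
    stop("fix file must have header ", paste(need, collapse = ","))

  ts <- as.POSIXct(strptime(raw$timestamp_utc, "%Y-%m-%dT%H:%M:%OSZ",
                            tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt))
    ts[alt] <- as.POSIXct(strptime(raw$timestamp_utc[alt],
                                   "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  spd <- suppressWarnings(as.numeric(raw$speed_kmh))
  ok <- !is.na(ts) & !is.na(lon) & !is.na(lat) & !is.na(spd) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90 & spd >= 0
  n_malformed <- sum(!ok)
  if (n_malformed)
    message(n_malformed, " malformed row(s) skipped in ", basename(path))
  df <- data.frame(id = raw$id[ok], timestamp = ts[ok], lon = lon[ok],
                   lat = lat[ok], speed_kmh = spd[ok])

  series <- split(df, df$id)
  report <- list()
  out <- list()
  for (id in names(series)) {
    s <- series[[id]]
    s <- s[order(s$timestamp), ]
    dup <- duplicated(s$timestamp)
    n_dup <- sum(dup)
    s <- s[!dup, ]
    # greedy forward pass: drop fixes implying ground speed > max_speed
    keep <- rep(TRUE, nrow(s))
    last <- 1L
    for (j in seq_len(nrow(s))[-1]) {
      dt_h <- as.numeric(difftime(s$timestamp[j], s$timestamp[last],
                                  units = "hours"))
      d_km <- gc_dist_km(s$lon[last], s$lat[last], s$lon[j], s$lat[j])
      if (dt_h > 0 && d_km / dt_h > max_speed) keep[j] <- FALSE
      else last <- j
    }
    n_speed <- sum(!keep)
    s <- s[keep, ]
    rownames(s) <- NULL
    class(s) <- c("fix_series", class(s))
    out[[id]] <- s
    report[[id]] <- data.frame(id = id, n_kept = nrow(s), n_duplicates = n_dup,
                               n_speed_dropped = n_speed)
  }
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  if (any(rep_df$n_duplicates > 0 | rep_df$n_speed_dropped > 0))
    message("dropped ", sum(rep_df$n_duplicates), " duplicate and ",
            sum(rep_df$n_speed_dropped), " implausible-speed fix(es)")
  attr(out, "report") <- rep_df
  out
}
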