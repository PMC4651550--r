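#' Plain-text input/output
#'
#' Tracks travel as CSV with ISO-8601 timestamps, configurations as JSON,
#' and ice stacks as one CSV grid per day plus a JSON index. Internally
#' time is numeric study days on a 365-day calendar; on disk a (non-leap)
#' base year anchors the timestamps.
#'
#' @name io
NULL

study_day_to_date <- function(t, base_year = 1990) {
  as.POSIXct((t - 1) * 86400,
             origin = sprintf("%d-01-01", base_year), tz = "UTC")
}

date_to_study_day <- function(ts, base_year = 1990) {
  origin <- as.POSIXct(sprintf("%d-01-01", base_year), tz = "UTC")
  as.numeric(difftime(as.POSIXct(ts, tz = "UTC"), origin, units = "days")) + 1
}

#' Write and read tracks as CSV
#'
#' Columns: `id`, `timestamp` (ISO-8601 UTC), `x_km`, `y_km`, `class`,
#' plus `period` so a round trip is lossless for the fields the analysis
#' needs. Sensor series are not serialized here.
#'
#' @param tracks list of `bear_track`s.
#' @param path CSV file path.
#' @param base_year anchor year for timestamps (non-leap).
#' @return `read_tracks_csv()` returns a list of `bear_track`s.
#' @export
write_tracks_csv <- function(tracks, path, base_year = 1990) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = tr$bear_id, period = tr$period,
               timestamp = format(study_day_to_date(tr$fixes$time, base_year),
                                  "%Y-%m-%dT%H:%M:%SZ"),
               x_km = tr$fixes$x, y_km = tr$fixes$y,
               class = tr$fixes$class)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, base_year = 1990) {
  df <- utils::read.csv(path, colClasses = c(class = "character"))
  lapply(split(df, df$id), function(d) {
    d <- d[order(d$timestamp), ]
    make_track(d$id[1], d$period[1],
               data.frame(time = date_to_study_day(d$timestamp, base_year),
                          x = d$x_km, y = d$y_km, class = d$class))
  })
}

#' Write and read a simulation configuration as JSON
#'
#' @param config a `sim_config`.
#' @param path JSON file path.
#' @return `read_config()` returns a validated `sim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  # jsonlite drops names of atomic vectors; keep them as JSON objects
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(keep_names(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  # named scalar collections come back as named lists; coerce to vectors
  revector <- function(v) {
    if (is.list(v) && !is.null(names(v)) &&
        all(vapply(v, function(e) is.numeric(e) && length(e) == 1,
                   logical(1))))
      return(unlist(v))
    if (is.list(v)) return(lapply(v, revector))
    v
  }
  args <- lapply(raw, revector)
  fml <- names(formals(sim_config))
  do.call(sim_config, args[names(args) %in% fml])
}

#' Write an ice stack as daily CSV grids with a JSON index
#'
#' One `conc_DDD.csv` matrix per day under `dir`, plus `index.json`
#' recording dates, grid geometry and mask files.
#'
#' @param stack an `ice_stack`.
#' @param dir output directory (created if needed).
#' @export
write_ice_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$dates)) {
    utils::write.table(stack$conc[, , i],
                       file.path(dir, sprintf("conc_%03d.csv", stack$dates[i])),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(stack$land_mask * 1L, file.path(dir, "land_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(stack$shelf_mask * 1L, file.path(dir, "shelf_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(dates = stack$dates, cell_km = stack$cell_km,
         x_centers = stack$x_centers, y_centers = stack$y_centers,
         year = stack$year,
         files = sprintf("conc_%03d.csv", stack$dates)),
    file.path(dir, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write bear-year summaries as CSV
#'
#' @param report a `study_report`.
#' @param path CSV file path.
#' @export
write_summaries_csv <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  utils::write.csv(report$summaries, path, row.names = FALSE)
  invisible(path)
}
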