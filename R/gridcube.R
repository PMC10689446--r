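#' Gridded variable cube
#'
#' Container for one variable on a regular lat/lon grid over time: a
#' `time x lat x lon` array plus units, a strictly increasing time axis
#' (calendar years for growing-season aggregates, or month indices), and a
#' per-pixel validity mask. Latitudes supplied descending are normalized to
#' ascending order (with the data reordered to match), so all cubes in one
#' analysis share an orientation.
#'
#' @param values Numeric array `[time, lat, lon]`.
#' @param time_axis Strictly increasing numeric time coordinate.
#' @param lat,lon Cell-center coordinates.
#' @param units Unit string (e.g. `"hPa"`).
#' @param valid_mask Logical `[lat, lon]` matrix; default all valid.
#' @return An object of class `grid_cube`.
#' @export
grid_cube <- function(values, time_axis, lat, lon, units = "",
                      valid_mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("`values` must be time x lat x lon", call. = FALSE)
  d <- dim(values)
  if (d[1] != length(time_axis) || d[2] != length(lat) || d[3] != length(lon)) {
    stop("dimension mismatch between `values` and coordinates", call. = FALSE)
  }
  if (any(diff(time_axis) <= 0)) stop("`time_axis` must be strictly increasing", call. = FALSE)
  if (length(lat) > 1 && all(diff(lat) < 0)) {
    o <- rev(seq_along(lat))
    lat <- lat[o]
    values <- values[, o, , drop = FALSE]
    if (!is.null(valid_mask)) valid_mask <- valid_mask[o, , drop = FALSE]
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[2], d[3])
  structure(
    list(values = values, time_axis = as.numeric(time_axis),
         lat = as.numeric(lat), lon = as.numeric(lon),
         units = units, valid_mask = valid_mask),
    class = "grid_cube"
  )
}

#' @export
print.grid_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_cube> %d time x %d lat x %d lon [%s], %d/%d valid pixels\n",
              d[1], d[2], d[3], x$units, sum(x$valid_mask), d[2] * d[3]))
  invisible(x)
}

#' @export
dim.grid_cube <- function(x) dim(x$values)

# Stop unless all cubes share grid and time axis.
check_aligned <- function(...) {
  cubes <- list(...)
  ref <- cubes[[1]]
  for (cb in cubes[-1]) {
    if (!isTRUE(all.equal(ref$lat, cb$lat)) ||
        !isTRUE(all.equal(ref$lon, cb$lon)) ||
        !isTRUE(all.equal(ref$time_axis, cb$time_axis))) {
      stop("grid cubes are not aligned (lat/lon/time mismatch)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write / read a grid cube as long-format CSV
#'
#' Plain-text serialization: one row per (time, lat, lon) cell with the value
#' and validity flag, units carried in a header comment. Round-trips through
#' [read_grid_cube()] bit-exactly for masks and to full double precision for
#' values.
#'
#' @param cube A `grid_cube`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_cube <- function(cube, path) {
  d <- dim(cube$values)
  df <- data.frame(
    time = rep(cube$time_axis, times = d[2] * d[3]),
    lat = rep(rep(cube$lat, each = d[1]), times = d[3]),
    lon = rep(cube$lon, each = d[1] * d[2]),
    value = as.vector(cube$values),
    valid = rep(as.vector(cube$valid_mask), each = d[1])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", cube$units), con)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_cube
#' @export
read_grid_cube <- function(path) {
  first <- readLines(path, n = 1)
  units <- sub("^# units: ?", "", first)
  df <- utils::read.csv(path, comment.char = "#")
  time_axis <- sort(unique(df$time))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  o <- order(df$lon, df$lat, df$time)
  df <- df[o, ]
  values <- array(df$value, dim = c(length(time_axis), length(lat), length(lon)))
  vm <- matrix(df$valid[seq(1, nrow(df), by = length(time_axis))],
               nrow = length(lat))
  grid_cube(values, time_axis, lat, lon, units = units,
            valid_mask = vm)
}
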