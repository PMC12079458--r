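# Localization table I/O.
#
# The canonical on-disk dialect is the ThunderSTORM CSV export
# ("frame","x [nm]","y [nm]","intensity [photon]"); a generic dialect with a
# user-supplied column map covers other exports.  In memory a localization
# table is a plain data.frame (frame, x, y, intensity, unknown columns kept)
# of class "loc_table" carrying frame_interval_s and fov bounds as attributes.

#' @keywords internal
as_loc_table <- function(df, frame_interval_s = 30, fov_size = NULL) {
  stopifnot(all(c("frame", "x", "y", "intensity") %in% names(df)))
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "frame_interval_s") <- frame_interval_s
  attr(df, "fov_size") <- fov_size
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Frame interval of a localization table
#' @param table a `loc_table`.
#' @param default value used when the table carries no interval.
#' @return frame interval in seconds.
#' @export
frame_interval <- function(table, default = 30) {
  fi <- attr(table, "frame_interval_s")
  if (is.null(fi)) default else fi
}

#' Acquisition time of each localization
#'
#' Frames are 1-based (ThunderSTORM convention); frame f maps to time
#' `(f - 1) * frame_interval`.
#'
#' @inheritParams frame_interval
#' @return numeric vector of times in seconds.
#' @export
loc_times <- function(table, default = 30)
  (table$frame - 1) * frame_interval(table, default)

ts_header <- c("frame", "x [nm]", "y [nm]", "intensity [photon]")

#' Read a localization table
#'
#' @param path CSV file path.
#' @param dialect `"thunderstorm"` (quoted `"x [nm]"` style header) or
#'   `"generic"` with an explicit `column_map`.
#' @param column_map named list/vector mapping canonical names (`frame`, `x`,
#'   `y`, `intensity`) to the file's column names (generic dialect).
#' @param frame_interval_s acquisition frame interval attached to the table, s.
#' @return a `loc_table` data.frame with columns `frame`, `x`, `y`,
#'   `intensity` in nm/photons; unknown columns are preserved untouched.
#' @export
read_localizations <- function(path,
                               dialect = c("thunderstorm", "generic"),
                               column_map = NULL, frame_interval_s = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_localizations: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  map <- if (dialect == "thunderstorm") {
    c(frame = "frame", x = "x [nm]", y = "y [nm]",
      intensity = "intensity [photon]")
  } else {
    if (is.null(column_map))
      stop("read_localizations: generic dialect needs a column_map")
    unlist(column_map)
  }
  missing <- setdiff(names(map), c("frame", "x", "y", "intensity"))
  if (length(missing))
    stop("read_localizations: unknown canonical column(s) in map: ",
         paste(missing, collapse = ", "))
  for (canon in c("frame", "x", "y", "intensity")) {
    col <- map[[canon]]
    if (is.null(col) || !col %in% names(df))
      stop("read_localizations: required column missing: ",
           if (is.null(col)) canon else col)
  }
  out <- df[, unname(map[c("frame", "x", "y", "intensity")]), drop = FALSE]
  names(out) <- c("frame", "x", "y", "intensity")
  for (j in names(out)) {
    v <- out[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("read_localizations: non-numeric value in column '", j,
             "' at data line ", bad[1L], " (file line ", bad[1L] + 1L, ")")
      out[[j]] <- vn
    }
  }
  if (nrow(out)) {
    if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
      stop("read_localizations: non-finite coordinates")
    if (any(out$intensity < 0, na.rm = TRUE))
      stop("read_localizations: negative intensities")
  }
  extras <- setdiff(names(df), unname(map))
  if (length(extras)) out[extras] <- df[extras]
  as_loc_table(out, frame_interval_s)
}

#' Write a localization table (ThunderSTORM dialect)
#'
#' @param table a `loc_table` or data.frame with frame/x/y/intensity.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)[, c("frame", "x", "y", "intensity")]
  names(df) <- ts_header
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read a ground-truth sidecar (localization row -> aggregate id)
#'
#' @param aggregate_id integer vector, 0 = noise, aligned with the
#'   localization table's rows.
#' @param path CSV path.
#' @return `path` (write) or an integer vector (read).
#' @export
write_ground_truth <- function(aggregate_id, path) {
  utils::write.csv(data.frame(row = seq_along(aggregate_id),
                              aggregate_id = aggregate_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path)
  df$aggregate_id[order(df$row)]
}

#' Write turbidity data (long format)
#' @param df data.frame with condition, replicate, time_min, absorbance.
#' @param path CSV path.
#' @export
write_turbidity <- function(df, path) {
  utils::write.csv(df[, c("condition", "replicate", "time_min", "absorbance")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Render a reconstruction image
#'
#' 2D histogram of all localizations acquired up to `t_max`, on a half-open
#' `[k*pixel, (k+1)*pixel)` grid anchored at the field-of-view lower-left
#' corner.  This replaces external rendering tools for documentation figures.
#'
#' @param table a `loc_table`.
#' @param pixel_nm pixel size, nm (> 0).
#' @param t_max only localizations with `(frame-1)*frame_interval <= t_max`
#'   are rendered; `Inf` renders everything.
#' @param weighted if `TRUE`, pixels accumulate photon counts instead of
#'   localization counts.
#' @param bounds optional `list(x = c(lo, hi), y = c(lo, hi))`; defaults to
#'   the table's field of view or data range.
#' @return numeric matrix (rows = x bins, cols = y bins) with attributes
#'   `pixel_nm` and `origin`.
#' @export
render_reconstruction <- function(table, pixel_nm, t_max = Inf,
                                  weighted = FALSE, bounds = NULL) {
  if (pixel_nm <= 0) stop("render_reconstruction: pixel_nm must be > 0")
  if (is.null(bounds)) {
    fov <- attr(table, "fov_size")
    bounds <- if (!is.null(fov)) list(x = c(0, fov[1L]), y = c(0, fov[2L]))
    else if (nrow(table)) list(x = range(table$x), y = range(table$y))
    else list(x = c(0, pixel_nm), y = c(0, pixel_nm))
  }
  nx <- max(1L, ceiling((bounds$x[2L] - bounds$x[1L]) / pixel_nm))
  ny <- max(1L, ceiling((bounds$y[2L] - bounds$y[1L]) / pixel_nm))
  img <- matrix(0, nx, ny)
  keep <- loc_times(table) <= t_max
  t2 <- table[keep, , drop = FALSE]
  if (nrow(t2)) {
    ix <- floor((t2$x - bounds$x[1L]) / pixel_nm) + 1
    iy <- floor((t2$y - bounds$y[1L]) / pixel_nm) + 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    w <- if (weighted) t2$intensity[ok] else rep.int(1, sum(ok))
    if (any(ok)) {
      idx <- (iy[ok] - 1) * nx + ix[ok]
      tab <- rowsum(w, idx)
      img[as.integer(rownames(tab))] <- tab[, 1L]
    }
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "origin") <- c(bounds$x[1L], bounds$y[1L])
  img
}
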