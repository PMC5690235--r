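#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Rasters are serialized in the plain-text ESRI ASCII grid format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value`
#' header followed by rows north to south), which every desktop GIS reads.
#' Non-finite values (barriers, unreachable cells) are stored as the
#' no-data sentinel and restored as `Inf` on read, so a pace or
#' travel-time grid round-trips exactly.
#'
#' @param g an [emoc_grid()].
#' @param path file path (conventionally `.asc`).
#' @param nodata sentinel written for non-finite cells.
#' @return `write_grid_asc` returns `path` invisibly; `read_grid_asc`
#'   returns an `emoc_grid`.
#' @export
write_grid_asc <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "emoc_grid"))
  v <- g$values
  storage.mode(v) <- "double"
  v[!is.finite(v)] <- nodata
  ext <- grid_extent(g)
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", ext[["xmin"]]),
    sprintf("yllcorner %.10g", ext[["ymin"]]),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- as.numeric(kv[, 2])
  names(val) <- tolower(kv[, 1])
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("raster body has %d values, expected %d x %d",
                 length(body), nr, nc))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- Inf
  emoc_grid(m, cellsize = val[["cellsize"]], xmin = val[["xllcorner"]],
            ymax = val[["yllcorner"]] + nr * val[["cellsize"]])
}

#' Read and write road networks and point sets as GeoJSON
#'
#' Roads are a `FeatureCollection` of `LineString`s with a `class`
#' property (4 local, 5 provincial, 6 national); facilities and dwellings
#' are `Point` features (`tier` property for facilities). Coordinates are
#' planar metres in the grid frame.
#'
#' @param roads a road network as returned by [gen_roads()].
#' @param path file path.
#' @return readers return the corresponding package object.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads$lines, function(ln) {
    list(type = "Feature",
         properties = list(class = ln$class),
         geometry = list(type = "LineString",
                         coordinates = apply(ln$coords, 1L, as.numeric,
                                             simplify = FALSE)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lines <- lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    if (is.null(f$properties$class))
      stop(sprintf("feature %d has no `class` property", i))
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) as.numeric(unlist(p))))
    list(coords = coords, class = as.integer(f$properties$class))
  })
  structure(list(lines = lines), class = "emoc_roads")
}

#' @param points matrix of world coordinates (one row per point).
#' @param properties optional data.frame of per-point properties
#'   (e.g. `tier`).
#' @rdname write_roads_geojson
#' @export
write_points_geojson <- function(points, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(points)), function(i) {
    props <- if (is.null(properties)) structure(list(), names = character())
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = as.numeric(points[i, ])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  pts <- do.call(rbind, lapply(fc$features, function(f)
    as.numeric(unlist(f$geometry$coordinates))))
  props <- lapply(fc$features, function(f) f$properties)
  tier <- vapply(props, function(p)
    if (is.null(p$tier)) NA_character_ else as.character(p$tier), "")
  out <- data.frame(x = pts[, 1], y = pts[, 2])
  if (!all(is.na(tier))) out$tier <- tier
  out
}
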