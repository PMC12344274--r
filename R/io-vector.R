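#' Vector feature layer
#'
#' A homogeneous GIS layer: point or line geometries with per-feature
#' attributes, on WGS84 (EPSG:4326).  Geometries are stored as
#' `c(lat, lon)` for points and as an `n x 2` matrix with columns
#' `lat, lon` for lines; writers emit the GeoJSON `lon, lat` axis order.
#'
#' @param name layer name.
#' @param geometry_type `"point"` or `"line"`.
#' @param features list of features, each a list with `geometry` and
#'   `attributes` (a named list that must include `image_id`).
#' @param crs CRS identifier (only `"EPSG:4326"` is written).
#' @return An object of class `geo_feature_set`.
#' @export
geo_feature_set <- function(name, geometry_type = c("point", "line"),
                            features = list(), crs = "EPSG:4326") {
  geometry_type <- match.arg(geometry_type)
  for (f in features) {
    if (is.null(f$attributes$image_id))
      stop("every feature must carry an image_id attribute")
  }
  structure(list(name = name, geometry_type = geometry_type,
                 features = features, crs = crs),
            class = "geo_feature_set")
}

#' @export
print.geo_feature_set <- function(x, ...) {
  cat(sprintf("<geo_feature_set '%s': %d %s feature(s), %s>\n",
              x$name, length(x$features), x$geometry_type, x$crs))
  invisible(x)
}

features_attr_df <- function(fs) {
  if (length(fs$features) == 0L)
    return(data.frame(image_id = character(), stringsAsFactors = FALSE))
  keys <- unique(unlist(lapply(fs$features, function(f) names(f$attributes))))
  df <- as.data.frame(lapply(keys, function(k)
    sapply(fs$features, function(f) {
      v <- f$attributes[[k]]
      if (is.null(v)) NA else v
    })), stringsAsFactors = FALSE)
  names(df) <- keys
  df
}

#' Write a vector layer
#'
#' GeoJSON (RFC 7946, the canonical lossless output) or ESRI Shapefile
#' (best-effort dialect: single geometry type, attribute names truncated
#' to 10 characters with a JSON manifest of renames written alongside).
#'
#' @param fs a [geo_feature_set()].
#' @param path output path; the shapefile writer derives `.shx`, `.dbf`
#'   and `.prj` paths from it.
#' @param format `"geojson"` or `"shapefile"` (default from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
write_vector <- function(fs, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     geojson = , json = "geojson", shp = "shapefile",
                     stop("cannot infer format from extension of ", path))
  }
  switch(match.arg(format, c("geojson", "shapefile")),
         geojson = write_geojson(fs, path),
         shapefile = write_shapefile(fs, path))
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  switch(tolower(tools::file_ext(path)),
         geojson = , json = read_geojson(path),
         shp = read_shapefile(path),
         stop("cannot infer format from extension of ", path))
}

# ---- GeoJSON ---------------------------------------------------------------

write_geojson <- function(fs, path) {
  feat <- lapply(fs$features, function(f) {
    geom <- if (fs$geometry_type == "point") {
      list(type = "Point",
           coordinates = c(f$geometry[["lon"]], f$geometry[["lat"]]))
    } else {
      list(type = "LineString",
           coordinates = unname(cbind(f$geometry[, "lon"], f$geometry[, "lat"])))
    }
    list(type = "Feature", geometry = geom, properties = f$attributes)
  })
  doc <- list(type = "FeatureCollection", name = fs$name, features = feat)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  gtype <- NULL
  feats <- lapply(doc$features, function(f) {
    g <- f$geometry
    if (g$type == "Point") {
      gtype <<- "point"
      geom <- c(lat = g$coordinates[[2]], lon = g$coordinates[[1]])
    } else if (g$type == "LineString") {
      gtype <<- "line"
      m <- do.call(rbind, lapply(g$coordinates, function(p)
        c(lat = p[[2]], lon = p[[1]])))
      geom <- m
    } else stop("unsupported geometry type: ", g$type)
    list(geometry = geom, attributes = f$properties)
  })
  geo_feature_set(if (is.null(doc$name)) "layer" else doc$name,
                  if (is.null(gtype)) "point" else gtype, feats)
}

# ---- ESRI Shapefile --------------------------------------------------------

wgs84_wkt <- paste0(
  'GEOGCS["GCS_WGS_1984",DATUM["D_WGS_1984",SPHEROID["WGS_1984",',
  '6378137.0,298.257223563]],PRIMEM["Greenwich",0.0],',
  'UNIT["Degree",0.0174532925199433]]')

shp_header <- function(con, file_length_words, shape_type, bbox) {
  writeBin(9994L, con, size = 4, endian = "big")
  writeBin(integer(5), con, size = 4, endian = "big")
  writeBin(as.integer(file_length_words), con, size = 4, endian = "big")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(as.integer(shape_type), con, size = 4, endian = "little")
  writeBin(c(bbox, 0, 0, 0, 0), con, size = 8, endian = "little")
}

write_shapefile <- function(fs, path) {
  base <- tools::file_path_sans_ext(path)
  pts_of <- function(f) {
    if (fs$geometry_type == "point")
      matrix(c(f$geometry[["lon"]], f$geometry[["lat"]]), 1,
             dimnames = list(NULL, c("lon", "lat")))
    else cbind(lon = f$geometry[, "lon"], lat = f$geometry[, "lat"])
  }
  n <- length(fs$features)
  shape_type <- if (fs$geometry_type == "point") 1L else 3L
  all_pts <- if (n > 0) do.call(rbind, lapply(fs$features, pts_of)) else
    matrix(0, 0, 2, dimnames = list(NULL, c("lon", "lat")))
  bbox <- if (nrow(all_pts) > 0)
    c(min(all_pts[, 1]), min(all_pts[, 2]), max(all_pts[, 1]), max(all_pts[, 2]))
  else c(0, 0, 0, 0)

  contents <- lapply(fs$features, function(f) {
    p <- pts_of(f)
    if (shape_type == 1L) {
      len_words <- 10L  # type + x + y
    } else {
      len_words <- (4L + 32L + 8L + 4L + 16L * nrow(p)) / 2L
    }
    list(p = p, len_words = as.integer(len_words))
  })
  total_words <- 50L + sum(vapply(contents, function(cn)
    4L + cn$len_words, integer(1)))

  con <- file(paste0(base, ".shp"), "wb")
  shp_header(con, total_words, shape_type, bbox)
  offsets <- integer(n)
  pos <- 50L
  for (i in seq_len(n)) {
    cn <- contents[[i]]
    offsets[i] <- pos
    writeBin(i, con, size = 4, endian = "big")
    writeBin(cn$len_words, con, size = 4, endian = "big")
    writeBin(shape_type, con, size = 4, endian = "little")
    if (shape_type == 1L) {
      writeBin(as.numeric(cn$p[1, ]), con, size = 8, endian = "little")
    } else {
      writeBin(c(min(cn$p[, 1]), min(cn$p[, 2]),
                 max(cn$p[, 1]), max(cn$p[, 2])), con, size = 8,
               endian = "little")
      writeBin(1L, con, size = 4, endian = "little")          # numparts
      writeBin(nrow(cn$p), con, size = 4, endian = "little")  # numpoints
      writeBin(0L, con, size = 4, endian = "little")          # part start
      writeBin(as.numeric(t(cn$p)), con, size = 8, endian = "little")
    }
    pos <- pos + 4L + cn$len_words
  }
  close(con)

  con <- file(paste0(base, ".shx"), "wb")
  shp_header(con, 50L + 4L * n, shape_type, bbox)
  for (i in seq_len(n)) {
    writeBin(offsets[i], con, size = 4, endian = "big")
    writeBin(contents[[i]]$len_words, con, size = 4, endian = "big")
  }
  close(con)

  df <- features_attr_df(fs)
  renames <- list()
  nm <- names(df)
  short <- substr(nm, 1, 10)
  short <- make.unique(substr(short, 1, 10), sep = "")
  for (i in seq_along(nm)) if (short[i] != nm[i]) renames[[short[i]]] <- nm[i]
  names(df) <- short
  if (nrow(df) == 0L) df <- data.frame(image_id = "")[0, , drop = FALSE]
  # write.dbf warns computing field widths for empty tables
  suppressWarnings(foreign::write.dbf(df, paste0(base, ".dbf")))
  writeLines(wgs84_wkt, paste0(base, ".prj"))
  if (length(renames) > 0)
    jsonlite::write_json(renames, paste0(base, ".fieldnames.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_shapefile <- function(path) {
  base <- tools::file_path_sans_ext(path)
  con <- file(paste0(base, ".shp"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, 4, endian = "big")
  if (magic != 9994L) stop("not a shapefile: ", path)
  readBin(con, "integer", 5, 4, endian = "big")
  file_words <- readBin(con, "integer", 1, 4, endian = "big")
  readBin(con, "integer", 1, 4, endian = "little")  # version
  shape_type <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "numeric", 8, 8, endian = "little")  # bbox
  geoms <- list()
  pos <- 50L
  while (pos < file_words) {
    readBin(con, "integer", 1, 4, endian = "big")   # record number
    len <- readBin(con, "integer", 1, 4, endian = "big")
    rtype <- readBin(con, "integer", 1, 4, endian = "little")
    if (rtype == 1L) {
      xy <- readBin(con, "numeric", 2, 8, endian = "little")
      geoms[[length(geoms) + 1L]] <- c(lat = xy[2], lon = xy[1])
    } else if (rtype == 3L) {
      readBin(con, "numeric", 4, 8, endian = "little")
      nparts <- readBin(con, "integer", 1, 4, endian = "little")
      npts <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", nparts, 4, endian = "little")
      xy <- matrix(readBin(con, "numeric", 2 * npts, 8, endian = "little"),
                   ncol = 2, byrow = TRUE)
      geoms[[length(geoms) + 1L]] <- cbind(lat = xy[, 2], lon = xy[, 1])
    } else stop("unsupported shapefile record type: ", rtype)
    pos <- pos + 4L + len
  }
  df <- if (file.exists(paste0(base, ".dbf")))
    foreign::read.dbf(paste0(base, ".dbf"), as.is = TRUE) else NULL
  ren_path <- paste0(base, ".fieldnames.json")
  if (!is.null(df) && file.exists(ren_path)) {
    ren <- jsonlite::read_json(ren_path, simplifyVector = TRUE)
    for (s in names(ren)) names(df)[names(df) == s] <- ren[[s]]
  }
  feats <- lapply(seq_along(geoms), function(i) {
    at <- if (is.null(df) || nrow(df) < i) list(image_id = NA) else
      as.list(df[i, , drop = FALSE])
    list(geometry = geoms[[i]], attributes = at)
  })
  geo_feature_set(basename(base),
                  if (shape_type == 1L) "point" else "line", feats)
}
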