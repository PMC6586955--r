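#' Read GPS positions from CSV
#'
#' Expects columns `individual_id`, `timestamp` (ISO 8601, assumed UTC when no
#' offset is given), `x`, `y` (projected planar meters) and optionally
#' `burst_id`. Rows are returned sorted by individual and time.
#'
#' @param path CSV file path.
#' @param crs_note Free-text note recorded as an attribute; the package does
#'   no geodetic math and trusts coordinates to be planar meters.
#' @return A tibble of fixes with columns `individual_id`, `burst_id` (NA if
#'   absent), `t` (epoch seconds, UTC), `x`, `y`.
#' @export
read_positions <- function(path, crs_note = "planar meters") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("positions file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  line_no <- seq_len(n) + 1L  # header is line 1
  t <- .parse_iso8601(df$timestamp)
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(t) | !is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("malformed position row(s) at line ",
         paste(line_no[bad], collapse = ", "),
         " (unparseable timestamp or non-finite coordinate)", call. = FALSE)
  fixes <- tibble::tibble(
    individual_id = df$individual_id,
    burst_id = if ("burst_id" %in% names(df)) df$burst_id else
      NA_character_,
    t = t, x = x, y = y)
  dup <- fixes[duplicated(fixes[, c("individual_id", "t")]) |
                 duplicated(fixes[, c("individual_id", "t")],
                            fromLast = TRUE), ]
  if (nrow(dup))
    stop("duplicate timestamps within an individual: ",
         paste(unique(paste0(dup$individual_id, "@", dup$t)),
               collapse = ", "), call. = FALSE)
  fixes <- fixes[order(fixes$individual_id, fixes$t), ]
  attr(fixes, "crs_note") <- crs_note
  fixes
}

# ISO 8601 parser on top of strptime; returns epoch seconds (UTC) or NA.
.parse_iso8601 <- function(s) {
  s <- sub("Z$", "", sub("T", " ", s))
  out <- as.POSIXct(s, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"),
                    optional = TRUE)
  as.numeric(out)
}

#' Write GPS positions to CSV
#'
#' Inverse of [read_positions()]: epoch seconds are rendered as ISO 8601
#' UTC timestamps, coordinates to millimeter precision. Reading the file
#' back reproduces all fields.
#'
#' @param fixes Fix tibble with `individual_id`, `t`, `x`, `y` and
#'   optionally `burst_id`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(fixes, path) {
  out <- data.frame(
    individual_id = fixes$individual_id,
    timestamp = strftime(as.POSIXct(fixes$t, origin = "1970-01-01",
                                    tz = "UTC"),
                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = sprintf("%.3f", fixes$x),
    y = sprintf("%.3f", fixes$y))
  if ("burst_id" %in% names(fixes) && !all(is.na(fixes$burst_id)))
    out$burst_id <- fixes$burst_id
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Segment a fix stream into bursts
#'
#' A new burst starts whenever the inter-fix gap within an individual exceeds
#' `gap_s`. Fixes that already carry a `burst_id` keep it verbatim; the gap
#' rule is only applied to fixes without one. `seq_index` is (re)assigned
#' 0..n-1 within each burst.
#'
#' @param fixes A fix tibble (see [read_positions()]), sorted by individual
#'   and time.
#' @param gap_s Gap threshold in seconds; default twice the 15 s nominal
#'   inter-fix interval, tolerant of a single missed fix.
#' @return The fix tibble with `burst_id` and `seq_index` columns filled in.
#' @export
segment_bursts <- function(fixes, gap_s = 30) {
  if (nrow(fixes) == 0) {
    fixes$seq_index <- integer(0)
    return(fixes)
  }
  stopifnot(gap_s > 0)
  fixes <- fixes[order(fixes$individual_id, fixes$t), ]
  out <- lapply(split(fixes, fixes$individual_id), function(d) {
    has_id <- !is.na(d$burst_id)
    if (all(has_id)) {
      bid <- d$burst_id
    } else {
      new_burst <- c(TRUE, diff(d$t) > gap_s)
      grp <- cumsum(new_burst)
      bid <- sprintf("%s_b%04d", d$individual_id, grp)
      bid[has_id] <- d$burst_id[has_id]
    }
    d$burst_id <- bid
    idx <- stats::ave(seq_len(nrow(d)), bid, FUN = seq_along)
    d$seq_index <- as.integer(idx - 1L)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

#' Read linear features from GeoJSON
#'
#' Accepts a FeatureCollection of LineString / MultiLineString geometries,
#' each carrying a `feature_type` property in [lft_feature_types()].
#' MultiLineStrings are exploded into one feature per part. Coordinates are
#' taken verbatim as planar meters.
#'
#' @param path GeoJSON file path.
#' @return An `lft_features` object.
#' @export
read_features <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  types <- lft_feature_types()
  out <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    ft <- f$properties$feature_type
    if (is.null(ft))
      stop("feature ", i, " has no `feature_type` property", call. = FALSE)
    if (!ft %in% types)
      stop("feature ", i, ": unknown feature_type \"", ft,
           "\" (allowed: ", paste(types, collapse = ", "), ")",
           call. = FALSE)
    g <- f$geometry
    id <- if (!is.null(f$properties$feature_id)) f$properties$feature_id else
      sprintf("f%03d", i)
    if (g$type == "LineString") {
      out[[length(out) + 1L]] <- list(feature_id = id, ftype = ft,
                                      vertices = .coords_to_matrix(g$coordinates))
    } else if (g$type == "MultiLineString") {
      for (j in seq_along(g$coordinates))
        out[[length(out) + 1L]] <- list(
          feature_id = paste0(id, "_", j), ftype = ft,
          vertices = .coords_to_matrix(g$coordinates[[j]]))
    } else {
      stop("feature ", i, ": geometry type \"", g$type,
           "\" is not supported here (use extract_forest_edges() for ",
           "polygons)", call. = FALSE)
    }
  }
  feature_set(out)
}

.coords_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  m
}

#' Extract forest-edge polylines from forest polygons
#'
#' Converts the exterior and interior rings of (Multi)Polygon geometries into
#' closed polylines typed `forest_edge` — the boundary between forest and
#' open land cover.
#'
#' @param path GeoJSON file of Polygon / MultiPolygon features.
#' @return An `lft_features` object of `forest_edge` polylines.
#' @export
extract_forest_edges <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  out <- list()
  add_rings <- function(rings, id) {
    for (r in seq_along(rings)) {
      v <- .coords_to_matrix(rings[[r]])
      # ensure ring closure
      if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
      out[[length(out) + 1L]] <<- list(
        feature_id = paste0(id, "_ring", r), ftype = "forest_edge",
        vertices = v)
    }
  }
  for (i in seq_along(gj$features)) {
    g <- gj$features[[i]]$geometry
    id <- sprintf("forest%03d", i)
    if (g$type == "Polygon") {
      add_rings(g$coordinates, id)
    } else if (g$type == "MultiPolygon") {
      for (j in seq_along(g$coordinates))
        add_rings(g$coordinates[[j]], paste0(id, "_", j))
    } else {
      stop("feature ", i, ": expected Polygon or MultiPolygon, got \"",
           g$type, "\"", call. = FALSE)
    }
  }
  feature_set(out)
}

#' Write a feature set to GeoJSON
#'
#' @param fs An `lft_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "lft_features"))
  feats <- lapply(seq_len(nrow(fs$features)), function(i) {
    v <- fs$vertices[[i]]
    list(type = "Feature",
         properties = list(feature_id = fs$features$feature_id[i],
                           feature_type = fs$features$ftype[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(v)), function(k)
                           c(v[k, 1], v[k, 2]))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an analysis table to CSV
#'
#' Deterministic column order (as passed), numeric columns formatted to six
#' significant digits, so that a write/read round trip reproduces values to
#' that precision.
#'
#' @param df A data frame (events, survival records, case-control rows,
#'   coefficient tables, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lft_table <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 6, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a table written by [write_lft_table()]
#'
#' @param path CSV path.
#' @return A tibble with numeric columns restored.
#' @export
read_lft_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
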