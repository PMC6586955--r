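#' Build a linear feature set
#'
#' A feature set holds typed polylines (roads, forest edges, streams) in a
#' projected planar coordinate system, together with a flattened segment
#' representation used for exact minimum-distance queries.
#'
#' @param features A list; each element a list with fields `ftype` (one of
#'   [lft_feature_types()]), `vertices` (an n x 2 numeric matrix of planar
#'   coordinates in meters, n >= 2), and optionally `feature_id`.
#' @return An object of class `lft_features`.
#' @export
feature_set <- function(features = list()) {
  types <- lft_feature_types()
  n <- length(features)
  ids <- character(n); ftypes <- character(n)
  verts <- vector("list", n)
  for (i in seq_len(n)) {
    f <- features[[i]]
    ft <- f$ftype
    if (is.null(ft) || !ft %in% types)
      stop("feature ", i, ": `ftype` must be one of ",
           paste(types, collapse = ", "), call. = FALSE)
    v <- f$vertices
    if (is.data.frame(v)) v <- as.matrix(v)
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 2 || !all(is.finite(v)))
      stop("feature ", i, ": `vertices` must be a finite n x 2 matrix, n >= 2",
           call. = FALSE)
    dd <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    if (any(dd == 0))
      stop("feature ", i, ": consecutive vertices must not be identical",
           call. = FALSE)
    ids[i] <- if (!is.null(f$feature_id)) as.character(f$feature_id) else
      sprintf("%s_%03d", ft, i)
    ftypes[i] <- ft
    dimnames(v) <- NULL
    verts[[i]] <- v
  }
  fs <- structure(list(
    features = tibble::tibble(
      feature_id = ids, ftype = ftypes,
      n_vertices = vapply(verts, nrow, 0L),
      length_m = vapply(verts, function(v)
        sum(sqrt(rowSums((v[-1, , drop = FALSE] -
                          v[-nrow(v), , drop = FALSE])^2))), 0)),
    vertices = verts), class = "lft_features")
  fs$segs <- .flatten_segments(fs)
  fs
}

# Flattened, feature-ordered segment arrays for the C++ kernels.
.flatten_segments <- function(fs) {
  types <- lft_feature_types()
  x0 <- y0 <- x1 <- y1 <- scum <- slen <- numeric(0)
  sfeat <- stype <- integer(0)
  nf <- length(fs$vertices)
  feat_first <- integer(nf); feat_nseg <- integer(nf); feat_len <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- fs$vertices[[i]]
    ns <- nrow(v) - 1L
    a <- v[-nrow(v), , drop = FALSE]; b <- v[-1, , drop = FALSE]
    sl <- sqrt(rowSums((b - a)^2))
    feat_first[i] <- length(x0)            # 0-based
    feat_nseg[i] <- ns
    feat_len[i] <- sum(sl)
    x0 <- c(x0, a[, 1]); y0 <- c(y0, a[, 2])
    x1 <- c(x1, b[, 1]); y1 <- c(y1, b[, 2])
    scum <- c(scum, cumsum(c(0, sl[-ns])))
    slen <- c(slen, sl)
    sfeat <- c(sfeat, rep(i - 1L, ns))
    stype <- c(stype, rep(match(fs$features$ftype[i], types) - 1L, ns))
  }
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, sfeat = sfeat, stype = stype,
       scum = scum, slen = slen, feat_first = feat_first,
       feat_nseg = feat_nseg, feat_len = feat_len)
}

#' @export
print.lft_features <- function(x, ...) {
  cat("<lft_features> ", nrow(x$features), " features\n", sep = "")
  tab <- table(factor(x$features$ftype, levels = lft_feature_types()))
  for (ft in names(tab))
    cat(sprintf("  %-12s %3d features, %8.1f m total\n", ft, tab[[ft]],
                sum(x$features$length_m[x$features$ftype == ft])))
  invisible(x)
}

#' Minimum distance from a point to a polyline
#'
#' Exact minimum Euclidean distance from a planar point to the union of a
#' polyline's segments (interior projection or nearest endpoint per segment).
#'
#' @param p Numeric length-2 vector `(x, y)` in meters.
#' @param vertices An n x 2 vertex matrix (n >= 2).
#' @return Distance in meters.
#' @export
point_to_polyline_distance <- function(p, vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  stopifnot(is.numeric(p), length(p) == 2, is.matrix(vertices),
            ncol(vertices) == 2, nrow(vertices) >= 2)
  .point_polyline_dist_cpp(p[1], p[2], vertices)
}

#' Minimum distances from points to each feature type
#'
#' @param xy An n x 2 matrix of planar points (meters).
#' @param fs An `lft_features` object.
#' @return An n x 3 matrix with columns `road`, `forest_edge`, `stream`;
#'   `Inf` where the feature set has no feature of that type.
#' @export
feature_min_distances <- function(xy, fs) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  stopifnot(inherits(fs, "lft_features"), is.matrix(xy), ncol(xy) == 2)
  types <- lft_feature_types()
  if (nrow(fs$features) == 0) {
    m <- matrix(Inf, nrow(xy), length(types))
    colnames(m) <- types
    return(m)
  }
  s <- fs$segs
  m <- .min_dist_by_type_cpp(xy[, 1], xy[, 2], s$x0, s$y0, s$x1, s$y1,
                             s$stype, length(types))
  colnames(m) <- types
  m
}
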