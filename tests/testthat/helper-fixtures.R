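# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests write themselves.

# A burst tibble from coordinate vectors (15 s spacing by default).
make_burst <- function(x, y, t = NULL, dt = 15, individual_id = "fox1",
                       burst_id = "fox1_b0001") {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) * dt
  tibble::tibble(individual_id = individual_id, burst_id = burst_id,
                 seq_index = seq_len(n) - 1L, t = t, x = x, y = y)
}

# A single horizontal road along y = 0 from x = -L to x = L.
road_along_x <- function(L = 1000) {
  feature_set(list(list(feature_id = "road_1", ftype = "road",
                        vertices = cbind(c(-L, L), c(0, 0)))))
}

# A burst walking along the road at `speed` m/s with fixed lateral offset.
burst_on_road <- function(n = 6, speed = 3, dt = 15, y_off = 2, x0 = 0, ...) {
  make_burst(x = x0 + (seq_len(n) - 1) * speed * dt,
             y = rep(y_off, n), dt = dt, ...)
}

# Brute-force min distance from a point to a polyline by dense sampling.
brute_polyline_dist <- function(p, verts, step = 0.001) {
  best <- Inf
  for (s in seq_len(nrow(verts) - 1)) {
    a <- verts[s, ]; b <- verts[s + 1, ]
    L <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, by = min(1, step / L))
    px <- a[1] + tt * (b[1] - a[1]); py <- a[2] + tt * (b[2] - a[2])
    best <- min(best, sqrt((p[1] - px)^2 + (p[2] - py)^2))
  }
  best
}

# Write a small GeoJSON FeatureCollection for reader tests.
write_geojson <- function(features, path) {
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  path
}

gj_linestring <- function(coords, feature_type = "road", ...) {
  list(type = "Feature",
       properties = c(list(feature_type = feature_type), list(...)),
       geometry = list(type = "LineString", coordinates = coords))
}
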