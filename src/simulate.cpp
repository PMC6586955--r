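#include <Rcpp.h>
using namespace Rcpp;

// Two-state latent movement model at 1 s resolution.
//
// Free state: correlated random walk (gamma speeds, normal turning).
// On entering the proximity buffer of any feature (from outside), the animal
// switches to tracking with probability p_track: it then travels along the
// encountered polyline at the feature type's tracking speed, holding a
// mean-reverting lateral offset from the line, and abandons tracking with a
// constant per-second hazard (geometric duration) or when it runs off either
// end of the feature.
//
// Segments are passed flattened and ordered within feature:
//   sx0..sy1  segment endpoints
//   sfeat     0-based feature index per segment
//   stype     0-based feature type per segment
//   scum      arc length at the segment's start within its feature
//   feat_first, feat_nseg, feat_len : per-feature segment ranges / lengths
//
// All randomness uses the R RNG, so set.seed() governs reproducibility.

static inline double seg_dist2_t(double px, double py,
                                 double x0, double y0, double x1, double y1,
                                 double *tt) {
  double dx = x1 - x0, dy = y1 - y0;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - x0) * dx + (py - y0) * dy) / l2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  *tt = t;
  double qx = x0 + t * dx, qy = y0 + t * dy;
  return (px - qx) * (px - qx) + (py - qy) * (py - qy);
}

// [[Rcpp::export(name = ".sim_path_cpp")]]
List sim_path_cpp(int n_sec, double start_x, double start_y, double heading0,
                  NumericVector sx0, NumericVector sy0,
                  NumericVector sx1, NumericVector sy1,
                  IntegerVector sfeat, IntegerVector stype,
                  NumericVector scum,
                  IntegerVector feat_first, IntegerVector feat_nseg,
                  NumericVector feat_len,
                  double buffer_m, double p_track,
                  double speed_shape, double speed_scale, double turn_sd,
                  NumericVector track_speed, NumericVector track_hazard,
                  double lat_phi, double lat_sd,
                  double xmin, double xmax, double ymin, double ymax) {
  int ns = sx0.size();
  NumericVector X(n_sec + 1), Y(n_sec + 1);
  IntegerVector state(n_sec + 1), feat(n_sec + 1);
  const double *SX0 = sx0.begin(), *SY0 = sy0.begin();
  const double *SX1 = sx1.begin(), *SY1 = sy1.begin();

  double x = start_x, y = start_y, heading = heading0;
  bool in_buffer_prev = false;
  // distance slack to the nearest buffer edge: while positive we cannot have
  // entered any buffer, so the all-segments scan can be skipped
  double slack = -1.0;

  // tracking state
  bool tracking = false;
  int tr_feat = -1, tr_type = -1, tr_seg = -1, tr_dir = 1;
  double tr_s = 0.0, tr_lat = 0.0;

  X[0] = x; Y[0] = y; state[0] = 0; feat[0] = -1;

  for (int t = 1; t <= n_sec; ++t) {
    if (!tracking) {
      double sp = R::rgamma(speed_shape, speed_scale);
      heading += R::rnorm(0.0, turn_sd);
      double nx = x + sp * std::cos(heading);
      double ny = y + sp * std::sin(heading);
      // reflect at arena boundary
      if (nx < xmin) { nx = 2 * xmin - nx; heading = M_PI - heading; }
      if (nx > xmax) { nx = 2 * xmax - nx; heading = M_PI - heading; }
      if (ny < ymin) { ny = 2 * ymin - ny; heading = -heading; }
      if (ny > ymax) { ny = 2 * ymax - ny; heading = -heading; }
      x = nx; y = ny;

      slack -= sp;
      if (slack > 0.0) {
        // still provably outside every buffer
        in_buffer_prev = false;
        X[t] = x; Y[t] = y; state[t] = 0; feat[t] = -1;
        continue;
      }
      // nearest segment over all features
      double best = R_PosInf, bt = 0.0, tt;
      int bseg = -1;
      for (int s = 0; s < ns; ++s) {
        double d2 = seg_dist2_t(x, y, SX0[s], SY0[s], SX1[s], SY1[s], &tt);
        if (d2 < best) { best = d2; bseg = s; bt = tt; }
      }
      double dmin = std::sqrt(best);
      slack = dmin - buffer_m;
      bool in_buf = (bseg >= 0) && (dmin < buffer_m);
      if (in_buf && !in_buffer_prev && R::runif(0.0, 1.0) < p_track) {
        // commit to tracking the encountered feature
        tracking = true;
        tr_seg = bseg;
        tr_feat = sfeat[bseg];
        tr_type = stype[bseg];
        double dx = sx1[bseg] - sx0[bseg], dy = sy1[bseg] - sy0[bseg];
        double sl = std::sqrt(dx * dx + dy * dy);
        tr_s = scum[bseg] + bt * sl;
        // direction of travel along the line: align with current heading
        double dot = std::cos(heading) * dx + std::sin(heading) * dy;
        tr_dir = (dot >= 0.0) ? 1 : -1;
        // signed lateral offset (left of travel direction positive)
        double qx = sx0[bseg] + bt * dx, qy = sy0[bseg] + bt * dy;
        double nxv = -dy / sl * tr_dir, nyv = dx / sl * tr_dir;
        tr_lat = (x - qx) * nxv + (y - qy) * nyv;
      }
      in_buffer_prev = in_buf;
    } else {
      int f = tr_feat;
      bool leave = (R::runif(0.0, 1.0) < track_hazard[tr_type]);
      tr_s += tr_dir * track_speed[tr_type];
      // reverse at feature ends: the departure hazard is the sole
      // terminator, so episode durations stay geometric
      if (tr_s < 0.0) { tr_s = -tr_s; tr_dir = -tr_dir; }
      if (tr_s > feat_len[f]) {
        tr_s = 2.0 * feat_len[f] - tr_s;
        tr_dir = -tr_dir;
      }
      // locate segment containing arc position tr_s
      int lo = feat_first[f], hi = feat_first[f] + feat_nseg[f] - 1;
      if (tr_seg < lo || tr_seg > hi) tr_seg = lo;
      while (tr_seg < hi && tr_s > scum[tr_seg + 1]) ++tr_seg;
      while (tr_seg > lo && tr_s < scum[tr_seg]) --tr_seg;
      double dx = sx1[tr_seg] - sx0[tr_seg], dy = sy1[tr_seg] - sy0[tr_seg];
      double sl = std::sqrt(dx * dx + dy * dy);
      double frac = (sl > 0.0) ? (tr_s - scum[tr_seg]) / sl : 0.0;
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      // AR(1) lateral offset, stationary sd = lat_sd
      tr_lat = lat_phi * tr_lat +
        R::rnorm(0.0, lat_sd * std::sqrt(1.0 - lat_phi * lat_phi));
      double qx = sx0[tr_seg] + frac * dx, qy = sy0[tr_seg] + frac * dy;
      double nxv = -dy / sl * tr_dir, nyv = dx / sl * tr_dir;
      x = qx + tr_lat * nxv;
      y = qy + tr_lat * nyv;
      heading = std::atan2(tr_dir * dy, tr_dir * dx);
      if (leave) {
        tracking = false;
        // depart at an angle away from the line so the buffer is left
        double side = (R::runif(0.0, 1.0) < 0.5) ? 1.0 : -1.0;
        heading += side * (M_PI / 2.0 + R::rnorm(0.0, 0.3));
        in_buffer_prev = true;  // still inside; no instant re-encounter
        slack = 0.0;            // force a rescan on the next free step
      }
    }
    X[t] = x; Y[t] = y;
    state[t] = tracking ? (tr_type + 1) : 0;
    feat[t] = tracking ? tr_feat : -1;
  }

  return List::create(_["x"] = X, _["y"] = Y,
                      _["state"] = state, _["feature"] = feat);
}
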