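// Simulation core: two-segment larva state machine stepped at dt, with
// odour-field evaluation and wall handling. All angles in degrees, lengths
// in mm, rates in 1/s. Kept in one translation unit so the field evaluator
// used by the engine is byte-identical to the one exposed to R.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double D2R = M_PI / 180.0;
static const double R2D = 180.0 / M_PI;

static inline double wrap180(double a) {
  a -= 360.0 * std::floor((a + 180.0) / 360.0); // [-180, 180)
  if (a == -180.0) a = 180.0;                   // (-180, 180]
  return a;
}

// ---------------------------------------------------------------------------
// Counter-seeded xoshiro256++; one independent stream per larva so batches
// are reproducible and order-independent.
struct LarvaRng {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); } // [0, 1)
};

// ---------------------------------------------------------------------------
// Odour fields. kind: 0 uniform, 1 gaussian, 2 linear, 3 exponential,
// 4 step, 5 grid. Grid lookups are bilinear inside the hull and
// constant-extrapolated outside; an optional multiplicative-noise grid is
// piecewise constant per cell.
struct FieldC {
  int kind;
  double p[8];
  // grid payload (NumericMatrix members keep the SEXPs alive)
  NumericMatrix gmat, nmat;
  const double* g = nullptr; int gnx = 0, gny = 0; double gox = 0, goy = 0, gcell = 1;
  // noise payload
  const double* nm = nullptr; int nnx = 0, nny = 0; double nox = 0, noy = 0, ncell = 1;

  double base(double x, double y) const {
    switch (kind) {
    case 0: return p[0];
    case 1: { // gaussian: px py sigma peak
      double dx = x - p[0], dy = y - p[1];
      return p[3] * std::exp(-(dx * dx + dy * dy) / (2.0 * p[2] * p[2]));
    }
    case 2: { // linear: fx fy tx ty low high (clamped outside the segment span)
      double ax = p[2] - p[0], ay = p[3] - p[1];
      double L2 = ax * ax + ay * ay;
      double s = ((x - p[0]) * ax + (y - p[1]) * ay) / L2;
      if (s < 0) s = 0; if (s > 1) s = 1;
      return p[4] + (p[5] - p[4]) * s;
    }
    case 3: { // exponential: px py ux uy scale peak, capped at peak value
      double s = (x - p[0]) * p[2] + (y - p[1]) * p[3];
      if (s > 0) s = 0;
      return p[5] * std::exp(s / p[4]);
    }
    case 4: { // step: cx cy ux uy width low high
      double s = (x - p[0]) * p[2] + (y - p[1]) * p[3];
      double hw = 0.5 * p[4];
      if (s <= -hw) return p[5];
      if (s >= hw) return p[6];
      return p[5] + (p[6] - p[5]) * (s + hw) / p[4];
    }
    case 5: { // grid, bilinear, clamped coordinates
      double gx = (x - gox) / gcell, gy = (y - goy) / gcell;
      if (gx < 0) gx = 0; if (gx > gnx - 1) gx = gnx - 1;
      if (gy < 0) gy = 0; if (gy > gny - 1) gy = gny - 1;
      int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
      if (i0 > gnx - 2) i0 = gnx - 2; if (i0 < 0) i0 = 0;
      if (j0 > gny - 2) j0 = gny - 2; if (j0 < 0) j0 = 0;
      double fx = gx - i0, fy = gy - j0;
      if (gnx == 1) { i0 = 0; fx = 0; }
      if (gny == 1) { j0 = 0; fy = 0; }
      // values stored with nrow = ny (row = y index), column-major
      int i1 = (gnx == 1) ? i0 : i0 + 1, j1 = (gny == 1) ? j0 : j0 + 1;
      double v00 = g[j0 + i0 * gny], v10 = g[j0 + i1 * gny];
      double v01 = g[j1 + i0 * gny], v11 = g[j1 + i1 * gny];
      return (1 - fx) * ((1 - fy) * v00 + fy * v01) + fx * ((1 - fy) * v10 + fy * v11);
    }
    }
    return 0.0;
  }

  double eval(double x, double y) const {
    double c = base(x, y);
    if (nm) {
      int ix = (int)std::floor((x - nox) / ncell);
      int iy = (int)std::floor((y - noy) / ncell);
      if (ix < 0) ix = 0; if (ix > nnx - 1) ix = nnx - 1;
      if (iy < 0) iy = 0; if (iy > nny - 1) iy = nny - 1;
      c *= nm[iy + ix * nny];
    }
    return c < 0 ? 0.0 : c;
  }
};

static FieldC parse_field(List field) {
  FieldC f;
  f.kind = as<int>(field["kind"]);
  NumericVector p = field["p"];
  for (int i = 0; i < 8; ++i) f.p[i] = (i < p.size()) ? p[i] : 0.0;
  if (f.kind == 5) {
    List gr = field["grid"];
    f.gmat = as<NumericMatrix>(gr["values"]);
    if (f.gmat.size() == 0) stop("grid odour field has an empty matrix");
    f.g = REAL(f.gmat); f.gny = f.gmat.nrow(); f.gnx = f.gmat.ncol();
    NumericVector o = gr["origin"];
    f.gox = o[0]; f.goy = o[1]; f.gcell = as<double>(gr["cell"]);
  }
  if (field.containsElementNamed("noise") && !Rf_isNull(field["noise"])) {
    List nz = field["noise"];
    f.nmat = as<NumericMatrix>(nz["values"]);
    f.nm = REAL(f.nmat); f.nny = f.nmat.nrow(); f.nnx = f.nmat.ncol();
    NumericVector o = nz["origin"];
    f.nox = o[0]; f.noy = o[1]; f.ncell = as<double>(nz["cell"]);
  }
  return f;
}

// [[Rcpp::export]]
NumericVector field_eval_cpp(List field, NumericMatrix pts) {
  FieldC f = parse_field(field);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = f.eval(pts(i, 0), pts(i, 1));
  return out;
}

// ---------------------------------------------------------------------------
// Arenas. kind: 0 none, 1 circle (cx cy r), 2 rectangle (cx cy w h).
struct ArenaC {
  int kind; double p[4];
  // true when (x, y) is on or outside the wall; (nx, ny) inward unit normal,
  // pen = distance outside the boundary (>= 0).
  bool contact(double x, double y, double& nx, double& ny, double& pen) const {
    if (kind == 1) {
      double dx = x - p[0], dy = y - p[1];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < p[2]) return false;
      if (d == 0) { nx = 1; ny = 0; pen = p[2]; return true; }
      nx = -dx / d; ny = -dy / d; pen = d - p[2];
      return true;
    }
    if (kind == 2) {
      double dx = x - p[0], dy = y - p[1];
      double hw = 0.5 * p[2], hh = 0.5 * p[3];
      double ox = std::fabs(dx) - hw, oy = std::fabs(dy) - hh;
      if (ox < 0 && oy < 0) return false;
      double vx = 0, vy = 0;
      if (ox >= 0) vx = (dx > 0) ? -1.0 : 1.0;
      if (oy >= 0) vy = (dy > 0) ? -1.0 : 1.0;
      double nrm = std::sqrt(vx * vx + vy * vy);
      nx = vx / nrm; ny = vy / nrm;
      pen = std::max(ox > 0 ? ox : 0.0, oy > 0 ? oy : 0.0);
      return true;
    }
    return false;
  }
};

// [[Rcpp::export]]
List arena_contact_cpp(List arena, NumericMatrix pts) {
  ArenaC a;
  a.kind = as<int>(arena["kind"]);
  NumericVector p = arena["p"];
  for (int i = 0; i < 4; ++i) a.p[i] = (i < p.size()) ? p[i] : 0.0;
  int n = pts.nrow();
  LogicalVector hit(n);
  NumericVector nx(n, NA_REAL), ny(n, NA_REAL), pen(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double cx, cy, pn;
    if (a.contact(pts(i, 0), pts(i, 1), cx, cy, pn)) {
      hit[i] = true; nx[i] = cx; ny[i] = cy; pen[i] = pn;
    } else hit[i] = false;
  }
  return List::create(_["contact"] = hit, _["nx"] = nx, _["ny"] = ny, _["pen"] = pen);
}

// ---------------------------------------------------------------------------
// Transition rate: base + dot(kernel, history), clamped at zero. History is
// most-recent-first; shorter histories are zero-padded (equivalent to the
// buffer being initialised with zeros).
// [[Rcpp::export]]
double rate_from_history_cpp(NumericVector kernel, NumericVector history, double base) {
  double acc = base;
  int n = std::min(kernel.size(), history.size());
  for (int k = 0; k < n; ++k) acc += kernel[k] * history[k];
  return acc < 0 ? 0.0 : acc;
}

// ---------------------------------------------------------------------------
enum Mode { RUN = 0, HEAD_CAST = 1 };
enum WvMode { WV_CASTING = 0, WV_PAUSED = 1, WV_SUSPENDED = 2 };
enum Phase { OUTWARD = 0, INWARD = 1 };

// [[Rcpp::export]]
List sim_larva_cpp(List params, List kernels, List field, List arena,
                   double duration, double master_seed, int larva_index,
                   NumericVector init, int stride, List trunc, bool record_full) {
  const double dt = as<double>(params["dt"]);
  const double v = as<double>(params["v_forward"]);
  const double t_min_run = as<double>(params["t_min_run"]);
  const double th_max = as<double>(params["theta_max_head_cast"]);
  const double th_min = as<double>(params["theta_min_head_cast"]);
  const double cast_speed = as<double>(params["cast_speed"]);
  const double wv_max = as<double>(params["theta_max_weathervane_cast"]);
  const double wv_speed = as<double>(params["weathervane_cast_speed"]);
  const double r_run_base = as<double>(params["r_run_termination_base"]);
  const double r_cast_base = as<double>(params["r_cast_termination_base"]);
  const double r_wv_base = as<double>(params["r_weathervane_cast_termination_base"]);
  const double r_wv_resume = as<double>(params["r_weathervane_cast_resume"]);
  const double Lh = as<double>(params["L_head"]);
  const double Lb = as<double>(params["L_body"]);
  const double wall_deflect = as<double>(params["wall_deflection"]);
  const bool wv_enabled = as<double>(params["weathervane_casting"]) != 0.0;
  const bool first_cast_bias = as<double>(params["first_cast_bias"]) != 0.0;
  const double eps = 1e-12;

  NumericVector k_run = kernels["run"], k_cast = kernels["cast"], k_wv = kernels["weathervane"];
  const int n_run = k_run.size(), n_cast = k_cast.size(), n_wv = k_wv.size();
  int cap = std::max(n_run, std::max(n_cast, n_wv));
  if (cap < 1) cap = 1;
  std::vector<double> hist(cap, 0.0);
  int hpos = 0; // index of most recent sample

  FieldC f = parse_field(field);
  ArenaC ar;
  ar.kind = as<int>(arena["kind"]);
  {
    NumericVector p = arena["p"];
    for (int i = 0; i < 4; ++i) ar.p[i] = (i < p.size()) ? p[i] : 0.0;
  }

  const int tr_kind = as<int>(trunc["kind"]); // 0 none, 1 wall, 2 radius, 3 line
  double trp[3] = {0, 0, 0};
  {
    NumericVector p = trunc["p"];
    for (int i = 0; i < 3 && i < p.size(); ++i) trp[i] = p[i];
  }

  LarvaRng rng;
  rng.seed((uint64_t)master_seed * 0x9E3779B97F4A7C15ULL +
           (uint64_t)(larva_index + 1) * 0xD2B74407B1CE6E93ULL);

  // state
  double jx = init[0], jy = init[1];
  double alpha = init[2], theta = init[3];
  double tx = jx - Lb * std::cos(alpha * D2R), ty = jy - Lb * std::sin(alpha * D2R);
  int mode = RUN, wv_mode, wv_dir, cast_dir = 1, phase = OUTWARD;
  double run_time = 0.0;
  wv_dir = (rng.unif() < 0.5) ? 1 : -1;
  wv_mode = (std::fabs(theta) > wv_max) ? WV_SUSPENDED : WV_CASTING;

  const int n_steps = (int)std::lround(duration / dt);
  const int max_rec = record_full ? (n_steps / stride + 3) : 2;
  NumericMatrix out(max_rec, 15);
  int nrec = 0, cause = 0;

  double hx = jx + Lh * std::cos((alpha + theta) * D2R);
  double hy = jy + Lh * std::sin((alpha + theta) * D2R);
  double c_prev = f.eval(hx, hy);

  auto record = [&](double t, double conc, double phi, double rr, double rc, double rw) {
    int i = record_full ? nrec : (nrec > 0 ? 1 : 0);
    out(i, 0) = t; out(i, 1) = hx; out(i, 2) = hy; out(i, 3) = jx; out(i, 4) = jy;
    out(i, 5) = tx; out(i, 6) = ty; out(i, 7) = alpha; out(i, 8) = theta;
    out(i, 9) = mode; out(i, 10) = conc; out(i, 11) = phi;
    out(i, 12) = rr; out(i, 13) = rc; out(i, 14) = rw;
    if (record_full || nrec == 0) ++nrec; else nrec = 2;
  };

  // initial record: empty history, so rates sit at their bases
  record(0.0, c_prev, 0.0, r_run_base, r_cast_base, r_wv_base);
  if (!record_full) nrec = 1;

  int step = 0;
  for (step = 1; step <= n_steps; ++step) {
    // perception at the head tip, before movement
    double c_now = f.eval(hx, hy);
    double phi = (c_now - c_prev) / (std::max(c_now, eps) * dt);
    c_prev = c_now;
    hpos = (hpos + 1) % cap;
    hist[hpos] = phi;

    // transition rates, computed every step regardless of state
    double r_run = r_run_base, r_cast = r_cast_base, r_wv = r_wv_base;
    {
      int idx = hpos;
      int nmax = cap;
      for (int k = 0; k < nmax; ++k) {
        double ph = hist[idx];
        if (k < n_run) r_run += k_run[k] * ph;
        if (k < n_cast) r_cast += k_cast[k] * ph;
        if (k < n_wv) r_wv += k_wv[k] * ph;
        idx = (idx == 0) ? cap - 1 : idx - 1;
      }
      if (r_run < 0) r_run = 0;
      if (r_cast < 0) r_cast = 0;
      if (r_wv < 0) r_wv = 0;
    }

    if (mode == RUN) {
      double h = alpha + theta; // world head orientation
      double hr = h * D2R;
      jx += v * dt * std::cos(hr);
      jy += v * dt * std::sin(hr);
      // trailer kinematics: body realigns toward the joint's track
      double dx = jx - tx, dy = jy - ty;
      alpha = std::atan2(dy, dx) * R2D;
      tx = jx - Lb * std::cos(alpha * D2R);
      ty = jy - Lb * std::sin(alpha * D2R);
      theta = wrap180(h - alpha);
      run_time += dt;

      if (wv_enabled) {
        if (wv_mode == WV_SUSPENDED && std::fabs(theta) <= wv_max) {
          wv_mode = WV_CASTING;
          wv_dir = (rng.unif() < 0.5) ? 1 : -1;
        }
        if (wv_mode == WV_CASTING) {
          theta += wv_dir * wv_speed * dt;
          if (std::fabs(theta) >= wv_max) {
            theta = (theta > 0) ? wv_max : -wv_max;
            wv_dir = -wv_dir; // strict alternation
          }
          if (rng.unif() < r_wv * dt) wv_mode = WV_PAUSED;
        } else if (wv_mode == WV_PAUSED) {
          if (rng.unif() < r_wv_resume * dt) wv_mode = WV_CASTING;
        }
      }

      if (run_time > t_min_run + 1e-12 && rng.unif() < r_run * dt) {
        mode = HEAD_CAST;
        phase = OUTWARD;
        if (theta > 0) cast_dir = 1;
        else if (theta < 0) cast_dir = -1;
        else cast_dir = (rng.unif() < 0.5) ? 1 : -1;
        if (!first_cast_bias) cast_dir = (rng.unif() < 0.5) ? 1 : -1;
      }
    } else { // HEAD_CAST: body stationary, head section sweeps
      double tprev = theta;
      theta += cast_dir * cast_speed * dt;
      if (std::fabs(theta) >= th_max) {
        theta = (theta > 0) ? th_max : -th_max;
        cast_dir = -cast_dir;
        phase = INWARD;
      }
      if ((tprev > 0 && theta <= 0) || (tprev < 0 && theta >= 0)) {
        phase = OUTWARD; // crossed the centreline
        if (rng.unif() < 0.5) cast_dir = -cast_dir; // repeat-cast branch
      }
      if (phase == OUTWARD && std::fabs(theta) >= th_min && rng.unif() < r_cast * dt) {
        mode = RUN;
        run_time = 0.0;
        if (wv_enabled) {
          if (std::fabs(theta) > wv_max) wv_mode = WV_SUSPENDED;
          else { wv_mode = WV_CASTING; wv_dir = (rng.unif() < 0.5) ? 1 : -1; }
        }
      }
    }

    hx = jx + Lh * std::cos((alpha + theta) * D2R);
    hy = jy + Lh * std::sin((alpha + theta) * D2R);

    // wall response (skipped when the protocol truncates at the wall)
    if (ar.kind != 0 && tr_kind != 1) {
      double nx, ny, pen;
      if (ar.contact(hx, hy, nx, ny, pen)) {
        if (mode == RUN) {
          double h = alpha + theta;
          double ndeg = std::atan2(ny, nx) * R2D;
          double s = (wrap180(ndeg - h) >= 0) ? 1.0 : -1.0;
          theta += s * wall_deflect; // turn the head section away from the wall
          if (theta > th_max) theta = th_max;
          if (theta < -th_max) theta = -th_max;
          hx = jx + Lh * std::cos((alpha + theta) * D2R);
          hy = jy + Lh * std::sin((alpha + theta) * D2R);
          if (ar.contact(hx, hy, nx, ny, pen) && pen > 0) {
            double sx = nx * (pen + 1e-9), sy = ny * (pen + 1e-9);
            jx += sx; jy += sy; tx += sx; ty += sy; hx += sx; hy += sy;
          }
        } else {
          cast_dir = -cast_dir;
        }
      }
    }

    if (!(std::isfinite(jx) && std::isfinite(jy) && std::isfinite(alpha) && std::isfinite(theta))) {
      cause = -1;
      record(step * dt, c_now, phi, r_run, r_cast, r_wv);
      break;
    }

    // truncation rules
    bool stop = false;
    if (tr_kind == 1 && ar.kind != 0) {
      double nx, ny, pen;
      if (ar.contact(hx, hy, nx, ny, pen)) { stop = true; cause = 1; }
    } else if (tr_kind == 2) {
      double dx = jx - trp[0], dy = jy - trp[1];
      if (dx * dx + dy * dy <= trp[2] * trp[2]) { stop = true; cause = 2; }
    } else if (tr_kind == 3) {
      if (jx * trp[0] + jy * trp[1] >= trp[2]) { stop = true; cause = 3; }
    }

    if (stop || step == n_steps || (step % stride) == 0) {
      record(step * dt, c_now, phi, r_run, r_cast, r_wv);
    }
    if (stop) break;
  }

  int used = record_full ? nrec : std::min(nrec, 2);
  NumericMatrix traj(used, 15);
  for (int i = 0; i < used; ++i)
    for (int j = 0; j < 15; ++j) traj(i, j) = out(i, j);

  return List::create(_["traj"] = traj, _["cause"] = cause,
                      _["steps"] = std::min(step, n_steps));
}
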