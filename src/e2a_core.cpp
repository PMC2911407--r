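// Core chain construction, excluded-volume bookkeeping, pivot Monte Carlo and
// pair/contact computations for the extended two-angle chromatin model.
//
// All randomness goes through R's RNG so that set.seed() on the R side fixes
// ensembles bit-for-bit.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x = 0, y = 0, z = 0;
};
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
inline V3 unit(V3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

struct Frame {
  V3 pos, t, n;  // chain end, tangent, normal reference (unit, n perp t)
};

// element types: 0 nucleosome (sub 0 regular / 1 linker-histone skip),
//                1 naked-DNA joint followed by a straight segment
struct Element {
  int type = 0, sub = 0, gidx = -1;
  double len = 0;         // nucleosome: incoming linker length; DNA: segment length (nm)
  double a1 = 0, a2 = 0;  // nucleosome: alpha, beta; DNA: bend magnitude, azimuth
  double bp = 0;          // genomic coordinate of the placed site (bp)
};

struct ModelPar {
  double alpha_mean, alpha_sd, beta_mean, beta_sd;
  double lh_alpha_min, lh_alpha_max;
  double linker_nm, linker_sd, pitch_nm, wrap_off;
  double nrl_bp, linker_bp, rise, seg_bp, naked_lp;
  double sub_r, ring_r, dna_r, excl_bp;
  int max_retries;
  bool use_ev;
};

ModelPar read_par(const List& par) {
  ModelPar p;
  p.alpha_mean = par["alpha_mean"];
  p.alpha_sd = par["alpha_sd"];
  p.beta_mean = par["beta_mean"];
  p.beta_sd = par["beta_sd"];
  p.lh_alpha_min = par["lh_alpha_min"];
  p.lh_alpha_max = par["lh_alpha_max"];
  p.linker_nm = par["linker_nm"];
  p.linker_sd = par["linker_sd"];
  p.pitch_nm = par["pitch_nm"];
  p.wrap_off = par["wrap_off"];
  p.nrl_bp = par["nrl_bp"];
  p.linker_bp = par["linker_bp"];
  p.rise = par["rise"];
  p.seg_bp = par["seg_bp"];
  p.naked_lp = par["naked_lp"];
  p.sub_r = par["sub_r"];
  p.ring_r = par["ring_r"];
  p.dna_r = par["dna_r"];
  p.excl_bp = par["excl_bp"];
  p.max_retries = as<int>(par["max_retries"]);
  p.use_ev = as<bool>(par["use_ev"]);
  return p;
}

struct NucGeom {
  V3 entry, exit, center, axis, tin;
};

// Advance the frame through one nucleosome: the in/out linkers subtend the
// opening angle alpha at the nucleosome, the bend plane is rotated by the
// dihedral beta about the incoming linker, entry and exit are offset by the
// DNA pitch along the local nucleosome axis, and the octamer center sits on
// the inside of the kink at the wrap offset.
NucGeom nuc_step(Frame& f, double alpha, double beta, double len_in,
                 double pitch, double wrap_off) {
  V3 a = f.pos + len_in * f.t;
  double th = M_PI - alpha;
  V3 bn = cross(f.t, f.n);
  V3 tout = std::cos(th) * f.t +
            std::sin(th) * (std::cos(beta) * f.n + std::sin(beta) * bn);
  tout = unit(tout);
  V3 w = cross(f.t, tout);
  double wn = norm(w);
  V3 axis = (wn < 1e-10) ? f.n : (1.0 / wn) * w;
  V3 x = a + pitch * axis;
  V3 c = 0.5 * (a + x) + (0.5 * wrap_off) * (tout - f.t);
  NucGeom g{a, x, c, axis, f.t};
  V3 nn = f.t - dot(f.t, tout) * tout;
  if (norm(nn) < 1e-8) nn = f.n - dot(f.n, tout) * tout;
  f.pos = x;
  f.t = tout;
  f.n = unit(nn);
  return g;
}

// Advance through a naked-DNA joint: bend by g about azimuth psi, then move
// one segment forward. Returns the new vertex.
V3 dna_step(Frame& f, double g, double psi, double seg) {
  V3 bn = cross(f.t, f.n);
  V3 tout = std::cos(g) * f.t +
            std::sin(g) * (std::cos(psi) * f.n + std::sin(psi) * bn);
  tout = unit(tout);
  V3 nn = f.t - dot(f.t, tout) * tout;
  if (norm(nn) < 1e-8) nn = f.n - dot(f.n, tout) * tout;
  f.n = unit(nn);
  f.t = tout;
  f.pos = f.pos + seg * f.t;
  return f.pos;
}

// ---- excluded-volume point cloud + spatial hash grid ----------------------

struct EvCloud {
  std::vector<double> x, y, z, r, bp;
  void add(V3 p, double rad, double b) {
    x.push_back(p.x);
    y.push_back(p.y);
    z.push_back(p.z);
    r.push_back(rad);
    bp.push_back(b);
  }
  size_t size() const { return x.size(); }
};

// 7-sphere decomposition of the nucleosome cylinder: one central sphere plus
// six on a ring in the cylinder mid-plane.
void add_nuc_ev(EvCloud& c, const NucGeom& g, double bp, const ModelPar& p) {
  c.add(g.center, p.sub_r, bp);
  V3 u = cross(g.axis, g.tin);
  if (norm(u) < 1e-8) u = cross(g.axis, V3{1, 0, 0});
  if (norm(u) < 1e-8) u = cross(g.axis, V3{0, 1, 0});
  u = unit(u);
  V3 v = cross(g.axis, u);
  for (int k = 0; k < 6; ++k) {
    double ph = k * M_PI / 3.0;
    V3 q = g.center + (p.ring_r * std::cos(ph)) * u + (p.ring_r * std::sin(ph)) * v;
    c.add(q, p.sub_r, bp);
  }
}

// linker DNA between two present nucleosomes, as a chain of small spheres
void add_linker_ev(EvCloud& c, V3 from, V3 to, double bp_from, double bp_to,
                   const ModelPar& p) {
  double len = norm(to - from);
  int m = std::max(1, (int)std::ceil(len / (p.seg_bp * p.rise)));
  for (int i = 1; i < m; ++i) {
    double s = (double)i / m;
    c.add(from + s * (to - from), p.dna_r, bp_from + s * (bp_to - bp_from));
  }
}

struct Grid {
  double cell = 5.5;
  std::unordered_map<long long, std::vector<int>> cells;
  const EvCloud* pc = nullptr;

  static long long key(long long ix, long long iy, long long iz) {
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  }
  void reset(const EvCloud& c, double cell_) {
    cells.clear();
    pc = &c;
    cell = cell_;
  }
  void insert(int idx) {
    long long ix = (long long)std::floor(pc->x[idx] / cell);
    long long iy = (long long)std::floor(pc->y[idx] / cell);
    long long iz = (long long)std::floor(pc->z[idx] / cell);
    cells[key(ix, iy, iz)].push_back(idx);
  }
  bool clash(double x, double y, double z, double r, double bp,
             double excl) const {
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    long long iz = (long long)std::floor(z / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int idx : it->second) {
            if (std::fabs(bp - pc->bp[idx]) < excl) continue;
            double ddx = x - pc->x[idx], ddy = y - pc->y[idx],
                   ddz = z - pc->z[idx];
            double rr = r + pc->r[idx];
            if (ddx * ddx + ddy * ddy + ddz * ddz < rr * rr) return true;
          }
        }
    return false;
  }
};

// ---- element skeleton from a defect mask ----------------------------------

// mask codes: 0 regular, 1 linker-histone skip, 2 nucleosome skip
std::vector<Element> make_skeleton(const IntegerVector& mask,
                                   const ModelPar& p) {
  std::vector<Element> els;
  int n = mask.size();
  double pending_bp = 0;    // naked DNA accumulated from nucleosome skips
  double run_start_bp = 0;  // genomic start of the current naked run
  bool first = true;

  auto emit_run = [&](double bp_total, double start_bp) {
    double L = bp_total * p.rise;
    int m = std::max(1, (int)std::lround(bp_total / p.seg_bp));
    double seg = L / m;
    for (int i = 0; i < m; ++i) {
      Element e;
      e.type = 1;
      e.len = seg;
      e.bp = start_bp + (i + 1) * bp_total / m;
      els.push_back(e);
    }
  };

  for (int j = 0; j < n; ++j) {
    if (mask[j] == 2) {
      if (pending_bp == 0) run_start_bp = j * p.nrl_bp;
      pending_bp += p.nrl_bp;
      continue;
    }
    Element e;
    e.type = 0;
    e.sub = (mask[j] == 1) ? 1 : 0;
    e.gidx = j;
    e.bp = j * p.nrl_bp + p.linker_bp + (p.nrl_bp - p.linker_bp) / 2.0;
    if (first) {
      if (pending_bp > 0) {
        emit_run(pending_bp + p.linker_bp, run_start_bp);
        e.len = 0;
      } else {
        e.len = 0;
      }
      first = false;
    } else if (pending_bp > 0) {
      emit_run(pending_bp + p.linker_bp, run_start_bp);
      e.len = 0;
    } else {
      e.len = p.linker_nm;
    }
    pending_bp = 0;
    els.push_back(e);
  }
  if (pending_bp > 0) emit_run(pending_bp, run_start_bp);
  return els;
}

// ---- angle sampling -------------------------------------------------------

void draw_angles(Element& e, const ModelPar& p) {
  if (e.type == 0) {
    // incoming linker length varies between repeats (NRL heterogeneity);
    // elements entered from a naked-DNA run keep len 0
    if (e.len > 0 && p.linker_sd > 0)
      e.len = std::max(0.1, R::rnorm(p.linker_nm, p.linker_sd));
    if (e.sub == 1) {
      // H1 missing: entry-exit constraint released, opening angle uniform
      // on the configured wide interval; the dihedral keeps its regular
      // distribution (the stem fixes alpha, not the linker twist)
      e.a1 = R::runif(p.lh_alpha_min, p.lh_alpha_max);
      e.a2 = R::rnorm(p.beta_mean, p.beta_sd);
    } else {
      // constrained opening angle: Gaussian truncated at 3 SD with an
      // absolute steric floor -- the wrapped DNA and the H1 stem exclude
      // near-zero opening angles (the outgoing linker would fold back
      // through the incoming one inside the bonded-pair exemption of the
      // excluded-volume test)
      const double alpha_floor = 0.15;
      double lo = std::max(alpha_floor, p.alpha_mean - 3.0 * p.alpha_sd);
      double hi = std::min(M_PI - 1e-3, p.alpha_mean + 3.0 * p.alpha_sd);
      if (hi < lo) hi = lo;
      double a = R::rnorm(p.alpha_mean, p.alpha_sd);
      if (a < lo) a = lo;
      if (a > hi) a = hi;
      e.a1 = a;
      e.a2 = R::rnorm(p.beta_mean, p.beta_sd);
    }
  } else {
    double sd = std::sqrt(e.len / p.naked_lp);
    double gx = R::rnorm(0, sd), gy = R::rnorm(0, sd);
    e.a1 = std::sqrt(gx * gx + gy * gy);
    e.a2 = std::atan2(gy, gx);
  }
}

// ---- full chain build (fixed angles) --------------------------------------

struct ChainResult {
  std::vector<NucGeom> nucs;
  std::vector<double> nuc_bp;
  std::vector<int> nuc_gidx, nuc_sub;
  std::vector<double> nuc_a1, nuc_a2;
  std::vector<V3> dna_v;
  std::vector<double> dna_bp;
  std::vector<Frame> frames;  // frame AFTER each element
  EvCloud cloud;
};

void build_chain(const std::vector<Element>& els, const ModelPar& p,
                 ChainResult& out, size_t from = 0,
                 const Frame* start = nullptr) {
  Frame f;
  if (from == 0 || start == nullptr) {
    f = Frame{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}};
  } else {
    f = *start;
  }
  if (from == 0) {
    out.nucs.clear();
    out.nuc_bp.clear();
    out.nuc_gidx.clear();
    out.nuc_sub.clear();
    out.nuc_a1.clear();
    out.nuc_a2.clear();
    out.dna_v.clear();
    out.dna_bp.clear();
    out.frames.assign(els.size(), f);
    out.cloud = EvCloud();
  }
  for (size_t k = from; k < els.size(); ++k) {
    const Element& e = els[k];
    if (e.type == 0) {
      V3 prev_pos = f.pos;
      // linker spans [exit of previous nucleosome, entry of this one]
      double bp_to = e.bp - (p.nrl_bp - p.linker_bp) / 2.0;
      NucGeom g = nuc_step(f, e.a1, e.a2, e.len, p.pitch_nm, p.wrap_off);
      if (e.len > 0)
        add_linker_ev(out.cloud, prev_pos, g.entry, bp_to - p.linker_bp, bp_to,
                      p);
      add_nuc_ev(out.cloud, g, e.bp, p);
      out.nucs.push_back(g);
      out.nuc_bp.push_back(e.bp);
      out.nuc_gidx.push_back(e.gidx);
      out.nuc_sub.push_back(e.sub);
      out.nuc_a1.push_back(e.a1);
      out.nuc_a2.push_back(e.a2);
    } else {
      V3 v = dna_step(f, e.a1, e.a2, e.len);
      out.cloud.add(v, p.dna_r, e.bp);
      out.dna_v.push_back(v);
      out.dna_bp.push_back(e.bp);
    }
    out.frames[k] = f;
  }
}

List chain_to_list(const std::vector<Element>& els, const ChainResult& cr,
                   bool ok, int placed, long long retries) {
  int nn = cr.nucs.size();
  NumericMatrix centers(nn, 3), entry(nn, 3), exit_(nn, 3), axis(nn, 3),
      tin(nn, 3);
  for (int i = 0; i < nn; ++i) {
    const NucGeom& g = cr.nucs[i];
    centers(i, 0) = g.center.x;
    centers(i, 1) = g.center.y;
    centers(i, 2) = g.center.z;
    entry(i, 0) = g.entry.x;
    entry(i, 1) = g.entry.y;
    entry(i, 2) = g.entry.z;
    exit_(i, 0) = g.exit.x;
    exit_(i, 1) = g.exit.y;
    exit_(i, 2) = g.exit.z;
    axis(i, 0) = g.axis.x;
    axis(i, 1) = g.axis.y;
    axis(i, 2) = g.axis.z;
    tin(i, 0) = g.tin.x;
    tin(i, 1) = g.tin.y;
    tin(i, 2) = g.tin.z;
  }
  int nd = cr.dna_v.size();
  NumericMatrix dna(nd, 3);
  for (int i = 0; i < nd; ++i) {
    dna(i, 0) = cr.dna_v[i].x;
    dna(i, 1) = cr.dna_v[i].y;
    dna(i, 2) = cr.dna_v[i].z;
  }
  int K = els.size();
  IntegerVector el_type(K), el_sub(K), el_gidx(K);
  NumericVector el_len(K), el_a1(K), el_a2(K), el_bp(K);
  for (int k = 0; k < K; ++k) {
    el_type[k] = els[k].type;
    el_sub[k] = els[k].sub;
    el_gidx[k] = els[k].gidx;
    el_len[k] = els[k].len;
    el_a1[k] = els[k].a1;
    el_a2[k] = els[k].a2;
    el_bp[k] = els[k].bp;
  }
  return List::create(
      _["centers"] = centers, _["entry"] = entry, _["exit"] = exit_,
      _["axis"] = axis, _["tin"] = tin, _["nuc_bp"] = wrap(cr.nuc_bp),
      _["gidx"] = wrap(cr.nuc_gidx), _["lh_skip"] = wrap(cr.nuc_sub),
      _["alpha"] = wrap(cr.nuc_a1), _["beta"] = wrap(cr.nuc_a2),
      _["dna"] = dna, _["dna_bp"] = wrap(cr.dna_bp), _["el_type"] = el_type,
      _["el_sub"] = el_sub, _["el_gidx"] = el_gidx, _["el_len"] = el_len,
      _["el_a1"] = el_a1, _["el_a2"] = el_a2, _["el_bp"] = el_bp,
      _["ok"] = ok, _["n_placed"] = placed, _["retries"] = (double)retries);
}

std::vector<Element> els_from_list(const List& ch) {
  IntegerVector el_type = ch["el_type"], el_sub = ch["el_sub"],
                el_gidx = ch["el_gidx"];
  NumericVector el_len = ch["el_len"], el_a1 = ch["el_a1"], el_a2 = ch["el_a2"],
                el_bp = ch["el_bp"];
  std::vector<Element> els(el_type.size());
  for (int k = 0; k < el_type.size(); ++k) {
    els[k].type = el_type[k];
    els[k].sub = el_sub[k];
    els[k].gidx = el_gidx[k];
    els[k].len = el_len[k];
    els[k].a1 = el_a1[k];
    els[k].a2 = el_a2[k];
    els[k].bp = el_bp[k];
  }
  return els;
}

// EV points contributed by a single element placed from frame f (copy).
void element_ev_points(const Element& e, Frame& f, const ModelPar& p,
                       EvCloud& pts) {
  if (e.type == 0) {
    V3 prev_pos = f.pos;
    double bp_to = e.bp - (p.nrl_bp - p.linker_bp) / 2.0;
    NucGeom g = nuc_step(f, e.a1, e.a2, e.len, p.pitch_nm, p.wrap_off);
    if (e.len > 0)
      add_linker_ev(pts, prev_pos, g.entry, bp_to - p.linker_bp, bp_to, p);
    add_nuc_ev(pts, g, e.bp, p);
  } else {
    V3 v = dna_step(f, e.a1, e.a2, e.len);
    pts.add(v, p.dna_r, e.bp);
  }
}

}  // namespace

// ---------------------------------------------------------------------------
// exported functions
// ---------------------------------------------------------------------------

// Stochastic chain growth with excluded-volume rejection and backtracking:
// when a placement cannot be made clash-free within max_retries draws, the
// last few elements are removed and regrown (dead ends of self-avoiding
// growth); a global backtrack budget bounds the total work.
// [[Rcpp::export]]
List cpp_grow(IntegerVector mask, List par) {
  ModelPar p = read_par(par);
  int max_backtracks = 1000;
  if (par.containsElementNamed("max_backtracks"))
    max_backtracks = as<int>(par["max_backtracks"]);
  const int backtrack_depth = 25;
  std::vector<Element> els = make_skeleton(mask, p);
  size_t K = els.size();
  ChainResult cr;
  cr.frames.assign(K, Frame{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}});
  Frame f{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}};
  Grid grid;
  grid.reset(cr.cloud, 2.0 * std::max(p.sub_r, p.dna_r));
  // bookkeeping for backtracking: container sizes before each element
  std::vector<size_t> cstart(K + 1, 0), nstart(K + 1, 0), dstart(K + 1, 0);
  long long total_retries = 0;
  int backtracks = 0;
  size_t k = 0;

  while (k < K) {
    Element& e = els[k];
    cstart[k] = cr.cloud.size();
    nstart[k] = cr.nucs.size();
    dstart[k] = cr.dna_v.size();
    bool committed = false;
    for (int attempt = 0; attempt <= p.max_retries; ++attempt) {
      draw_angles(e, p);
      Frame fc = f;
      EvCloud cand;
      element_ev_points(e, fc, p, cand);
      bool clash = false;
      if (p.use_ev) {
        for (size_t i = 0; i < cand.size() && !clash; ++i)
          clash = grid.clash(cand.x[i], cand.y[i], cand.z[i], cand.r[i],
                             cand.bp[i], p.excl_bp);
      }
      if (!clash) {
        for (size_t i = 0; i < cand.size(); ++i) {
          cr.cloud.add(V3{cand.x[i], cand.y[i], cand.z[i]}, cand.r[i],
                       cand.bp[i]);
          grid.insert(cr.cloud.size() - 1);
        }
        if (e.type == 0) {
          Frame fr = f;
          NucGeom g = nuc_step(fr, e.a1, e.a2, e.len, p.pitch_nm, p.wrap_off);
          cr.nucs.push_back(g);
          cr.nuc_bp.push_back(e.bp);
          cr.nuc_gidx.push_back(e.gidx);
          cr.nuc_sub.push_back(e.sub);
          cr.nuc_a1.push_back(e.a1);
          cr.nuc_a2.push_back(e.a2);
        } else {
          cr.dna_v.push_back(fc.pos);
          cr.dna_bp.push_back(e.bp);
        }
        f = fc;
        cr.frames[k] = f;
        committed = true;
        ++k;
        break;
      }
      ++total_retries;
    }
    if (!committed) {
      if (backtracks >= max_backtracks || k == 0) {
        els.resize(k);
        return chain_to_list(els, cr, false, (int)k, total_retries);
      }
      ++backtracks;
      size_t kb = (k > (size_t)backtrack_depth) ? k - backtrack_depth : 0;
      cr.cloud.x.resize(cstart[kb]);
      cr.cloud.y.resize(cstart[kb]);
      cr.cloud.z.resize(cstart[kb]);
      cr.cloud.r.resize(cstart[kb]);
      cr.cloud.bp.resize(cstart[kb]);
      cr.nucs.resize(nstart[kb]);
      cr.nuc_bp.resize(nstart[kb]);
      cr.nuc_gidx.resize(nstart[kb]);
      cr.nuc_sub.resize(nstart[kb]);
      cr.nuc_a1.resize(nstart[kb]);
      cr.nuc_a2.resize(nstart[kb]);
      grid.reset(cr.cloud, 2.0 * std::max(p.sub_r, p.dna_r));
      for (size_t i = 0; i < cr.cloud.size(); ++i) grid.insert(i);
      f = (kb == 0) ? Frame{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}}
                    : cr.frames[kb - 1];
      k = kb;
    }
  }
  return chain_to_list(els, cr, true, (int)K, total_retries);
}

// Deterministic rebuild of a chain from stored element angles.
// [[Rcpp::export]]
List cpp_rebuild(List chain, List par) {
  ModelPar p = read_par(par);
  std::vector<Element> els = els_from_list(chain);
  ChainResult cr;
  build_chain(els, p, cr);
  return chain_to_list(els, cr, true, els.size(), 0);
}

// Pivot Monte Carlo: resample the internal coordinates of one site and
// rigidly rebuild everything downstream; accept iff the new configuration is
// clash-free. Because proposals are drawn from the same per-site
// distributions used during growth, acceptance on clash-freedom alone
// preserves the athermal target distribution.
// [[Rcpp::export]]
List cpp_mc(List chain, List par, int sweeps) {
  ModelPar p = read_par(par);
  std::vector<Element> els = els_from_list(chain);
  int K = els.size();
  if (K == 0) return chain;
  ChainResult cr;
  build_chain(els, p, cr);
  // per-element EV point ranges
  std::vector<int> ev_start(K + 1, 0);
  {
    ChainResult tmp;
    tmp.frames.assign(K, Frame{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}});
    Frame f{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}};
    for (int k = 0; k < K; ++k) {
      ev_start[k] = tmp.cloud.size();
      element_ev_points(els[k], f, p, tmp.cloud);
    }
    ev_start[K] = tmp.cloud.size();
  }
  long long accepted = 0, total = 0;
  long long nmoves = (long long)sweeps * K;
  for (long long mv = 0; mv < nmoves; ++mv) {
    int k = (int)std::floor(R::unif_rand() * K);
    if (k >= K) k = K - 1;
    Element old = els[k];
    draw_angles(els[k], p);
    ++total;
    // rebuild suffix from cached frame of element k-1
    Frame fstart =
        (k == 0) ? Frame{{0, 0, 0}, {0, 0, 1}, {1, 0, 0}} : cr.frames[k - 1];
    EvCloud suffix;
    std::vector<Frame> sfr(K - k);
    {
      Frame f = fstart;
      for (int j = k; j < K; ++j) {
        element_ev_points(els[j], f, p, suffix);
        sfr[j - k] = f;
      }
    }
    bool clash = false;
    if (p.use_ev) {
      // prefix grid: EV points of elements 0..k-1
      EvCloud prefix;
      for (int i = 0; i < ev_start[k]; ++i)
        prefix.add(V3{cr.cloud.x[i], cr.cloud.y[i], cr.cloud.z[i]},
                   cr.cloud.r[i], cr.cloud.bp[i]);
      Grid grid;
      grid.reset(prefix, 2.0 * std::max(p.sub_r, p.dna_r));
      for (size_t i = 0; i < prefix.size(); ++i) grid.insert(i);
      size_t n_site = ev_start[k + 1] - ev_start[k];
      for (size_t i = 0; i < suffix.size() && !clash; ++i)
        clash = grid.clash(suffix.x[i], suffix.y[i], suffix.z[i], suffix.r[i],
                          suffix.bp[i], p.excl_bp);
      if (!clash && n_site > 0 && K - k > 1) {
        // moved site's own points against the (rigid) downstream block
        EvCloud down;
        for (size_t i = n_site; i < suffix.size(); ++i)
          down.add(V3{suffix.x[i], suffix.y[i], suffix.z[i]}, suffix.r[i],
                   suffix.bp[i]);
        Grid g2;
        g2.reset(down, 2.0 * std::max(p.sub_r, p.dna_r));
        for (size_t i = 0; i < down.size(); ++i) g2.insert(i);
        for (size_t i = 0; i < n_site && !clash; ++i)
          clash = g2.clash(suffix.x[i], suffix.y[i], suffix.z[i], suffix.r[i],
                          suffix.bp[i], p.excl_bp);
      }
    }
    if (clash) {
      els[k] = old;
    } else {
      ++accepted;
      // commit: splice suffix EV points and rebuilt geometry
      // simplest correct update: full rebuild (O(K))
      build_chain(els, p, cr);
    }
  }
  List out = chain_to_list(els, cr, true, K, 0);
  out["mc_accepted"] = (double)accepted;
  out["mc_moves"] = (double)total;
  return out;
}

// Histogram of all unordered pair distances with r <= cutoff.
// pts may have 2 or 3 columns. cutoff < 0 means "no cutoff": bins cover the
// maximum distance. Returns counts, bin width, cutoff used and pair totals.
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix pts, double cutoff, double bin) {
  int n = pts.nrow(), d = pts.ncol();
  double cut = cutoff;
  if (cut < 0) {
    double m2 = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double s = 0;
        for (int c = 0; c < d; ++c) {
          double dd = pts(i, c) - pts(j, c);
          s += dd * dd;
        }
        if (s > m2) m2 = s;
      }
    cut = std::sqrt(m2) + bin;
  }
  int nb = std::max(1, (int)std::ceil(cut / bin));
  NumericVector counts(nb);
  double c2 = cut * cut;
  long long within = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double dd = pts(i, c) - pts(j, c);
        s += dd * dd;
      }
      if (s > c2) continue;
      int b = (int)std::floor(std::sqrt(s) / bin);
      if (b >= nb) b = nb - 1;
      counts[b] += 1;
      ++within;
    }
  return List::create(_["counts"] = counts, _["bin"] = bin, _["cutoff"] = cut,
                      _["n_points"] = n,
                      _["n_pairs_total"] = (double)n * (n - 1) / 2.0,
                      _["n_pairs_within"] = (double)within);
}

// Grid-accelerated contact detection: all unordered point pairs with
// 3D distance <= radius and genomic separation >= min_sep (bp).
// Returns 1-based point indices.
// [[Rcpp::export]]
List cpp_contacts(NumericMatrix pts, NumericVector bp, double radius,
                  double min_sep) {
  int n = pts.nrow();
  std::unordered_map<long long, std::vector<int>> cells;
  double cell = radius > 0 ? radius : 1.0;
  auto key = [](long long ix, long long iy, long long iz) {
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  };
  std::vector<long long> kx(n), ky(n), kz(n);
  for (int i = 0; i < n; ++i) {
    kx[i] = (long long)std::floor(pts(i, 0) / cell);
    ky[i] = (long long)std::floor(pts(i, 1) / cell);
    kz[i] = (long long)std::floor(pts(i, 2) / cell);
    cells[key(kx[i], ky[i], kz[i])].push_back(i);
  }
  std::vector<int> ii, jj;
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    // hash collisions can alias two distinct cells onto one bucket, so the
    // same neighbour may be seen from several scan offsets; dedupe per i
    std::vector<int> seen;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(kx[i] + dx, ky[i] + dy, kz[i] + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            if (std::fabs(bp[i] - bp[j]) < min_sep) continue;
            double ddx = pts(i, 0) - pts(j, 0), ddy = pts(i, 1) - pts(j, 1),
                   ddz = pts(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) seen.push_back(j);
          }
        }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (int j : seen) {
      ii.push_back(i + 1);
      jj.push_back(j + 1);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj));
}
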