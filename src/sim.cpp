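// Overdamped Langevin dynamics of a quasi-2D toy membrane: point lipid
// discs with soft-core repulsion plus up to two rigid elliptical protein
// bodies (rings of particles), in a periodic square box.  Optional
// restraints: a harmonic umbrella on the inter-body centre-of-mass
// separation and a torque-only orientational restraint per body
// (pivot-free radial-motion form with an area-scale regularizer).
//
// Thermal noise comes from a ziggurat normal sampler whose stream is
// seeded from R's RNG, so trajectories are reproducible under
// set.seed() on the calling side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// --- fast normal deviates: Marsaglia-Tsang ziggurat over xorshift64* ---
// The generator state is seeded from R's RNG at the start of every run,
// so trajectories remain bit-reproducible under set.seed().
namespace zig {
static uint64_t state;
static inline uint64_t next_u64() {
  uint64_t x = state;
  x ^= x >> 12;
  x ^= x << 25;
  x ^= x >> 27;
  state = x;
  return x * 0x2545F4914F6CDD1DULL;
}
static inline double next_unif() {
  return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
}
static uint32_t kn[128];
static double wn[128], fn[128];
static bool ready = false;
static void setup() {
  const double m = 2147483648.0;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  kn[0] = (uint32_t)((dn / q) * m);
  kn[1] = 0;
  wn[0] = q / m;
  wn[127] = dn / m;
  fn[0] = 1.0;
  fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    kn[i + 1] = (uint32_t)((dn / tn) * m);
    tn = dn;
    fn[i] = std::exp(-0.5 * dn * dn);
    wn[i] = dn / m;
  }
  ready = true;
}
static double nfix(int32_t hz, int iz) {
  const double r = 3.442619855899;
  double x, y;
  for (;;) {
    x = hz * wn[iz];
    if (iz == 0) {
      do {
        x = -std::log(next_unif()) / r;
        y = -std::log(next_unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -r - x;
    }
    if (fn[iz] + next_unif() * (fn[iz - 1] - fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    hz = (int32_t)(uint32_t)next_u64();
    iz = hz & 127;
    if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
  }
}
static inline double rnorm_fast() {
  int32_t hz = (int32_t)(uint32_t)next_u64();
  int iz = hz & 127;
  return ((uint32_t)std::abs(hz) < kn[iz]) ? hz * wn[iz] : nfix(hz, iz);
}
} // namespace zig

static inline double min_image(double d, double box) {
  if (d > 0.5 * box)
    d -= box;
  else if (d < -0.5 * box)
    d += box;
  return d;
}

static inline double wrap(double x, double box) {
  return x - box * std::floor(x / box);
}

// half-harmonic repulsion: U(r) = (eps/2)(1 - r/sig)^2 for r < sig
// force magnitude along the separation: (eps/sig)(1 - r/sig)
static inline void pair_force(double dx, double dy, double sig, double eps,
                              double &fx, double &fy) {
  double r2 = dx * dx + dy * dy;
  if (r2 >= sig * sig || r2 <= 0.0) {
    fx = 0.0; fy = 0.0;
    return;
  }
  double r = std::sqrt(r2);
  double fmag = (eps / sig) * (1.0 - r / sig) / r;
  fx = fmag * dx;
  fy = fmag * dy;
}

// [[Rcpp::export]]
List cpp_sim_run(NumericMatrix lipid0, NumericMatrix body_ref,
                 NumericVector com0, NumericVector angle0, int n_prot,
                 double box, double dt, double temperature, double friction,
                 double eps_pair, double sig_ll, double sig_lb, double sig_bb,
                 double k_umb, double d0, double k_rot, double eps_reg,
                 NumericVector theta_ref, int n_steps, int frame_stride,
                 int sample_stride, bool store_frames) {
  const int nl = lipid0.nrow();
  const int nb = body_ref.nrow();

  std::vector<double> lx(nl), ly(nl);
  for (int i = 0; i < nl; ++i) {
    lx[i] = lipid0(i, 0);
    ly[i] = lipid0(i, 1);
  }
  std::vector<double> cx(n_prot), cy(n_prot), th(n_prot);
  for (int p = 0; p < n_prot; ++p) {
    cx[p] = com0[2 * p];
    cy[p] = com0[2 * p + 1];
    th[p] = angle0[p];
  }

  // body-frame particle coordinates (shared shape for all bodies)
  std::vector<double> bx(nb), by(nb), r0sq(nb);
  double inertia = 0.0;
  for (int i = 0; i < nb; ++i) {
    bx[i] = body_ref(i, 0);
    by[i] = body_ref(i, 1);
    r0sq[i] = bx[i] * bx[i] + by[i] * by[i];
    inertia += r0sq[i];
  }
  // reference relative coordinates of the rotational restraint, per body
  std::vector<double> rrx(n_prot * nb), rry(n_prot * nb);
  for (int p = 0; p < n_prot; ++p) {
    double c = std::cos(theta_ref[p]), s = std::sin(theta_ref[p]);
    for (int i = 0; i < nb; ++i) {
      rrx[p * nb + i] = c * bx[i] - s * by[i];
      rry[p * nb + i] = s * bx[i] + c * by[i];
    }
  }

  // cell list for lipid-lipid neighbours (cells no smaller than sig_ll)
  int ncell = std::max(1, (int)std::floor(box / sig_ll));
  if (ncell < 4) ncell = 1; // box too small for a useful grid
  const double cellw = box / ncell;
  std::vector<int> cell_head(ncell * ncell), cell_next(nl);
  // bounding radius for lipid-body interaction pre-screening
  double body_rmax = 0.0;
  for (int i = 0; i < nb; ++i)
    body_rmax = std::max(body_rmax, std::sqrt(r0sq[i]));
  const double lb_cut = body_rmax + sig_lb;

  const int n_frames = store_frames ? n_steps / frame_stride : 0;
  const int n_body_frames = n_steps / frame_stride;
  const int n_samples = (n_prot == 2) ? n_steps / sample_stride : 0;

  NumericVector frame_time(n_body_frames);
  NumericVector lipid_frames(store_frames ? (R_xlen_t)n_frames * nl * 2 : 0);
  NumericVector com_frames((R_xlen_t)n_body_frames * n_prot * 2);
  NumericVector angle_frames((R_xlen_t)n_body_frames * n_prot);
  NumericVector sep_series(n_samples);
  NumericVector sample_time(n_samples);

  // per-step particle world coordinates and force accumulators
  std::vector<double> px(n_prot * nb), py(n_prot * nb);
  std::vector<double> flx(nl), fly(nl);
  std::vector<double> fcx(n_prot), fcy(n_prot), torq(n_prot);

  const double noise_l = std::sqrt(2.0 * temperature * dt / friction);
  const double noise_ct = std::sqrt(2.0 * temperature * dt / (friction * nb));
  const double noise_cr =
      std::sqrt(2.0 * temperature * dt / (friction * inertia));
  const double mob_l = dt / friction;
  const double mob_ct = dt / (friction * nb);
  const double mob_cr = dt / (friction * inertia);

  GetRNGstate();
  if (!zig::ready) zig::setup();
  // derive the stream state from R's RNG so set.seed() governs the run
  zig::state = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
               (uint64_t)(unif_rand() * 4294967296.0) ^ 0x9E3779B97F4A7C15ULL;
  if (zig::state == 0) zig::state = 0x9E3779B97F4A7C15ULL;
  for (int w = 0; w < 8; ++w) zig::next_u64(); // warm up

  int fidx = 0, sidx = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // body particle world coordinates
    for (int p = 0; p < n_prot; ++p) {
      double c = std::cos(th[p]), s = std::sin(th[p]);
      for (int i = 0; i < nb; ++i) {
        px[p * nb + i] = cx[p] + c * bx[i] - s * by[i];
        py[p * nb + i] = cy[p] + s * bx[i] + c * by[i];
      }
    }

    std::fill(flx.begin(), flx.end(), 0.0);
    std::fill(fly.begin(), fly.end(), 0.0);
    std::fill(fcx.begin(), fcx.end(), 0.0);
    std::fill(fcy.begin(), fcy.end(), 0.0);
    std::fill(torq.begin(), torq.end(), 0.0);

    double fx, fy;
    // lipid-lipid via cell list (half-neighbourhood enumeration)
    if (ncell == 1) {
      for (int i = 0; i < nl; ++i) {
        for (int j = i + 1; j < nl; ++j) {
          double dx = min_image(lx[i] - lx[j], box);
          if (std::fabs(dx) >= sig_ll) continue;
          double dy = min_image(ly[i] - ly[j], box);
          if (std::fabs(dy) >= sig_ll) continue;
          pair_force(dx, dy, sig_ll, eps_pair, fx, fy);
          flx[i] += fx; fly[i] += fy;
          flx[j] -= fx; fly[j] -= fy;
        }
      }
    } else {
      std::fill(cell_head.begin(), cell_head.end(), -1);
      for (int i = 0; i < nl; ++i) {
        int cxi = (int)(lx[i] / cellw); if (cxi >= ncell) cxi = ncell - 1;
        int cyi = (int)(ly[i] / cellw); if (cyi >= ncell) cyi = ncell - 1;
        int c = cyi * ncell + cxi;
        cell_next[i] = cell_head[c];
        cell_head[c] = i;
      }
      // half-stencil: same cell (j>i within list), E, NE, N, NW
      static const int sx[4] = {1, 1, 0, -1};
      static const int sy[4] = {0, 1, 1, 1};
      for (int cyi = 0; cyi < ncell; ++cyi) {
        for (int cxi = 0; cxi < ncell; ++cxi) {
          int c = cyi * ncell + cxi;
          for (int i = cell_head[c]; i >= 0; i = cell_next[i]) {
            for (int j = cell_next[i]; j >= 0; j = cell_next[j]) {
              double dx = min_image(lx[i] - lx[j], box);
              if (std::fabs(dx) >= sig_ll) continue;
              double dy = min_image(ly[i] - ly[j], box);
              if (std::fabs(dy) >= sig_ll) continue;
              pair_force(dx, dy, sig_ll, eps_pair, fx, fy);
              flx[i] += fx; fly[i] += fy;
              flx[j] -= fx; fly[j] -= fy;
            }
            for (int s = 0; s < 4; ++s) {
              int c2 = ((cyi + sy[s] + ncell) % ncell) * ncell +
                       (cxi + sx[s] + ncell) % ncell;
              for (int j = cell_head[c2]; j >= 0; j = cell_next[j]) {
                double dx = min_image(lx[i] - lx[j], box);
                if (std::fabs(dx) >= sig_ll) continue;
                double dy = min_image(ly[i] - ly[j], box);
                if (std::fabs(dy) >= sig_ll) continue;
                pair_force(dx, dy, sig_ll, eps_pair, fx, fy);
                flx[i] += fx; fly[i] += fy;
                flx[j] -= fx; fly[j] -= fy;
              }
            }
          }
        }
      }
    }
    // lipid-body (pre-screen on distance to the body COM)
    for (int p = 0; p < n_prot; ++p) {
      for (int i = 0; i < nl; ++i) {
        double dxc = min_image(lx[i] - cx[p], box);
        if (std::fabs(dxc) >= lb_cut) continue;
        double dyc = min_image(ly[i] - cy[p], box);
        if (std::fabs(dyc) >= lb_cut) continue;
        if (dxc * dxc + dyc * dyc >= lb_cut * lb_cut) continue;
        for (int k = 0; k < nb; ++k) {
          double rkx = px[p * nb + k] - cx[p];
          double rky = py[p * nb + k] - cy[p];
          double dx = dxc - rkx;
          if (std::fabs(dx) >= sig_lb) continue;
          double dy = dyc - rky;
          if (std::fabs(dy) >= sig_lb) continue;
          pair_force(dx, dy, sig_lb, eps_pair, fx, fy);
          flx[i] += fx; fly[i] += fy;
          fcx[p] -= fx; fcy[p] -= fy;
          torq[p] -= rkx * fy - rky * fx;
        }
      }
    }
    // body-body (between the two proteins)
    if (n_prot == 2) {
      double dxc = min_image(cx[0] - cx[1], box);
      double dyc = min_image(cy[0] - cy[1], box);
      for (int i = 0; i < nb; ++i) {
        double rix = px[i] - cx[0], riy = py[i] - cy[0];
        for (int j = 0; j < nb; ++j) {
          double rjx = px[nb + j] - cx[1], rjy = py[nb + j] - cy[1];
          double dx = dxc + rix - rjx;
          if (std::fabs(dx) >= sig_bb) continue;
          double dy = dyc + riy - rjy;
          if (std::fabs(dy) >= sig_bb) continue;
          pair_force(dx, dy, sig_bb, eps_pair, fx, fy);
          fcx[0] += fx; fcy[0] += fy;
          torq[0] += rix * fy - riy * fx;
          fcx[1] -= fx; fcy[1] -= fy;
          torq[1] -= rjx * fy - rjy * fx;
        }
      }
      // umbrella on COM separation
      double dsep = std::sqrt(dxc * dxc + dyc * dyc);
      if (k_umb > 0.0 && dsep > 0.0) {
        double fmag = -k_umb * (dsep - d0); // scalar force along separation
        fcx[0] += fmag * dxc / dsep;
        fcy[0] += fmag * dyc / dsep;
        fcx[1] -= fmag * dxc / dsep;
        fcy[1] -= fmag * dyc / dsep;
      }
      if (sample_stride > 0 && step % sample_stride == 0) {
        sep_series[sidx] = dsep;
        sample_time[sidx] = step * dt;
        ++sidx;
      }
    }
    // torque-only orientational restraint (pivot-free radial-motion form)
    if (k_rot > 0.0) {
      for (int p = 0; p < n_prot; ++p) {
        double tq = 0.0;
        for (int i = 0; i < nb; ++i) {
          double rx = px[p * nb + i] - cx[p];
          double ry = py[p * nb + i] - cy[p];
          double r0x = rrx[p * nb + i], r0y = rry[p * nb + i];
          double a = rx * r0y - ry * r0x;
          double b = rx * rx + ry * ry + eps_reg;
          // tau = -dV/dtheta for V = k/2 sum a^2/b with da/dtheta = -(r.r0)
          tq += k_rot * (a / b) * (rx * r0x + ry * r0y);
        }
        torq[p] += tq;
      }
    }

    // integrate (Euler-Maruyama, overdamped)
    for (int i = 0; i < nl; ++i) {
      lx[i] = wrap(lx[i] + mob_l * flx[i] + noise_l * zig::rnorm_fast(), box);
      ly[i] = wrap(ly[i] + mob_l * fly[i] + noise_l * zig::rnorm_fast(), box);
    }
    for (int p = 0; p < n_prot; ++p) {
      cx[p] = wrap(cx[p] + mob_ct * fcx[p] + noise_ct * zig::rnorm_fast(), box);
      cy[p] = wrap(cy[p] + mob_ct * fcy[p] + noise_ct * zig::rnorm_fast(), box);
      th[p] += mob_cr * torq[p] + noise_cr * zig::rnorm_fast();
    }

    if (step % frame_stride == 0) {
      if (!R_finite(cx[0]) || (nl > 0 && !R_finite(lx[0])))
        stop("non-finite coordinates at step %d (integration error)", step);
      frame_time[fidx] = step * dt;
      for (int p = 0; p < n_prot; ++p) {
        com_frames[(R_xlen_t)fidx * n_prot * 2 + 2 * p] = cx[p];
        com_frames[(R_xlen_t)fidx * n_prot * 2 + 2 * p + 1] = cy[p];
        angle_frames[(R_xlen_t)fidx * n_prot + p] = th[p];
      }
      if (store_frames) {
        R_xlen_t base = (R_xlen_t)fidx * nl * 2;
        for (int i = 0; i < nl; ++i) {
          lipid_frames[base + 2 * i] = lx[i];
          lipid_frames[base + 2 * i + 1] = ly[i];
        }
      }
      ++fidx;
    }
  }

  PutRNGstate();

  return List::create(
      _["frame_time"] = frame_time, _["lipid_frames"] = lipid_frames,
      _["com_frames"] = com_frames, _["angle_frames"] = angle_frames,
      _["sep_series"] = sep_series, _["sample_time"] = sample_time,
      _["n_frames"] = n_body_frames);
}
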