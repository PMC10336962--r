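// Canonical-ensemble Metropolis Monte Carlo engine for the bead-necklace
// model: hard-sphere beads on harmonic bonds with extended Debye-Hueckel
// electrostatics, a uniform soft short-range attraction between chain beads,
// and explicit counterions. Periodic cubic box, minimum image convention.
//
// Uses R's RNG (unif_rand/norm_rand) so runs are reproducible under set.seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double box;
  double a_bead, a_ion;       // hard-sphere radii, Angstrom
  double r0, bond_k;          // bond equilibrium length, force constant kT/A^2
  double eps_sr, sigma_sr;    // attraction depth (kT) and contact distance
  double lB, kappa;           // Bjerrum length, inverse Debye length
  int n_chain, n_ion;
};

inline double mi(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

inline double dist(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<double>& z, int i, int j, double box) {
  double dx = mi(x[i] - x[j], box);
  double dy = mi(y[i] - y[j], box);
  double dz = mi(z[i] - z[j], box);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// One mobile system: chain beads first, then counterions.
struct System {
  std::vector<double> x, y, z; // positions
  std::vector<int> q;          // charges
  Params p;

  int n() const { return p.n_chain + p.n_ion; }
  bool is_chain(int i) const { return i < p.n_chain; }
  double radius(int i) const { return is_chain(i) ? p.a_bead : p.a_ion; }

  // non-bonded pair energy in kT; sets *overlap on hard-core violation
  double pair_u(int i, int j, bool* overlap) const {
    double r = dist(x, y, z, i, j, p.box);
    double contact = radius(i) + radius(j);
    if (r < contact) { *overlap = true; return 0.0; }
    double u = 0.0;
    if (q[i] != 0 && q[j] != 0) {
      double ai = radius(i), aj = radius(j);
      u += p.lB * q[i] * q[j] * std::exp(-p.kappa * (r - ai - aj)) /
           (r * (1.0 + p.kappa * ai) * (1.0 + p.kappa * aj));
    }
    if (is_chain(i) && is_chain(j) && p.eps_sr != 0.0) {
      double s = p.sigma_sr / r;
      double s2 = s * s;
      u -= p.eps_sr * s2 * s2 * s2;
    }
    return u;
  }

  double bond_u(int i, int j) const {
    double r = dist(x, y, z, i, j, p.box);
    double d = r - p.r0;
    return 0.5 * p.bond_k * d * d;
  }

  // full energy; *overlap set on any hard-core violation
  double total_u(bool* overlap) const {
    *overlap = false;
    double u = 0.0;
    int m = n();
    for (int i = 0; i < m && !*overlap; ++i)
      for (int j = i + 1; j < m; ++j) {
        u += pair_u(i, j, overlap);
        if (*overlap) break;
      }
    for (int i = 0; i + 1 < p.n_chain; ++i) u += bond_u(i, i + 1);
    return u;
  }

  // energy of all terms involving particle i
  double particle_u(int i, bool* overlap) const {
    *overlap = false;
    double u = 0.0;
    int m = n();
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      u += pair_u(i, j, overlap);
      if (*overlap) return 0.0;
    }
    if (is_chain(i)) {
      if (i > 0) u += bond_u(i, i - 1);
      if (i + 1 < p.n_chain) u += bond_u(i, i + 1);
    }
    return u;
  }

  // energy of all terms involving at least one chain bead
  double chain_involved_u(bool* overlap) const {
    *overlap = false;
    double u = 0.0;
    int m = n();
    for (int i = 0; i < p.n_chain; ++i) {
      for (int j = i + 1; j < m; ++j) {
        u += pair_u(i, j, overlap);
        if (*overlap) return 0.0;
      }
    }
    for (int i = 0; i + 1 < p.n_chain; ++i) u += bond_u(i, i + 1);
    return u;
  }

  // energy of all terms involving at least one chain bead in [lo, hi]
  double segment_u(int lo, int hi, bool* overlap) const {
    *overlap = false;
    double u = 0.0;
    int m = n();
    for (int i = lo; i <= hi; ++i) {
      for (int j = 0; j < m; ++j) {
        if (j >= lo && j <= i) continue; // segment-internal pairs once
        u += pair_u(i, j, overlap);
        if (*overlap) return 0.0;
      }
    }
    int blo = (lo > 0) ? lo - 1 : 0;
    int bhi = (hi + 1 < p.n_chain) ? hi : hi - 1;
    for (int i = blo; i <= bhi; ++i) u += bond_u(i, i + 1);
    return u;
  }

  // chain-counterion cross terms only
  double chain_ion_u(bool* overlap) const {
    *overlap = false;
    double u = 0.0;
    int m = n();
    for (int i = 0; i < p.n_chain; ++i)
      for (int j = p.n_chain; j < m; ++j) {
        u += pair_u(i, j, overlap);
        if (*overlap) return 0.0;
      }
    return u;
  }

  double min_pair_distance() const {
    double mn = R_PosInf;
    int m = n();
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) {
        double r = dist(x, y, z, i, j, p.box);
        if (r < mn) mn = r;
      }
    return mn;
  }

  void rg_ree(double* rg, double* ree2) const {
    int N = p.n_chain;
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
    cx /= N; cy /= N; cz /= N;
    double s = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
    *rg = std::sqrt(s / N);
    double ex = x[N - 1] - x[0], ey = y[N - 1] - y[0], ez = z[N - 1] - z[0];
    *ree2 = ex * ex + ey * ey + ez * ez;
  }
};

// Inverse-CDF sampler for the radial bond Boltzmann density
// p(b) ~ b^2 exp(-k (b - r0)^2 / 2), used by the slither (reptation) move so
// that regrown bonds are drawn from their exact equilibrium distribution.
struct BondSampler {
  std::vector<double> grid, cdf;
  void init(double r0, double k) {
    int ng = 2048;
    double sd = 1.0 / std::sqrt(k);
    double lo = std::max(0.0, r0 - 8 * sd), hi = r0 + 8 * sd;
    grid.resize(ng); cdf.resize(ng);
    double acc = 0.0, prev = 0.0;
    for (int i = 0; i < ng; ++i) {
      double b = lo + (hi - lo) * i / (ng - 1);
      double d = b - r0;
      double w = b * b * std::exp(-0.5 * k * d * d);
      if (i > 0) acc += 0.5 * (w + prev) * (hi - lo) / (ng - 1);
      grid[i] = b; cdf[i] = acc; prev = w;
    }
    for (int i = 0; i < ng; ++i) cdf[i] /= acc;
  }
  double draw() const {
    double u = unif_rand();
    int lo = 0, hi = (int)cdf.size() - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid; else hi = mid;
    }
    double span = cdf[hi] - cdf[lo];
    double f = (span > 0) ? (u - cdf[lo]) / span : 0.5;
    return grid[lo] + f * (grid[hi] - grid[lo]);
  }
};

void rand_unit(double* ux, double* uy, double* uz) {
  double a = norm_rand(), b = norm_rand(), c = norm_rand();
  double nrm = std::sqrt(a * a + b * b + c * c);
  while (nrm < 1e-12) {
    a = norm_rand(); b = norm_rand(); c = norm_rand();
    nrm = std::sqrt(a * a + b * b + c * c);
  }
  *ux = a / nrm; *uy = b / nrm; *uz = c / nrm;
}

// Rodrigues rotation of (px,py,pz) about axis u through the origin
void rotate(double ux, double uy, double uz, double ang,
            double* px, double* py, double* pz) {
  double c = std::cos(ang), s = std::sin(ang);
  double dx = *px, dy = *py, dz = *pz;
  double dot = ux * dx + uy * dy + uz * dz;
  double cx = uy * dz - uz * dy;
  double cy = uz * dx - ux * dz;
  double cz = ux * dy - uy * dx;
  *px = dx * c + cx * s + ux * dot * (1 - c);
  *py = dy * c + cy * s + uy * dot * (1 - c);
  *pz = dz * c + cz * s + uz * dot * (1 - c);
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix chain0, NumericMatrix ions0,
                IntegerVector bead_charge, IntegerVector ion_charge,
                double box, double bead_radius, double ion_radius,
                double bond_r0, double bond_k, double eps_sr, double sigma_sr,
                double lB, double kappa,
                int n_equil, int n_prod, int sample_interval,
                double d_bead, double d_ion, double d_chain, double theta_max,
                NumericVector move_weights, int n_store_frames) {
  RNGScope scope;

  System s;
  s.p.box = box; s.p.a_bead = bead_radius; s.p.a_ion = ion_radius;
  s.p.r0 = bond_r0; s.p.bond_k = bond_k;
  s.p.eps_sr = eps_sr; s.p.sigma_sr = sigma_sr;
  s.p.lB = lB; s.p.kappa = kappa;
  s.p.n_chain = chain0.nrow(); s.p.n_ion = ions0.nrow();
  int N = s.p.n_chain, M = s.p.n_ion, m = N + M;

  s.x.resize(m); s.y.resize(m); s.z.resize(m); s.q.resize(m);
  for (int i = 0; i < N; ++i) {
    s.x[i] = chain0(i, 0); s.y[i] = chain0(i, 1); s.z[i] = chain0(i, 2);
    s.q[i] = bead_charge[i];
  }
  for (int i = 0; i < M; ++i) {
    s.x[N + i] = ions0(i, 0); s.y[N + i] = ions0(i, 1); s.z[N + i] = ions0(i, 2);
    s.q[N + i] = ion_charge[i];
  }

  bool overlap = false;
  double U = s.total_u(&overlap);
  if (overlap) stop("initial configuration has hard-sphere overlaps");

  // move classes: 0 single-particle, 1 pivot, 2 chain translate, 3 slither
  double w[4] = {move_weights[0], move_weights[1], move_weights[2],
                 move_weights[3]};
  if (N < 3) { w[1] = 0.0; w[3] = 0.0; }
  if (N < 2) { w[2] = 0.0; }
  double wtot = w[0] + w[1] + w[2] + w[3];
  if (wtot <= 0 || w[0] <= 0) stop("single-particle move weight must be > 0");

  BondSampler bond_sampler;
  if (w[3] > 0) bond_sampler.init(bond_r0, bond_k);

  // acceptance bookkeeping: bead, ion, pivot, chain, slither
  std::vector<double> attempted(5, 0.0), accepted(5, 0.0);

  int n_samples = (sample_interval > 0) ? n_prod / sample_interval : 0;
  NumericVector rg_series(n_samples), ree2_series(n_samples),
      energy_series(n_samples), sample_cycle(n_samples);
  double min_dist_seen = R_PosInf;
  int keep_every = 1;
  if (n_store_frames > 0 && n_samples > n_store_frames)
    keep_every = (n_samples + n_store_frames - 1) / n_store_frames;
  List frames;

  std::vector<double> tx, ty, tz; // trial buffers

  long total_cycles = (long)n_equil + n_prod;
  int sample_idx = 0;
  for (long cycle = 0; cycle < total_cycles; ++cycle) {
    for (int step = 0; step < m; ++step) {
      double u = unif_rand() * wtot;
      int cls = 0;
      if (u < w[0]) cls = 0;
      else if (u < w[0] + w[1]) cls = 1;
      else if (u < w[0] + w[1] + w[2]) cls = 2;
      else cls = 3;

      if (cls == 0) {
        // single-particle translation (bead or counterion)
        int i = (int)(unif_rand() * m);
        if (i >= m) i = m - 1;
        int slot = s.is_chain(i) ? 0 : 1;
        attempted[slot] += 1;
        double d = s.is_chain(i) ? d_bead : d_ion;
        double ox = s.x[i], oy = s.y[i], oz = s.z[i];
        bool ov = false;
        double u_old = s.particle_u(i, &ov);
        s.x[i] = ox + (2 * unif_rand() - 1) * d;
        s.y[i] = oy + (2 * unif_rand() - 1) * d;
        s.z[i] = oz + (2 * unif_rand() - 1) * d;
        double u_new = s.particle_u(i, &ov);
        double dU = u_new - u_old;
        if (!ov && (dU <= 0.0 || unif_rand() < std::exp(-dU))) {
          U += dU;
          accepted[slot] += 1;
        } else {
          s.x[i] = ox; s.y[i] = oy; s.z[i] = oz;
        }
      } else if (cls == 1) {
        // pivot: rotate the shorter chain segment about an interior bead
        attempted[2] += 1;
        int piv = 1 + (int)(unif_rand() * (N - 2));
        if (piv > N - 2) piv = N - 2;
        int lo, hi; // rotated index range [lo, hi]
        if (piv < N - 1 - piv) { lo = 0; hi = piv - 1; }
        else { lo = piv + 1; hi = N - 1; }
        double ux, uy, uz;
        rand_unit(&ux, &uy, &uz);
        double ang = (2 * unif_rand() - 1) * theta_max;
        tx.assign(s.x.begin() + lo, s.x.begin() + hi + 1);
        ty.assign(s.y.begin() + lo, s.y.begin() + hi + 1);
        tz.assign(s.z.begin() + lo, s.z.begin() + hi + 1);
        bool ov = false;
        double u_old = s.segment_u(lo, hi, &ov);
        for (int i = lo; i <= hi; ++i) {
          double px = s.x[i] - s.x[piv], py = s.y[i] - s.y[piv],
                 pz = s.z[i] - s.z[piv];
          rotate(ux, uy, uz, ang, &px, &py, &pz);
          s.x[i] = s.x[piv] + px; s.y[i] = s.y[piv] + py;
          s.z[i] = s.z[piv] + pz;
        }
        double u_new = s.segment_u(lo, hi, &ov);
        double dU = u_new - u_old;
        if (!ov && (dU <= 0.0 || unif_rand() < std::exp(-dU))) {
          U += dU;
          accepted[2] += 1;
        } else {
          for (int i = lo; i <= hi; ++i) {
            s.x[i] = tx[i - lo]; s.y[i] = ty[i - lo]; s.z[i] = tz[i - lo];
          }
        }
      } else if (cls == 2) {
        // rigid chain translation: only chain-ion terms change
        attempted[3] += 1;
        double dx = (2 * unif_rand() - 1) * d_chain;
        double dy = (2 * unif_rand() - 1) * d_chain;
        double dz = (2 * unif_rand() - 1) * d_chain;
        // rigid translation leaves all chain-internal coordinate differences
        // untouched; only chain-ion terms can change
        bool ov = false;
        double u_old = s.chain_ion_u(&ov);
        for (int i = 0; i < N; ++i) { s.x[i] += dx; s.y[i] += dy; s.z[i] += dz; }
        double u_new = s.chain_ion_u(&ov);
        double dU = u_new - u_old;
        if (!ov && (dU <= 0.0 || unif_rand() < std::exp(-dU))) {
          U += dU;
          accepted[3] += 1;
        } else {
          for (int i = 0; i < N; ++i) { s.x[i] -= dx; s.y[i] -= dy; s.z[i] -= dz; }
        }
      } else {
        // slither (reptation): drop one end bead, regrow at the other end
        // with bond length drawn from the exact bond Boltzmann density;
        // charges stay with residue indices, so coordinates shift by one.
        // The end-bond energy difference cancels against the proposal
        // density, so the acceptance uses only the remaining terms.
        attempted[4] += 1;
        bool head_to_tail = unif_rand() < 0.5;
        tx.assign(s.x.begin(), s.x.begin() + N);
        ty.assign(s.y.begin(), s.y.begin() + N);
        tz.assign(s.z.begin(), s.z.begin() + N);
        double ux, uy, uz;
        rand_unit(&ux, &uy, &uz);
        double b_new = bond_sampler.draw();
        double b_old = head_to_tail ? dist(s.x, s.y, s.z, 0, 1, s.p.box)
                                    : dist(s.x, s.y, s.z, N - 2, N - 1, s.p.box);
        bool ov = false;
        double u_old = s.chain_involved_u(&ov);
        if (head_to_tail) {
          for (int i = 0; i + 1 < N; ++i) {
            s.x[i] = tx[i + 1]; s.y[i] = ty[i + 1]; s.z[i] = tz[i + 1];
          }
          s.x[N - 1] = tx[N - 1] + b_new * ux;
          s.y[N - 1] = ty[N - 1] + b_new * uy;
          s.z[N - 1] = tz[N - 1] + b_new * uz;
        } else {
          for (int i = N - 1; i > 0; --i) {
            s.x[i] = tx[i - 1]; s.y[i] = ty[i - 1]; s.z[i] = tz[i - 1];
          }
          s.x[0] = tx[0] + b_new * ux;
          s.y[0] = ty[0] + b_new * uy;
          s.z[0] = tz[0] + b_new * uz;
        }
        double u_new = s.chain_involved_u(&ov);
        double dU = u_new - u_old;
        double db = b_new - bond_r0, dbo = b_old - bond_r0;
        double dU_other = dU - 0.5 * bond_k * (db * db - dbo * dbo);
        if (!ov && (dU_other <= 0.0 || unif_rand() < std::exp(-dU_other))) {
          U += dU;
          accepted[4] += 1;
        } else {
          for (int i = 0; i < N; ++i) {
            s.x[i] = tx[i]; s.y[i] = ty[i]; s.z[i] = tz[i];
          }
        }
      }
    }

    if (cycle >= n_equil && sample_interval > 0 &&
        ((cycle - n_equil + 1) % sample_interval == 0) &&
        sample_idx < n_samples) {
      double rg, ree2;
      s.rg_ree(&rg, &ree2);
      rg_series[sample_idx] = rg;
      ree2_series[sample_idx] = ree2;
      energy_series[sample_idx] = U;
      sample_cycle[sample_idx] = (double)(cycle - n_equil + 1);
      double md = s.min_pair_distance();
      if (md < min_dist_seen) min_dist_seen = md;
      if (keep_every <= 1 || sample_idx % keep_every == 0) {
        NumericMatrix cm(N, 3), im(M, 3);
        for (int i = 0; i < N; ++i) {
          cm(i, 0) = s.x[i]; cm(i, 1) = s.y[i]; cm(i, 2) = s.z[i];
        }
        for (int i = 0; i < M; ++i) {
          im(i, 0) = s.x[N + i]; im(i, 1) = s.y[N + i]; im(i, 2) = s.z[N + i];
        }
        frames.push_back(List::create(_["chain"] = cm, _["ions"] = im,
                                      _["energy"] = U,
                                      _["cycle"] = (double)(cycle - n_equil + 1)));
      }
      ++sample_idx;
    }
  }

  bool ov_final = false;
  double U_recomputed = s.total_u(&ov_final);

  NumericMatrix chain_final(N, 3), ions_final(M, 3);
  for (int i = 0; i < N; ++i) {
    chain_final(i, 0) = s.x[i]; chain_final(i, 1) = s.y[i];
    chain_final(i, 2) = s.z[i];
  }
  for (int i = 0; i < M; ++i) {
    ions_final(i, 0) = s.x[N + i]; ions_final(i, 1) = s.y[N + i];
    ions_final(i, 2) = s.z[N + i];
  }

  CharacterVector move_names = CharacterVector::create(
      "single_bead", "single_ion", "pivot", "chain_translate", "slither");
  return List::create(
      _["rg_series"] = rg_series, _["ree2_series"] = ree2_series,
      _["energy_series"] = energy_series, _["sample_cycle"] = sample_cycle,
      _["frames"] = frames,
      _["move_type"] = move_names,
      _["attempted"] = NumericVector(attempted.begin(), attempted.end()),
      _["accepted"] = NumericVector(accepted.begin(), accepted.end()),
      _["energy_running"] = U, _["energy_recomputed"] = U_recomputed,
      _["min_pair_distance"] = min_dist_seen,
      _["chain_final"] = chain_final, _["ions_final"] = ions_final);
}
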