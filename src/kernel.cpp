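// Brownian-dynamics kernel: advects independent point particles through the
// instantaneous network flow for one flow-update interval. The flow (segment
// fluxes and pinch state per edge) is frozen during the interval, matching
// the quasi-steady hydraulic solve. Uses R's RNG so a single set.seed()
// governs the whole simulation.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct EdgeFlow {
  double Q1, Q4, b, bdot, L, L1, l, R;
  bool active;
};

// local geometry and flux at axial position z (piecewise linear pinch at the
// edge midpoint; L1 = L2)
inline void local_state(const EdgeFlow& f, double z, double& a, double& adot,
                        double& az, double& Q) {
  if (!f.active) {
    a = f.R; adot = 0.0; az = 0.0; Q = f.Q1;
    return;
  }
  const double z0 = f.L1 + f.L;
  if (z <= f.L1) {
    a = f.R; adot = 0.0; az = 0.0; Q = f.Q1;
  } else if (z >= f.L1 + 2.0 * f.L) {
    a = f.R; adot = 0.0; az = 0.0; Q = f.Q4;
  } else if (z <= z0) {
    const double w = (z - f.L1) / f.L;
    a = f.b * w + f.R * (1.0 - w);
    adot = f.bdot * w;
    az = (f.b - f.R) / f.L;
    Q = f.Q1 - 2.0 * M_PI * f.L * f.bdot *
        ((f.b - f.R) * w * w * w / 3.0 + f.R * w * w / 2.0);
  } else {
    const double w = (z - z0) / f.L;
    const double om = 1.0 - w;
    const double Qz0 = f.Q1 - 2.0 * M_PI * f.bdot * f.L * (f.R / 6.0 + f.b / 3.0);
    a = f.b * om + f.R * w;
    adot = f.bdot * om;
    az = (f.R - f.b) / f.L;
    Q = Qz0 - 2.0 * M_PI * f.L * f.bdot *
        (f.b * (1.0 - om * om * om) / 3.0 + f.R * (w * w / 2.0 - w * w * w / 3.0));
  }
}

inline void velocity(double a, double adot, double az, double Q, double r,
                     double slip, double& u, double& v) {
  const double rho = r / a;
  const double g = slip / a;
  const double denom = 1.0 + 4.0 * g;
  const double Qpa2 = Q / (M_PI * a * a);
  u = 2.0 / denom * Qpa2 * (1.0 - rho * rho + 2.0 * g);
  v = adot * rho * (2.0 - rho * rho + 4.0 * g) / denom +
      2.0 / denom * az * Qpa2 * rho *
          (1.0 + 3.0 * g - rho * rho - g / denom * (4.0 * g + 2.0 - rho * rho));
}

}  // namespace

// [[Rcpp::export]]
List advance_particles(NumericMatrix state, int n_sub, double dt, double t0,
                       double D, double rp, double slip,
                       IntegerVector ei, IntegerVector ej, NumericVector elen,
                       NumericVector erad, NumericVector ex1, NumericVector ey1,
                       NumericVector eax, NumericVector eay,
                       NumericVector Q1, NumericVector Q4, NumericVector bmin,
                       NumericVector bdot, NumericVector Lp, NumericVector L1,
                       IntegerVector node_ptr, IntegerVector node_edge,
                       IntegerVector node_orient,
                       NumericMatrix rec_x, NumericMatrix rec_y, int rec_every,
                       int step0, bool record_visits, bool check_confinement) {
  const int np = state.nrow();
  const int E = ei.size();
  std::vector<EdgeFlow> flows(E);
  for (int e = 0; e < E; ++e) {
    flows[e] = {Q1[e], Q4[e], bmin[e], bdot[e], Lp[e], L1[e],
                elen[e], erad[e], Lp[e] > 0.0};
  }
  const double sig = std::sqrt(2.0 * D * dt);
  std::vector<double> ev;       // particle, from, to, t_depart, t_arrive
  std::vector<double> visits;   // particle, time, node
  int confinement_violations = 0;
  const int n_rec = rec_x.ncol();

  for (int s = 0; s < n_sub; ++s) {
    const double t = t0 + (s + 1) * dt;
    for (int p = 0; p < np; ++p) {
      int e = (int)state(p, 0) - 1;
      double z = state(p, 1), y1 = state(p, 2), y2 = state(p, 3);
      const EdgeFlow* f = &flows[e];
      double a, adot, az, Q, u, v;
      double r = std::sqrt(y1 * y1 + y2 * y2);
      local_state(*f, z, a, adot, az, Q);
      // wall may have moved inwards past the particle between flow updates:
      // project back inside (r = a - rp), or to the axis if the lumen is
      // narrower than the particle
      if (r > a - rp) {
        const double rnew = (a - rp > 0.0) ? a - rp : 0.0;
        const double scale = (r > 0.0) ? rnew / r : 0.0;
        y1 *= scale; y2 *= scale; r = rnew;
      }
      velocity(a, adot, az, Q, r, slip, u, v);
      z += u * dt + sig * norm_rand();
      if (r > 0.0) {
        const double vr = v / r;
        y1 += vr * y1 * dt;
        y2 += vr * y2 * dt;
      }
      y1 += sig * norm_rand();
      y2 += sig * norm_rand();

      // node arrival: assign to node, do traversal bookkeeping, re-enter a
      // neighbouring tubule at its node-side end on the axis (instantaneous
      // node residence)
      if (z < 0.0 || z > f->l) {
        const int m = (z < 0.0) ? ei[e] : ej[e];
        const int last = (int)state(p, 4);
        if (last > 0 && last != m) {
          ev.push_back(p + 1.0);
          ev.push_back(last);
          ev.push_back(m);
          ev.push_back(state(p, 5));
          ev.push_back(t);
        }
        if (record_visits) {
          visits.push_back(p + 1.0);
          visits.push_back(t);
          visits.push_back(m);
        }
        state(p, 4) = m;
        state(p, 5) = t;
        // Peclet-weighted choice among incident tubules
        const int k0 = node_ptr[m - 1], k1 = node_ptr[m];
        double wsum = 0.0;
        double w[16];
        int nk = k1 - k0;
        if (nk > 16) nk = 16;
        for (int k = 0; k < nk; ++k) {
          const int fe = node_edge[k0 + k];
          const double R2 = erad[fe] * erad[fe];
          const double U = (node_orient[k0 + k] > 0)
                               ? flows[fe].Q1 / (M_PI * R2)
                               : -flows[fe].Q4 / (M_PI * R2);
          const double pe = U * erad[fe] / D;
          w[k] = (pe + 1.0 > 0.0) ? pe + 1.0 : 0.0;
          wsum += w[k];
        }
        int chosen = 0;
        if (wsum <= 0.0) {
          chosen = (int)(unif_rand() * nk);
          if (chosen >= nk) chosen = nk - 1;
        } else {
          double uu = unif_rand() * wsum, acc = 0.0;
          for (int k = 0; k < nk; ++k) {
            acc += w[k];
            if (uu <= acc) { chosen = k; break; }
            chosen = k;
          }
        }
        e = node_edge[k0 + chosen];
        f = &flows[e];
        z = (node_orient[k0 + chosen] > 0) ? 0.0 : f->l;
        y1 = 0.0; y2 = 0.0;
      }

      // wall interaction: specular reflection off the local wall, with the
      // finite particle radius; clamp to the axis if reflections do not
      // converge or the lumen is narrower than the particle
      r = std::sqrt(y1 * y1 + y2 * y2);
      local_state(*f, z, a, adot, az, Q);
      const double aeff = a - rp;
      if (aeff <= 0.0) {
        y1 = 0.0; y2 = 0.0;
      } else if (r > aeff) {
        double rr = r;
        int it = 0;
        while (rr > aeff && it < 10) {
          rr = 2.0 * aeff - rr;
          if (rr < 0.0) rr = -rr;
          ++it;
        }
        if (rr > aeff) rr = 0.0;
        if (check_confinement && rr > aeff) ++confinement_violations;
        const double scale = (r > 0.0) ? rr / r : 0.0;
        y1 *= scale; y2 *= scale;
      }

      state(p, 0) = e + 1;
      state(p, 1) = z;
      state(p, 2) = y1;
      state(p, 3) = y2;

      if (check_confinement) {
        double rr2 = std::sqrt(y1 * y1 + y2 * y2);
        if (rr2 > a - rp + 1e-12 && a - rp > 0) ++confinement_violations;
      }
    }
    const int g = step0 + s + 1;
    if (rec_every > 0 && g % rec_every == 0) {
      const int col = g / rec_every - 1;
      if (col >= 0 && col < n_rec) {
        for (int p = 0; p < np; ++p) {
          const int e = (int)state(p, 0) - 1;
          const double z = state(p, 1), y1 = state(p, 2);
          rec_x(p, col) = ex1[e] + eax[e] * z - eay[e] * y1;
          rec_y(p, col) = ey1[e] + eay[e] * z + eax[e] * y1;
        }
      }
    }
  }

  NumericMatrix evm((int)(ev.size() / 5), 5);
  for (size_t k = 0; k < ev.size(); ++k) evm(k / 5, k % 5) = ev[k];
  colnames(evm) = CharacterVector::create("particle", "from", "to",
                                          "t_depart", "t_arrive");
  List out = List::create(Named("events") = evm,
                          Named("confinement_violations") = confinement_violations);
  if (record_visits) {
    NumericMatrix vm((int)(visits.size() / 3), 3);
    for (size_t k = 0; k < visits.size(); ++k) vm(k / 3, k % 3) = visits[k];
    colnames(vm) = CharacterVector::create("particle", "time", "node");
    out["visits"] = vm;
  }
  return out;
}
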