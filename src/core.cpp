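// Hybrid stochastic / reaction-diffusion core for the cell-polarity model.
//
// Each cell lives on a periodic 1D membrane domain. Membrane-bound Rac/Rho
// molecules are tracked individually (fixed-timestep Bernoulli event
// sampling); branched (A) and bundled (B) F-actin densities follow two
// coupled reaction-diffusion equations integrated with explicit Euler and
// second-order central differences. Cells in a group are stepped jointly;
// all intercellular terms read the neighbour's previous-step state
// (explicit coupling), so an uncoupled group is bit-for-bit a set of
// independent single-cell runs given matched per-cell RNG streams.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// ---- deterministic RNG (per-cell substreams) ------------------------------

inline uint64_t sm64_mix(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  void seed(uint64_t v) {
    // splitmix64 expansion of the 64-bit seed
    uint64_t t = v;
    for (int i = 0; i < 4; ++i) { t = sm64_mix(t + (uint64_t)i * 0x632BE59BD9B4E019ULL); s[i] = t; }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }
  uint64_t next() { // xoshiro256++
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (double)(next() >> 11) * 0x1.0p-53; }
};

inline uint64_t cell_stream(uint64_t root, int cell) {
  uint64_t x = root + 0x9E3779B97F4A7C15ULL * (uint64_t)(cell + 1);
  return sm64_mix(x) & ((1ULL << 53) - 1);
}

// ---- configuration structs -------------------------------------------------

struct DynRate { // concentration-dependent gamma amplification
  int cell, sp, rate, src, ssp;
  double gamma;
  std::vector<int> idx, mir; // 0-based grid indices, aligned target<->mirror
};

struct DynEps { // concentration-dependent growth modification
  int cell, src;
  std::vector<int> idx, mir;
  double c[4]; // eAA, eAB, eBA, eBB
};

struct Stim {
  int cell, on, off;              // active for on <= step < off
  std::vector<double> prof[2];    // replacement k_on profiles (Rac, Rho)
};

struct Cell {
  double kon[2], koff[2], kfb, alpha, beta, m0, D, Dmem, rinh, Ccrit, eps0[2];
  int N[2];
  double init_frac, init_noise;
  std::vector<double> pos[2]; // bound molecule arclength positions
  int ninact[2];
  std::vector<double> A, B;
  std::vector<double> konfac[2], kofffac[2]; // constant junction factors
  std::vector<double> epsc[2];               // constant junction eps fields
  Xoshiro rng;
};

inline int wrap(int i, int n) { i %= n; return i < 0 ? i + n : i; }

// circular moving-sum of per-bin counts over +/- h bins
void window_counts(const std::vector<int>& bin, int h, std::vector<double>& out) {
  int n = (int)bin.size();
  double acc = 0;
  for (int j = -h; j <= h; ++j) acc += bin[wrap(j, n)];
  for (int i = 0; i < n; ++i) {
    out[i] = acc;
    acc -= bin[wrap(i - h, n)];
    acc += bin[wrap(i + h + 1, n)];
  }
}

// polarity axis: circular midpoint of the largest contiguous supra-threshold
// arc of A; defined only if both A and B exceed Ccrit somewhere.
bool axis_of(const std::vector<double>& A, const std::vector<double>& B,
             double Ccrit, double& ang_deg) {
  int n = (int)A.size();
  double mA = A[0], mB = B[0];
  int iA = 0;
  for (int i = 1; i < n; ++i) {
    if (A[i] > mA) { mA = A[i]; iA = i; }
    if (B[i] > mB) mB = B[i];
  }
  if (!(mA > Ccrit && mB > Ccrit)) return false;
  int nab = 0;
  for (int i = 0; i < n; ++i) nab += (A[i] > Ccrit);
  if (nab == n) { ang_deg = iA * 360.0 / n; return true; } // no edge: use peak
  double bestLen = -1, bestDen = 0;
  int bestStart = 0;
  for (int i = 0; i < n; ++i) {
    if (A[i] > Ccrit && !(A[wrap(i - 1, n)] > Ccrit)) {
      int len = 0, j = i; double den = 0;
      while (len < n && A[wrap(j, n)] > Ccrit) { den += A[wrap(j, n)]; ++len; ++j; }
      bool better = len > bestLen ||
        (len == bestLen && (den > bestDen + 1e-12 ||
         (std::fabs(den - bestDen) <= 1e-12 && i < bestStart)));
      if (better) { bestLen = len; bestDen = den; bestStart = i; }
    }
  }
  double mid = bestStart + (bestLen - 1) / 2.0;
  while (mid >= n) mid -= n;
  while (mid < 0) mid += n;
  ang_deg = mid * 360.0 / n;
  return true;
}

} // namespace

// [[Rcpp::export]]
double derive_cell_seed_cpp(double root, int cell) {
  return (double)cell_stream((uint64_t)root, cell);
}

// [[Rcpp::export]]
List sim_group_cpp(List cfg) {
  const int ng      = as<int>(cfg["n_grid"]);
  const double ds   = as<double>(cfg["ds"]);
  const double dt   = as<double>(cfg["dt"]);
  const int nsteps  = as<int>(cfg["n_steps"]);
  const int stride  = as<int>(cfg["stride"]);
  const bool neutralize  = as<bool>(cfg["neutralize"]);
  const double veto      = as<double>(cfg["veto"]);
  const bool check       = as<bool>(cfg["check"]);
  const bool rec_fields  = as<bool>(cfg["record_fields"]);
  const double L = ng * ds;

  List cl = cfg["cells"];
  const int nc = cl.size();
  std::vector<Cell> cells((size_t)nc);

  List konfacL = cfg["konfac"], kofffacL = cfg["kofffac"], epscL = cfg["epsc"];

  for (int c = 0; c < nc; ++c) {
    List p = cl[c];
    Cell& C = cells[c];
    NumericVector kon = p["kon"], koff = p["koff"], N = p["N"], eps0 = p["eps0"];
    for (int s = 0; s < 2; ++s) {
      C.kon[s] = kon[s]; C.koff[s] = koff[s];
      C.N[s] = (int)N[s]; C.eps0[s] = eps0[s];
      if (C.N[s] < 0) stop("negative molecule count");
    }
    C.kfb = as<double>(p["kfb"]);   C.alpha = as<double>(p["alpha"]);
    C.beta = as<double>(p["beta"]); C.m0 = as<double>(p["m0"]);
    C.D = as<double>(p["D"]);       C.Dmem = as<double>(p["Dmem"]);
    C.rinh = as<double>(p["rinh"]);
    C.Ccrit = as<double>(p["Ccrit"]);
    C.init_frac = as<double>(p["init_frac"]);
    C.init_noise = as<double>(p["init_noise"]);
    C.rng.seed((uint64_t)as<double>(p["seed"]));
    C.A.assign(ng, 1.0); C.B.assign(ng, 1.0);

    for (int s = 0; s < 2; ++s) {
      C.konfac[s].assign(ng, 1.0); C.kofffac[s].assign(ng, 1.0);
      C.epsc[s].assign(ng, 0.0);
    }
    if (konfacL.size() > c && !Rf_isNull(konfacL[c])) {
      NumericMatrix m = konfacL[c];
      for (int i = 0; i < ng; ++i) { C.konfac[0][i] = m(i, 0); C.konfac[1][i] = m(i, 1); }
    }
    if (kofffacL.size() > c && !Rf_isNull(kofffacL[c])) {
      NumericMatrix m = kofffacL[c];
      for (int i = 0; i < ng; ++i) { C.kofffac[0][i] = m(i, 0); C.kofffac[1][i] = m(i, 1); }
    }
    if (epscL.size() > c && !Rf_isNull(epscL[c])) {
      NumericMatrix m = epscL[c];
      for (int i = 0; i < ng; ++i) { C.epsc[0][i] = m(i, 0); C.epsc[1][i] = m(i, 1); }
    }

    // --- initial condition (RNG order: A noise, B noise, Rac pos, Rho pos) --
    bool haveA = p.containsElementNamed("initA") && !Rf_isNull(p["initA"]);
    if (haveA) {
      NumericVector a0 = p["initA"], b0 = p["initB"];
      for (int i = 0; i < ng; ++i) { C.A[i] = a0[i]; C.B[i] = b0[i]; }
    } else {
      for (int i = 0; i < ng; ++i) C.A[i] = 1.0 + C.init_noise * (2.0 * C.rng.unif() - 1.0);
      for (int i = 0; i < ng; ++i) C.B[i] = 1.0 + C.init_noise * (2.0 * C.rng.unif() - 1.0);
    }
    bool havePos = p.containsElementNamed("init_pos") && !Rf_isNull(p["init_pos"]);
    for (int s = 0; s < 2; ++s) {
      if (havePos) {
        List ip = p["init_pos"];
        NumericVector v = ip[s];
        C.pos[s].assign(v.begin(), v.end());
        if ((int)C.pos[s].size() > C.N[s]) stop("init_pos exceeds molecule count");
      } else {
        int nb = (int)std::lround(C.init_frac * C.N[s]);
        C.pos[s].resize(nb);
        for (int k = 0; k < nb; ++k) C.pos[s][k] = C.rng.unif() * L;
      }
      C.ninact[s] = C.N[s] - (int)C.pos[s].size();
    }
  }

  // dynamic couplings
  std::vector<DynRate> dynr;
  {
    List dl = cfg["dyn_rate"];
    for (int k = 0; k < dl.size(); ++k) {
      List e = dl[k];
      DynRate d;
      d.cell = as<int>(e["cell"]) - 1; d.sp = as<int>(e["species"]) - 1;
      d.rate = as<int>(e["rate"]) - 1; d.src = as<int>(e["src_cell"]) - 1;
      d.ssp = as<int>(e["src_species"]) - 1; d.gamma = as<double>(e["gamma"]);
      IntegerVector idx = e["idx"], mir = e["mir"];
      for (int i = 0; i < idx.size(); ++i) { d.idx.push_back(idx[i] - 1); d.mir.push_back(mir[i] - 1); }
      dynr.push_back(d);
    }
  }
  std::vector<DynEps> dyne;
  {
    List dl = cfg["dyn_eps"];
    for (int k = 0; k < dl.size(); ++k) {
      List e = dl[k];
      DynEps d;
      d.cell = as<int>(e["cell"]) - 1; d.src = as<int>(e["src_cell"]) - 1;
      IntegerVector idx = e["idx"], mir = e["mir"];
      NumericVector cf = e["coef"];
      for (int i = 0; i < 4; ++i) d.c[i] = cf[i];
      for (int i = 0; i < idx.size(); ++i) { d.idx.push_back(idx[i] - 1); d.mir.push_back(mir[i] - 1); }
      dyne.push_back(d);
    }
  }
  std::vector<Stim> stims;
  {
    List sl = cfg["stim"];
    for (int k = 0; k < sl.size(); ++k) {
      List e = sl[k];
      Stim s;
      s.cell = as<int>(e["cell"]) - 1;
      s.on = as<int>(e["step_on"]); s.off = as<int>(e["step_off"]);
      NumericMatrix m = e["prof"];
      for (int sp = 0; sp < 2; ++sp) {
        s.prof[sp].resize(ng);
        for (int i = 0; i < ng; ++i) s.prof[sp][i] = m(i, sp);
      }
      stims.push_back(s);
    }
  }

  const int nout = nsteps / stride + 1;
  NumericMatrix axis(nout, nc);
  LogicalMatrix polar(nout, nc);
  NumericVector tout(nout);
  std::vector<NumericMatrix> snapA, snapB;
  std::vector<IntegerMatrix> snapNr, snapNo;
  if (rec_fields) {
    for (int c = 0; c < nc; ++c) {
      snapA.push_back(NumericMatrix(ng, nout));
      snapB.push_back(NumericMatrix(ng, nout));
      snapNr.push_back(IntegerMatrix(ng, nout));
      snapNo.push_back(IntegerMatrix(ng, nout));
    }
  }

  // work buffers
  std::vector<std::vector<int> > bin(nc * 2, std::vector<int>(ng, 0));
  std::vector<std::vector<double> > win(nc * 2, std::vector<double>(ng, 0.0));
  std::vector<std::vector<double> > prevA(nc), prevB(nc);
  std::vector<double> konfld[2], kofffld[2], epsf[2], cw;
  for (int s = 0; s < 2; ++s) { konfld[s].resize(ng); kofffld[s].resize(ng); epsf[s].resize(ng); }
  cw.resize(ng);
  std::vector<double> newA(ng), newB(ng);
  std::vector<int> vbin[2]; std::vector<double> vwin[2];
  for (int s = 0; s < 2; ++s) { vbin[s].assign(ng, 0); vwin[s].assign(ng, 0.0); }

  const double dcoef = dt / (ds * ds);

  auto record = [&](int r, int step) {
    tout[r] = step * dt;
    for (int c = 0; c < nc; ++c) {
      double ang;
      bool ok = axis_of(cells[c].A, cells[c].B, cells[c].Ccrit, ang);
      polar(r, c) = ok;
      axis(r, c) = ok ? ang : NA_REAL;
      if (rec_fields) {
        for (int i = 0; i < ng; ++i) {
          snapA[c](i, r) = cells[c].A[i];
          snapB[c](i, r) = cells[c].B[i];
          snapNr[c](i, r) = bin[c * 2 + 0][i];
          snapNo[c](i, r) = bin[c * 2 + 1][i];
        }
      }
    }
  };

  // bin counts for step 0 recording
  for (int c = 0; c < nc; ++c)
    for (int s = 0; s < 2; ++s) {
      std::fill(bin[c * 2 + s].begin(), bin[c * 2 + s].end(), 0);
      for (double p : cells[c].pos[s]) {
        int i = (int)(p / ds); if (i >= ng) i = ng - 1;
        bin[c * 2 + s][i]++;
      }
    }
  record(0, 0);

  for (int step = 0; step < nsteps; ++step) {
    // ---- snapshot previous-step state --------------------------------------
    for (int c = 0; c < nc; ++c) {
      Cell& C = cells[c];
      int h = std::max(1, (int)std::lround(C.rinh / ds));
      for (int s = 0; s < 2; ++s) {
        std::fill(bin[c * 2 + s].begin(), bin[c * 2 + s].end(), 0);
        for (double p : C.pos[s]) {
          int i = (int)(p / ds); if (i >= ng) i = ng - 1;
          bin[c * 2 + s][i]++;
        }
        window_counts(bin[c * 2 + s], h, win[c * 2 + s]);
      }
      prevA[c] = C.A; prevB[c] = C.B;
    }

    // ---- per-cell update ---------------------------------------------------
    for (int c = 0; c < nc; ++c) {
      Cell& C = cells[c];

      // effective kinetic-rate fields
      const Stim* sact = nullptr;
      for (const Stim& s : stims)
        if (s.cell == c && step >= s.on && step < s.off) sact = &s;
      for (int sp = 0; sp < 2; ++sp) {
        const std::vector<double>& F = (sp == 0) ? prevA[c] : prevB[c];
        for (int i = 0; i < ng; ++i) {
          double base = sact ? sact->prof[sp][i]
                             : C.kon[sp] * (1.0 + C.beta * F[i]);
          konfld[sp][i] = base * C.konfac[sp][i];
          kofffld[sp][i] = C.koff[sp] * C.kofffac[sp][i];
        }
      }
      for (const DynRate& d : dynr) {
        if (d.cell != c) continue;
        std::vector<double>& fld = (d.rate == 0) ? konfld[d.sp] : kofffld[d.sp];
        const std::vector<double>& nsrc = win[d.src * 2 + d.ssp];
        for (size_t k = 0; k < d.idx.size(); ++k) {
          double f = std::max(1.0, d.gamma * nsrc[d.mir[k]]);
          fld[d.idx[k]] *= f;
        }
      }

      // growth-modification fields
      for (int sp = 0; sp < 2; ++sp)
        for (int i = 0; i < ng; ++i) epsf[sp][i] = C.epsc[sp][i] + C.eps0[sp];
      for (const DynEps& d : dyne) {
        if (d.cell != c) continue;
        const std::vector<double>& An = prevA[d.src];
        const std::vector<double>& Bn = prevB[d.src];
        for (size_t k = 0; k < d.idx.size(); ++k) {
          int i = d.idx[k], j = d.mir[k];
          epsf[0][i] += d.c[0] * An[j] + d.c[1] * Bn[j];
          epsf[1][i] += d.c[2] * An[j] + d.c[3] * Bn[j];
        }
      }

      // ---- stochastic GTPase events ----------------------------------------
      // membrane diffusion of bound molecules (uniform increments with
      // variance 2 * Dmem * dt); molecules drifting into a high-k_off arc
      // are removed by the unbinding phase right below
      if (C.Dmem > 0) {
        double a = std::sqrt(6.0 * C.Dmem * dt);
        for (int sp = 0; sp < 2; ++sp)
          for (double& p : C.pos[sp]) {
            p += a * (2.0 * C.rng.unif() - 1.0);
            while (p >= L) p -= L;
            while (p < 0) p += L;
          }
      }
      // unbinding phase (both species) first, so the mutual-inhibition veto
      // below reflects the molecules actually present
      for (int sp = 0; sp < 2; ++sp) {
        std::vector<double>& P = C.pos[sp];
        for (size_t k = 0; k < P.size();) {
          int i = (int)(P[k] / ds); if (i >= ng) i = ng - 1;
          double pr = 1.0 - std::exp(-kofffld[sp][i] * dt);
          if (C.rng.unif() < pr) {
            P[k] = P.back(); P.pop_back(); C.ninact[sp]++;
          } else ++k;
        }
      }

      // veto windows from post-unbinding positions
      int h = std::max(1, (int)std::lround(C.rinh / ds));
      for (int sp = 0; sp < 2; ++sp) {
        std::fill(vbin[sp].begin(), vbin[sp].end(), 0);
        for (double p : C.pos[sp]) {
          int i = (int)(p / ds); if (i >= ng) i = ng - 1;
          vbin[sp][i]++;
        }
        window_counts(vbin[sp], h, vwin[sp]);
      }

      // binding + recruitment phase (Rac then Rho)
      for (int sp = 0; sp < 2; ++sp) {
        const std::vector<double>& oppwin = vwin[1 - sp];
        std::vector<double>& P = C.pos[sp];
        size_t n_recruiters = P.size();

        // binding: per inactive molecule, hazard = spatial mean of k_on field
        double tot = 0;
        for (int i = 0; i < ng; ++i) { tot += konfld[sp][i]; cw[i] = tot; }
        double kbar = tot / ng;
        if (kbar > 0 && C.ninact[sp] > 0) {
          double pb = 1.0 - std::exp(-kbar * dt);
          int navail = C.ninact[sp];
          for (int k = 0; k < navail; ++k) {
            if (C.rng.unif() >= pb) continue;
            double u = C.rng.unif() * tot;
            int i = (int)(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
            if (i >= ng) i = ng - 1;
            if (oppwin[i] > 0 && (veto >= 1.0 || C.rng.unif() < veto)) continue;
            double p = (i + C.rng.unif()) * ds;
            if (p >= L) p -= L;
            P.push_back(p); C.ninact[sp]--;
          }
        }

        // feedback recruitment by molecules bound at start of the substep
        if (C.kfb > 0) {
          double pf = 1.0 - std::exp(-C.kfb * dt);
          for (size_t k = 0; k < n_recruiters; ++k) {
            if (C.ninact[sp] <= 0) break;
            if (C.rng.unif() >= pf) continue;
            double p = P[k] + (2.0 * C.rng.unif() - 1.0) * C.rinh;
            while (p >= L) p -= L;
            while (p < 0) p += L;
            int i = (int)(p / ds); if (i >= ng) i = ng - 1;
            if (oppwin[i] > 0 && (veto >= 1.0 || C.rng.unif() < veto)) continue;
            P.push_back(p); C.ninact[sp]--;
          }
        }

        // neutralization: rebind 10% of a fully unbound species
        if (neutralize && P.empty() && C.N[sp] > 0) {
          int nb = (int)std::lround(C.init_frac * C.N[sp]);
          nb = std::min(nb, C.ninact[sp]);
          for (int k = 0; k < nb; ++k) {
            P.push_back(C.rng.unif() * L); C.ninact[sp]--;
          }
        }

        if (check && (int)P.size() + C.ninact[sp] != C.N[sp])
          stop("mass conservation violated (cell %d species %d step %d)",
               c + 1, sp + 1, step);
      }

      // ---- reaction-diffusion update of A, B -------------------------------
      const std::vector<double>& nR = win[c * 2 + 0];
      const std::vector<double>& nH = win[c * 2 + 1];
      const std::vector<double>& A = C.A;
      const std::vector<double>& B = C.B;
      bool bad = false;
      for (int i = 0; i < ng; ++i) {
        int im = (i == 0) ? ng - 1 : i - 1, ip = (i == ng - 1) ? 0 : i + 1;
        double a = A[i], b = B[i];
        double ra = a * (1.0 + C.alpha * nR[i] + epsf[0][i]) - a * a - C.m0 * a * b;
        double rb = b * (1.0 + C.alpha * nH[i] + epsf[1][i]) - b * b - C.m0 * a * b;
        double na = a + dt * ra + dcoef * C.D * (A[ip] - 2.0 * a + A[im]);
        double nb = b + dt * rb + dcoef * C.D * (B[ip] - 2.0 * b + B[im]);
        if (!std::isfinite(na) || !std::isfinite(nb)) { bad = true; break; }
        newA[i] = na > 0 ? na : 0.0;
        newB[i] = nb > 0 ? nb : 0.0;
      }
      if (bad)
        stop("non-finite actin field (cell %d, step %d, t=%g)", c + 1, step, step * dt);
      C.A = newA; C.B = newB;
    }

    if ((step + 1) % stride == 0) {
      // refresh bins for the record (positions changed this step)
      if (rec_fields) {
        for (int c = 0; c < nc; ++c)
          for (int s = 0; s < 2; ++s) {
            std::fill(bin[c * 2 + s].begin(), bin[c * 2 + s].end(), 0);
            for (double p : cells[c].pos[s]) {
              int i = (int)(p / ds); if (i >= ng) i = ng - 1;
              bin[c * 2 + s][i]++;
            }
          }
      }
      record((step + 1) / stride, step + 1);
    }
  }

  // ---- outputs --------------------------------------------------------------
  NumericMatrix Af(ng, nc), Bf(ng, nc);
  List bound(nc);
  NumericMatrix inact(2, nc);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < ng; ++i) { Af(i, c) = cells[c].A[i]; Bf(i, c) = cells[c].B[i]; }
    std::vector<double> pr = cells[c].pos[0], ph = cells[c].pos[1];
    std::sort(pr.begin(), pr.end()); std::sort(ph.begin(), ph.end());
    bound[c] = List::create(_["rac"] = NumericVector(pr.begin(), pr.end()),
                            _["rho"] = NumericVector(ph.begin(), ph.end()));
    inact(0, c) = cells[c].ninact[0]; inact(1, c) = cells[c].ninact[1];
  }
  List out = List::create(
    _["time"] = tout, _["axis"] = axis, _["polarized"] = polar,
    _["A"] = Af, _["B"] = Bf, _["bound"] = bound, _["inactive"] = inact);
  if (rec_fields) {
    List sa(nc), sb(nc), sr(nc), so(nc);
    for (int c = 0; c < nc; ++c) { sa[c] = snapA[c]; sb[c] = snapB[c]; sr[c] = snapNr[c]; so[c] = snapNo[c]; }
    out["A_snapshots"] = sa; out["B_snapshots"] = sb;
    out["rac_snapshots"] = sr; out["rho_snapshots"] = so;
  }
  return out;
}
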