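// Coarse-grained Langevin engine: force terms, BAOAB integrator.
// Coordinates are arma::mat (N x 3). All energies in kT units when
// temperature = 1; masses and lengths in model units.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct EnmData {
  arma::uvec i, j;   // 0-based site indices
  arma::vec r0, k;
};

struct Term {
  std::string type;
  // enm / pair_restraints
  EnmData enm;
  // double_basin: arbitrary sub-terms for each basin
  std::vector<Term> basinA, basinB;
  double beta_mix = 1.0, dv = 0.0;
  // bias
  arma::mat bias_forces;   // N x 3
  // tether (harmonic position restraint)
  arma::uvec idx;
  arma::mat ref;           // n x 3
  double kspr = 0.0;
  // steered
  std::string coordinate;  // "pair_distance" or "projection"
  arma::uvec g1, g2;
  arma::vec axis;
  double k_pull = 0.0, center0 = 0.0, velocity = 0.0;
  // targeted
  arma::mat target;
  double k_t = 0.0, rmsd0 = 0.0;
  // soft repulsion
  arma::uvec tracer_idx, protein_idx;
  arma::vec sigma_protein;
  double eps = 0.0, sigma_tt = 0.0, eps_tt = 0.0;
  // cylinder wall
  double radius = 0.0, zlo = 0.0, zhi = 0.0, kwall = 0.0;
};

EnmData parse_enm(const List& t) {
  EnmData e;
  e.i = as<arma::uvec>(t["i"]);
  e.j = as<arma::uvec>(t["j"]);
  e.r0 = as<arma::vec>(t["r0"]);
  e.k = as<arma::vec>(t["k"]);
  if (e.i.n_elem != e.j.n_elem || e.i.n_elem != e.r0.n_elem ||
      e.i.n_elem != e.k.n_elem)
    stop("elastic-network term: pair arrays have inconsistent lengths");
  return e;
}

Term parse_one(const List& t);

std::vector<Term> parse_terms(const List& terms) {
  std::vector<Term> out;
  for (R_xlen_t ti = 0; ti < terms.size(); ++ti)
    out.push_back(parse_one(terms[ti]));
  return out;
}

Term parse_one(const List& t) {
    Term p;
    p.type = as<std::string>(t["type"]);
    if (p.type == "enm" || p.type == "pair_restraints") {
      p.enm = parse_enm(t);
    } else if (p.type == "double_basin") {
      p.basinA.push_back(parse_one(as<List>(t["basin_a"])));
      p.basinB.push_back(parse_one(as<List>(t["basin_b"])));
      p.beta_mix = as<double>(t["beta_mix"]);
      p.dv = as<double>(t["dv"]);
    } else if (p.type == "bias") {
      p.bias_forces = as<arma::mat>(t["forces"]);
    } else if (p.type == "tether") {
      p.idx = as<arma::uvec>(t["idx"]);
      p.ref = as<arma::mat>(t["ref"]);
      p.kspr = as<double>(t["k"]);
    } else if (p.type == "steered") {
      p.coordinate = as<std::string>(t["coordinate"]);
      p.g1 = as<arma::uvec>(t["group1"]);
      if (p.coordinate == "pair_distance") p.g2 = as<arma::uvec>(t["group2"]);
      else p.axis = arma::normalise(as<arma::vec>(t["axis"]));
      p.k_pull = as<double>(t["k_pull"]);
      p.center0 = as<double>(t["center0"]);
      p.velocity = as<double>(t["velocity"]);
    } else if (p.type == "targeted") {
      p.idx = as<arma::uvec>(t["idx"]);
      p.target = as<arma::mat>(t["target"]);
      p.k_t = as<double>(t["k_t"]);
      p.rmsd0 = as<double>(t["rmsd0"]);
      if (p.idx.n_elem < 3)
        stop("targeted restraint: superposition needs at least 3 sites");
    } else if (p.type == "soft_repulsion") {
      p.tracer_idx = as<arma::uvec>(t["tracer_idx"]);
      p.protein_idx = as<arma::uvec>(t["protein_idx"]);
      p.sigma_protein = as<arma::vec>(t["sigma_protein"]);
      p.eps = as<double>(t["eps"]);
      p.sigma_tt = as<double>(t["sigma_tt"]);
      p.eps_tt = as<double>(t["eps_tt"]);
    } else if (p.type == "cylinder_wall") {
      p.idx = as<arma::uvec>(t["idx"]);
      p.radius = as<double>(t["radius"]);
      p.zlo = as<double>(t["zlo"]);
      p.zhi = as<double>(t["zhi"]);
      p.kwall = as<double>(t["k"]);
    } else {
      stop("unknown force term type: " + p.type);
    }
    return p;
}

double enm_energy_forces(const EnmData& e, const arma::mat& x, arma::mat& f) {
  double en = 0.0;
  const arma::uword N = x.n_rows;
  const double* xp = x.memptr();  // column-major: x, then y, then z
  double* fp = f.memptr();
  const arma::uword* ip = e.i.memptr();
  const arma::uword* jp = e.j.memptr();
  const double* r0p = e.r0.memptr();
  const double* kp = e.k.memptr();
  for (arma::uword p = 0; p < e.i.n_elem; ++p) {
    const arma::uword a = ip[p], b = jp[p];
    const double dx = xp[a] - xp[b];
    const double dy = xp[a + N] - xp[b + N];
    const double dz = xp[a + 2 * N] - xp[b + 2 * N];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - r0p[p];
    en += 0.5 * kp[p] * dr * dr;
    if (r > 1e-12) {
      const double c = -kp[p] * dr / r;
      fp[a] += c * dx;         fp[b] -= c * dx;
      fp[a + N] += c * dy;     fp[b + N] -= c * dy;
      fp[a + 2 * N] += c * dz; fp[b + 2 * N] -= c * dz;
    }
  }
  return en;
}

double term_energy_forces(const Term& p, const arma::mat& x, double t_now,
                          arma::mat& f);

// Optimal proper rotation Q (and translation) superposing y onto x;
// returns rmsd. Rows of y map as  y Qt + t  (row-vector convention).
double kabsch_rmsd(const arma::mat& x, const arma::mat& y, arma::mat& Q,
                   arma::rowvec& tvec) {
  arma::rowvec cx = arma::mean(x, 0), cy = arma::mean(y, 0);
  arma::mat xc = x.each_row() - cx, yc = y.each_row() - cy;
  arma::mat H = yc.t() * xc;               // 3x3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("targeted restraint: SVD failed");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;
  Q = V * D * U.t();                       // column-vector rotation
  tvec = cx - cy * Q.t();
  arma::mat resid = xc - yc * Q.t();
  double msd = arma::accu(resid % resid) / x.n_rows;
  return std::sqrt(std::max(msd, 0.0));
}

double term_energy_forces(const Term& p, const arma::mat& x, double t_now,
                          arma::mat& f) {
  const arma::uword N = x.n_rows;
  if (p.type == "enm" || p.type == "pair_restraints") {
    return enm_energy_forces(p.enm, x, f);
  }
  if (p.type == "double_basin") {
    arma::mat fa(N, 3, arma::fill::zeros), fb(N, 3, arma::fill::zeros);
    double va = term_energy_forces(p.basinA[0], x, t_now, fa) + p.dv;
    double vb = term_energy_forces(p.basinB[0], x, t_now, fb);
    // E = -log(exp(-bm*va) + exp(-bm*vb)) / bm, log-sum-exp guarded
    double m = std::min(va, vb);
    double ea = std::exp(-p.beta_mix * (va - m));
    double eb = std::exp(-p.beta_mix * (vb - m));
    double en = m - std::log(ea + eb) / p.beta_mix;
    double wa = ea / (ea + eb);
    f += wa * fa + (1.0 - wa) * fb;
    return en;
  }
  if (p.type == "bias") {
    f += p.bias_forces;
    return -arma::accu(p.bias_forces % x);
  }
  if (p.type == "tether") {
    double en = 0.0;
    for (arma::uword q = 0; q < p.idx.n_elem; ++q) {
      arma::rowvec d = x.row(p.idx[q]) - p.ref.row(q);
      en += 0.5 * p.kspr * arma::dot(d, d);
      f.row(p.idx[q]) -= p.kspr * d;
    }
    return en;
  }
  if (p.type == "steered") {
    double c0 = p.center0 + p.velocity * t_now;
    if (p.coordinate == "pair_distance") {
      arma::rowvec c1 = arma::mean(x.rows(p.g1), 0);
      arma::rowvec c2 = arma::mean(x.rows(p.g2), 0);
      arma::rowvec d = c1 - c2;
      double r = std::sqrt(arma::dot(d, d));
      double dr = r - c0;
      if (r > 1e-12) {
        arma::rowvec g = (p.k_pull * dr / r) * d;  // dV/dc1
        for (arma::uword q = 0; q < p.g1.n_elem; ++q)
          f.row(p.g1[q]) -= g / p.g1.n_elem;
        for (arma::uword q = 0; q < p.g2.n_elem; ++q)
          f.row(p.g2[q]) += g / p.g2.n_elem;
      }
      return 0.5 * p.k_pull * dr * dr;
    }
    // projection of group centroid on axis
    arma::rowvec c1 = arma::mean(x.rows(p.g1), 0);
    double proj = arma::dot(c1.t(), p.axis);
    double dr = proj - c0;
    arma::rowvec g = (p.k_pull * dr) * p.axis.t();
    for (arma::uword q = 0; q < p.g1.n_elem; ++q)
      f.row(p.g1[q]) -= g / p.g1.n_elem;
    return 0.5 * p.k_pull * dr * dr;
  }
  if (p.type == "targeted") {
    arma::mat xs = x.rows(p.idx);
    arma::mat Q;
    arma::rowvec tv;
    double r = kabsch_rmsd(xs, p.target, Q, tv);
    double dr = r - p.rmsd0;
    double en = 0.5 * p.k_t * dr * dr;
    if (r > 1e-12) {
      arma::mat fitted = p.target * Q.t();
      fitted.each_row() += tv;
      arma::mat resid = xs - fitted;  // n x 3
      // dV/dx_i = k_t (r - rmsd0) / (n r) * resid_i  (superposition optimal)
      double pref = p.k_t * dr / (p.idx.n_elem * r);
      for (arma::uword q = 0; q < p.idx.n_elem; ++q)
        f.row(p.idx[q]) -= pref * resid.row(q);
    }
    return en;
  }
  if (p.type == "soft_repulsion") {
    // quartic soft core: E = eps * (1 - (r/sigma)^2)^2  for r < sigma
    double en = 0.0;
    for (arma::uword a = 0; a < p.tracer_idx.n_elem; ++a) {
      arma::uword ia = p.tracer_idx[a];
      for (arma::uword b = 0; b < p.protein_idx.n_elem; ++b) {
        arma::uword ib = p.protein_idx[b];
        double sig = p.sigma_protein[b];
        arma::rowvec d = x.row(ia) - x.row(ib);
        double r2 = arma::dot(d, d);
        if (r2 < sig * sig && sig > 0) {
          double u = 1.0 - r2 / (sig * sig);
          en += p.eps * u * u;
          arma::rowvec fv = (4.0 * p.eps * u / (sig * sig)) * d;
          f.row(ia) += fv;
          f.row(ib) -= fv;
        }
      }
      for (arma::uword b = a + 1; b < p.tracer_idx.n_elem; ++b) {
        arma::uword ib = p.tracer_idx[b];
        arma::rowvec d = x.row(ia) - x.row(ib);
        double r2 = arma::dot(d, d);
        double sig = p.sigma_tt;
        if (r2 < sig * sig && sig > 0) {
          double u = 1.0 - r2 / (sig * sig);
          en += p.eps_tt * u * u;
          arma::rowvec fv = (4.0 * p.eps_tt * u / (sig * sig)) * d;
          f.row(ia) += fv;
          f.row(ib) -= fv;
        }
      }
    }
    return en;
  }
  if (p.type == "cylinder_wall") {
    // flat-bottom: harmonic beyond radius in xy and outside [zlo, zhi]
    double en = 0.0;
    for (arma::uword q = 0; q < p.idx.n_elem; ++q) {
      arma::uword i = p.idx[q];
      double rxy = std::sqrt(x(i, 0) * x(i, 0) + x(i, 1) * x(i, 1));
      if (rxy > p.radius && rxy > 1e-12) {
        double dr = rxy - p.radius;
        en += 0.5 * p.kwall * dr * dr;
        f(i, 0) -= p.kwall * dr * x(i, 0) / rxy;
        f(i, 1) -= p.kwall * dr * x(i, 1) / rxy;
      }
      double z = x(i, 2);
      if (z > p.zhi) {
        en += 0.5 * p.kwall * (z - p.zhi) * (z - p.zhi);
        f(i, 2) -= p.kwall * (z - p.zhi);
      } else if (z < p.zlo) {
        en += 0.5 * p.kwall * (z - p.zlo) * (z - p.zlo);
        f(i, 2) -= p.kwall * (z - p.zlo);
      }
    }
    return en;
  }
  stop("unknown force term type: " + p.type);
}

double total_energy_forces(const std::vector<Term>& terms, const arma::mat& x,
                           double t_now, arma::mat& f,
                           const char** offending = nullptr) {
  f.zeros();
  double en = 0.0;
  static thread_local arma::mat ftmp;
  for (size_t k = 0; k < terms.size(); ++k) {
    double ek = term_energy_forces(terms[k], x, t_now, f);
    if (!std::isfinite(ek)) {
      if (offending) *offending = terms[k].type.c_str();
      return std::numeric_limits<double>::quiet_NaN();
    }
    en += ek;
  }
  (void)ftmp;
  return en;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_energy_forces")]]
List cpp_energy_forces(const arma::mat& coords, const List& terms,
                       double t_now = 0.0) {
  std::vector<Term> ts = parse_terms(terms);
  arma::mat f(coords.n_rows, 3, arma::fill::zeros);
  const char* bad = nullptr;
  double en = total_energy_forces(ts, coords, t_now, f, &bad);
  if (!std::isfinite(en))
    stop(std::string("non-finite energy in force term '") +
         (bad ? bad : "?") + "'");
  return List::create(_["energy"] = en, _["forces"] = f);
}

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(const arma::mat& coords0, const List& terms,
                      double temperature, double friction, double dt,
                      int n_steps, int save_stride, int seed,
                      const arma::vec& mass, double blowup_threshold = 1e10) {
  std::vector<Term> ts = parse_terms(terms);
  const arma::uword N = coords0.n_rows;
  if (mass.n_elem != N) stop("mass vector length must match site count");

  arma::mat x = coords0;
  arma::mat v(N, 3, arma::fill::zeros);
  arma::mat f(N, 3, arma::fill::zeros);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // thermalized initial velocities
  if (temperature > 0) {
    for (arma::uword i = 0; i < N; ++i) {
      double sv = std::sqrt(temperature / mass[i]);
      for (int d = 0; d < 3; ++d) v(i, d) = sv * gauss(rng);
    }
  }

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  const char* bad = nullptr;
  double en = total_energy_forces(ts, x, 0.0, f, &bad);
  if (!std::isfinite(en))
    stop(std::string("non-finite initial energy in term '") +
         (bad ? bad : "?") + "'");

  int n_save = n_steps / save_stride;
  arma::cube saved(N, 3, n_save);
  arma::vec times(n_save), epot(n_save), ekin(n_save), work(n_save);

  // locate a steered term (at most one) for work accumulation
  int steer_id = -1;
  for (size_t k = 0; k < ts.size(); ++k)
    if (ts[k].type == "steered") steer_id = static_cast<int>(k);
  double wacc = 0.0;

  int isave = 0;
  for (int step = 0; step < n_steps; ++step) {
    double t_now = step * dt;
    // B
    for (arma::uword i = 0; i < N; ++i)
      v.row(i) += (0.5 * dt / mass[i]) * f.row(i);
    // A
    x += (0.5 * dt) * v;
    // O
    if (temperature > 0) {
      for (arma::uword i = 0; i < N; ++i) {
        double sv = std::sqrt(temperature / mass[i]);
        for (int d = 0; d < 3; ++d)
          v(i, d) = c1 * v(i, d) + c2 * sv * gauss(rng);
      }
    } else {
      v *= c1;
    }
    // A
    x += (0.5 * dt) * v;
    // forces at end of step; steered center advances with time
    double t_next = (step + 1) * dt;
    en = total_energy_forces(ts, x, t_next, f, &bad);
    if (!std::isfinite(en) || std::abs(en) > blowup_threshold)
      stop("integration blow-up at step " + std::to_string(step + 1) +
           " (energy " + std::to_string(en) + ")");
    // B
    for (arma::uword i = 0; i < N; ++i)
      v.row(i) += (0.5 * dt / mass[i]) * f.row(i);

    // steered work increment: dW = k (x0 - c) * v_pull * dt
    if (steer_id >= 0) {
      const Term& p = ts[steer_id];
      double c0 = p.center0 + p.velocity * t_next;
      double cval;
      if (p.coordinate == "pair_distance") {
        arma::rowvec d =
            arma::mean(x.rows(p.g1), 0) - arma::mean(x.rows(p.g2), 0);
        cval = std::sqrt(arma::dot(d, d));
      } else {
        cval = arma::dot(arma::mean(x.rows(p.g1), 0).t(), p.axis);
      }
      wacc += p.k_pull * (c0 - cval) * p.velocity * dt;
    }

    if ((step + 1) % save_stride == 0) {
      saved.slice(isave) = x;
      times[isave] = t_next;
      epot[isave] = en;
      double ke = 0.0;
      for (arma::uword i = 0; i < N; ++i)
        ke += 0.5 * mass[i] * arma::dot(v.row(i), v.row(i));
      ekin[isave] = ke;
      work[isave] = wacc;
      ++isave;
    }
  }

  return List::create(
      _["coords"] = saved, _["times"] = times, _["potential"] = epot,
      _["kinetic"] = ekin, _["work"] = work, _["final_coords"] = x,
      _["final_velocities"] = v);
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat& x, const arma::mat& y) {
  arma::mat Q;
  arma::rowvec tv;
  double r = kabsch_rmsd(x, y, Q, tv);
  return List::create(_["rotation"] = Q, _["translation"] = tv,
                      _["rmsd"] = r);
}
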