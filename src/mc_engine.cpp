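// Rigid-molecule NPT Metropolis Monte Carlo engine for toy LJ+Coulomb
// liquids. Periodic cubic box, minimum-image atom-atom interactions
// truncated at a cutoff, analytic LJ tail correction, log-volume barostat
// moves. All molecules are copies of one rigid conformer; intramolecular
// energy is constant and handled outside the sampling loop.
//
// Units: kcal/mol, Angstrom, Kelvin, atm, elementary charge.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 1.987204259e-3;       // kcal/mol/K
static const double P_ATM = 1.458397e-5;       // kcal/mol per atm*A^3
static const double KE = 332.06371;            // Coulomb, kcal*A/mol/e^2

struct Box {
  double L;
  inline double mi(double d) const {
    if (d > 0.5 * L) return d - L;
    if (d < -0.5 * L) return d + L;
    return d;
  }
};

// pair energy between atom a of molecule m1 and atom b of molecule m2
static inline double pair_u(double dx, double dy, double dz,
                            double eps, double rmin, double q2,
                            double rc2) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= rc2) return 0.0;
  double u = 0.0;
  if (eps > 0.0) {
    double x2 = rmin * rmin / r2;
    double x6 = x2 * x2 * x2;
    u += eps * (x6 * x6 - 2.0 * x6);
  }
  if (q2 != 0.0) u += KE * q2 / std::sqrt(r2);
  return u;
}

class System {
public:
  int n_mol, n_at;                 // molecules, atoms per molecule
  std::vector<double> x, y, z;     // absolute coords, n_mol*n_at
  std::vector<double> cx, cy, cz;  // molecule centers
  std::vector<double> lx, ly, lz;  // rigid local coords (orientation per mol)
  std::vector<int> type;           // per local atom
  std::vector<double> q;           // per local atom
  NumericMatrix epsij, rminij;     // combined type tables
  double rc, rc2;
  Box box;
  double tail_coef;                // sum over atom pairs of I_ab (A^3*kcal/mol)

  System(NumericMatrix coords, IntegerVector type_, NumericVector q_,
         NumericMatrix epsij_, NumericMatrix rminij_, int n_mol_,
         double cutoff)
      : n_mol(n_mol_), n_at(coords.nrow()), epsij(epsij_), rminij(rminij_),
        rc(cutoff), rc2(cutoff * cutoff) {
    type.resize(n_at);
    q.resize(n_at);
    for (int a = 0; a < n_at; ++a) { type[a] = type_[a]; q[a] = q_[a]; }
    int N = n_mol * n_at;
    x.assign(N, 0.0); y.assign(N, 0.0); z.assign(N, 0.0);
    cx.assign(n_mol, 0.0); cy.assign(n_mol, 0.0); cz.assign(n_mol, 0.0);
    lx.assign(N, 0.0); ly.assign(N, 0.0); lz.assign(N, 0.0);
    for (int m = 0; m < n_mol; ++m)
      for (int a = 0; a < n_at; ++a) {
        lx[m * n_at + a] = coords(a, 0);
        ly[m * n_at + a] = coords(a, 1);
        lz[m * n_at + a] = coords(a, 2);
      }
    // tail coefficient: sum over all intermolecular-treatable atom pairs of
    // the cutoff integral; computed from whole-box type counts
    std::vector<double> cnt(epsij.nrow(), 0.0);
    for (int a = 0; a < n_at; ++a) cnt[type[a]] += n_mol;
    tail_coef = 0.0;
    for (int ta = 0; ta < epsij.nrow(); ++ta)
      for (int tb = 0; tb < epsij.ncol(); ++tb) {
        double eps = epsij(ta, tb), rm = rminij(ta, tb);
        if (eps <= 0.0) continue;
        double rm3 = rm * rm * rm, rm6 = rm3 * rm3, rm12 = rm6 * rm6;
        double rc3 = rc * rc * rc, rc9 = rc3 * rc3 * rc3;
        double I = eps * (rm12 / (9.0 * rc9) - 2.0 * rm6 / (3.0 * rc3));
        tail_coef += cnt[ta] * cnt[tb] * I;
      }
  }

  double tail(double V) const { return 2.0 * M_PI * tail_coef / V; }

  void rebuild_atoms(int m) {
    for (int a = 0; a < n_at; ++a) {
      int i = m * n_at + a;
      x[i] = cx[m] + lx[i];
      y[i] = cy[m] + ly[i];
      z[i] = cz[m] + lz[i];
    }
  }

  // interaction of molecule m with all other molecules
  double mol_energy(int m) const {
    double u = 0.0;
    for (int m2 = 0; m2 < n_mol; ++m2) {
      if (m2 == m) continue;
      for (int a = 0; a < n_at; ++a) {
        int i = m * n_at + a;
        int ta = type[a];
        double qa = q[a];
        for (int b = 0; b < n_at; ++b) {
          int j = m2 * n_at + b;
          double dx = box.mi(x[i] - x[j]);
          double dy = box.mi(y[i] - y[j]);
          double dz = box.mi(z[i] - z[j]);
          u += pair_u(dx, dy, dz, epsij(ta, type[b]), rminij(ta, type[b]),
                      qa * q[b], rc2);
        }
      }
    }
    return u;
  }

  double total_energy() const {
    double u = 0.0;
    for (int m = 0; m < n_mol; ++m)
      for (int m2 = m + 1; m2 < n_mol; ++m2)
        for (int a = 0; a < n_at; ++a) {
          int i = m * n_at + a;
          int ta = type[a];
          double qa = q[a];
          for (int b = 0; b < n_at; ++b) {
            int j = m2 * n_at + b;
            double dx = box.mi(x[i] - x[j]);
            double dy = box.mi(y[i] - y[j]);
            double dz = box.mi(z[i] - z[j]);
            u += pair_u(dx, dy, dz, epsij(ta, type[b]), rminij(ta, type[b]),
                        qa * q[b], rc2);
          }
        }
    return u;
  }

  void wrap(int m) {
    double L = box.L;
    cx[m] -= L * std::floor(cx[m] / L);
    cy[m] -= L * std::floor(cy[m] / L);
    cz[m] -= L * std::floor(cz[m] / L);
    rebuild_atoms(m);
  }

  void rotate_local(int m, double ax, double ay, double az, double angle) {
    // Rodrigues rotation of the molecule's local frame
    double c = std::cos(angle), s = std::sin(angle), C = 1.0 - c;
    for (int a = 0; a < n_at; ++a) {
      int i = m * n_at + a;
      double vx = lx[i], vy = ly[i], vz = lz[i];
      double dot = ax * vx + ay * vy + az * vz;
      double nx = vx * c + (ay * vz - az * vy) * s + ax * dot * C;
      double ny = vy * c + (az * vx - ax * vz) * s + ay * dot * C;
      double nz = vz * c + (ax * vy - ay * vx) * s + az * dot * C;
      lx[i] = nx; ly[i] = ny; lz[i] = nz;
    }
    rebuild_atoms(m);
  }
};

// [[Rcpp::export(name = ".run_toy_mc_cpp")]]
List run_toy_mc_cpp(NumericMatrix coords, IntegerVector type0,
                    NumericVector charges, NumericMatrix epsij,
                    NumericMatrix rminij, int n_mol, double temperature,
                    double pressure_atm, double cutoff, double init_volume,
                    int n_equil_moves, int n_prod_moves, int vol_interval,
                    int sample_interval, double max_trans, double max_rot,
                    double max_lnv) {
  System sys(coords, type0, charges, epsij, rminij, n_mol, cutoff);
  double beta = 1.0 / (KB * temperature);
  double Pconv = pressure_atm * P_ATM;   // kcal/mol per A^3

  double V = init_volume;
  sys.box.L = std::cbrt(V);
  if (cutoff >= 0.5 * sys.box.L)
    stop("cutoff exceeds half the initial box edge");

  // lattice start
  int n_side = (int)std::ceil(std::cbrt((double)n_mol));
  double a0 = sys.box.L / n_side;
  int m = 0;
  for (int i = 0; i < n_side && m < n_mol; ++i)
    for (int j = 0; j < n_side && m < n_mol; ++j)
      for (int k = 0; k < n_side && m < n_mol; ++k) {
        sys.cx[m] = (i + 0.5) * a0;
        sys.cy[m] = (j + 0.5) * a0;
        sys.cz[m] = (k + 0.5) * a0;
        // random initial orientation
        double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
        double axz = 1.0 - 2.0 * u1;
        double r = std::sqrt(std::max(0.0, 1.0 - axz * axz));
        double phi = 2.0 * M_PI * u2;
        sys.rotate_local(m, r * std::cos(phi), r * std::sin(phi), axz,
                         2.0 * M_PI * u3);
        sys.rebuild_atoms(m);
        ++m;
      }
  for (int mm = 0; mm < n_mol; ++mm) sys.rebuild_atoms(mm);

  double U = sys.total_energy();           // incremental intermolecular energy
  long acc_part = 0, try_part = 0, acc_vol = 0, try_vol = 0;

  std::vector<double> s_V, s_U, s_Mx, s_My, s_Mz;
  int total_moves = n_equil_moves + n_prod_moves;
  int moves_per_sweep = n_mol;
  int sweep = 0;

  for (int step = 0; step < total_moves; ++step) {
    bool is_sweep_end = ((step + 1) % moves_per_sweep) == 0;
    // particle move
    int mm = (int)std::floor(unif_rand() * n_mol);
    if (mm >= n_mol) mm = n_mol - 1;
    double u_old = sys.mol_energy(mm);
    double ocx = sys.cx[mm], ocy = sys.cy[mm], ocz = sys.cz[mm];
    std::vector<double> olx(sys.n_at), oly(sys.n_at), olz(sys.n_at);
    for (int a = 0; a < sys.n_at; ++a) {
      int i = mm * sys.n_at + a;
      olx[a] = sys.lx[i]; oly[a] = sys.ly[i]; olz[a] = sys.lz[i];
    }
    sys.cx[mm] += max_trans * (2.0 * unif_rand() - 1.0);
    sys.cy[mm] += max_trans * (2.0 * unif_rand() - 1.0);
    sys.cz[mm] += max_trans * (2.0 * unif_rand() - 1.0);
    if (sys.n_at > 1) {
      double u1 = unif_rand(), u2 = unif_rand();
      double axz = 1.0 - 2.0 * u1;
      double r = std::sqrt(std::max(0.0, 1.0 - axz * axz));
      double phi = 2.0 * M_PI * u2;
      sys.rotate_local(mm, r * std::cos(phi), r * std::sin(phi), axz,
                       max_rot * (2.0 * unif_rand() - 1.0));
    }
    sys.wrap(mm);
    double u_new = sys.mol_energy(mm);
    double dU = u_new - u_old;
    ++try_part;
    if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) {
      U += dU;
      ++acc_part;
    } else {
      sys.cx[mm] = ocx; sys.cy[mm] = ocy; sys.cz[mm] = ocz;
      for (int a = 0; a < sys.n_at; ++a) {
        int i = mm * sys.n_at + a;
        sys.lx[i] = olx[a]; sys.ly[i] = oly[a]; sys.lz[i] = olz[a];
      }
      sys.rebuild_atoms(mm);
    }

    if (is_sweep_end) {
      ++sweep;
      // volume move every vol_interval sweeps
      if (vol_interval > 0 && (sweep % vol_interval) == 0) {
        ++try_vol;
        double V_old = V, L_old = sys.box.L, U_old2 = U;
        std::vector<double> ocx2 = sys.cx, ocy2 = sys.cy, ocz2 = sys.cz;
        double lnv = std::log(V) + max_lnv * (2.0 * unif_rand() - 1.0);
        double V_new = std::exp(lnv);
        double L_new = std::cbrt(V_new);
        if (cutoff < 0.5 * L_new) {
          double scale = L_new / L_old;
          sys.box.L = L_new;
          for (int k2 = 0; k2 < n_mol; ++k2) {
            sys.cx[k2] *= scale; sys.cy[k2] *= scale; sys.cz[k2] *= scale;
            sys.rebuild_atoms(k2);
          }
          double U_new2 = sys.total_energy();
          double dW = (U_new2 + sys.tail(V_new)) - (U_old2 + sys.tail(V_old))
            + Pconv * (V_new - V_old)
            - (n_mol + 1) * KB * temperature * std::log(V_new / V_old);
          if (dW <= 0.0 || unif_rand() < std::exp(-beta * dW)) {
            V = V_new;
            U = U_new2;
            ++acc_vol;
          } else {
            sys.box.L = L_old;
            sys.cx = ocx2; sys.cy = ocy2; sys.cz = ocz2;
            for (int k2 = 0; k2 < n_mol; ++k2) sys.rebuild_atoms(k2);
          }
        }
      }
      // sampling (production only)
      if (step >= n_equil_moves && (sweep % sample_interval) == 0) {
        s_V.push_back(V);
        s_U.push_back(U + sys.tail(V));
        double Mx = 0, My = 0, Mz = 0;
        for (int k2 = 0; k2 < n_mol; ++k2)
          for (int a = 0; a < sys.n_at; ++a) {
            int i = k2 * sys.n_at + a;
            Mx += sys.q[a] * sys.x[i];
            My += sys.q[a] * sys.y[i];
            Mz += sys.q[a] * sys.z[i];
          }
        s_Mx.push_back(Mx); s_My.push_back(My); s_Mz.push_back(Mz);
      }
    }
  }

  double U_recomputed = sys.total_energy();

  return List::create(
    _["volume"] = NumericVector(s_V.begin(), s_V.end()),
    _["energy"] = NumericVector(s_U.begin(), s_U.end()),
    _["dipole_x"] = NumericVector(s_Mx.begin(), s_Mx.end()),
    _["dipole_y"] = NumericVector(s_My.begin(), s_My.end()),
    _["dipole_z"] = NumericVector(s_Mz.begin(), s_Mz.end()),
    _["U_incremental"] = U,
    _["U_recomputed"] = U_recomputed,
    _["final_volume"] = V,
    _["acc_particle"] = (double)acc_part / std::max(1L, try_part),
    _["acc_volume"] = (double)acc_vol / std::max(1L, try_vol));
}
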