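// Coarse-grained energy model and replica-exchange Metropolis Monte Carlo.
//
// Beads are C-alpha-placed residue beads. Rigid bodies move as units
// (translation / rotation about the body centroid); linker beads move by
// local displacement or by pivoting the free tail of their chain. All
// energies in kcal/mol, lengths in Angstrom, temperatures in Kelvin.
//
// R's RNG is used throughout (RNGScope via Rcpp attributes), so runs are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

struct Topo {
  int n;
  std::vector<int> body_id;   // 0 = linker/free bead
  std::vector<double> charge;
  std::vector<int> rtype;     // 1..20
  IntegerMatrix bonds;        // m x 2 (1-based)
  IntegerMatrix angles;       // m x 3
  IntegerMatrix torsions;     // m x 4
  std::vector<std::vector<int>> bodies;   // 0-based bead indices per body
  std::vector<std::vector<int>> linkers;  // 0-based bead indices per linker
  std::vector<int> anchor_start, anchor_end; // 0-based, -1 = free
  NumericMatrix restraints;   // k x 3: bead (1-based), z_target, spring k
  std::unordered_set<long long> excl;     // bonded 1-2 pairs
};

struct Model {
  double bond_k, bond_b0, angle_k, angle_theta0, torsion_k;
  NumericMatrix eps;          // 20 x 20 contact well depths (>= 0)
  double contact_range, ev_radius, rep_k, rep_cap;
  double coulomb_k, debye_len, dielectric;
  double z_m, mem_range, wall_k;
  std::vector<double> mem_eps; // per residue type well depth (>= 0)
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Topo parse_topo(const List& t) {
  Topo topo;
  topo.n = as<int>(t["n"]);
  topo.body_id = as<std::vector<int>>(t["body_id"]);
  topo.charge = as<std::vector<double>>(t["charge"]);
  topo.rtype = as<std::vector<int>>(t["rtype"]);
  topo.bonds = as<IntegerMatrix>(t["bonds"]);
  topo.angles = as<IntegerMatrix>(t["angles"]);
  topo.torsions = as<IntegerMatrix>(t["torsions"]);
  List bl = t["bodies"];
  for (int b = 0; b < bl.size(); ++b) {
    std::vector<int> v = as<std::vector<int>>(bl[b]);
    for (auto& x : v) x -= 1;
    topo.bodies.push_back(v);
  }
  List ll = t["linkers"];
  for (int l = 0; l < ll.size(); ++l) {
    std::vector<int> v = as<std::vector<int>>(ll[l]);
    for (auto& x : v) x -= 1;
    topo.linkers.push_back(v);
  }
  std::vector<int> as_ = as<std::vector<int>>(t["anchor_start"]);
  std::vector<int> ae_ = as<std::vector<int>>(t["anchor_end"]);
  for (size_t i = 0; i < as_.size(); ++i) {
    topo.anchor_start.push_back(as_[i] - 1); // 0 -> -1 (free)
    topo.anchor_end.push_back(ae_[i] - 1);
  }
  topo.restraints = as<NumericMatrix>(t["restraints"]);
  for (int b = 0; b < topo.bonds.nrow(); ++b)
    topo.excl.insert(pkey(topo.bonds(b, 0) - 1, topo.bonds(b, 1) - 1, topo.n));
  return topo;
}

static Model parse_model(const List& m) {
  Model mod;
  mod.bond_k = as<double>(m["bond_k"]);
  mod.bond_b0 = as<double>(m["bond_length"]);
  mod.angle_k = as<double>(m["angle_k"]);
  mod.angle_theta0 = as<double>(m["angle_0"]);
  mod.torsion_k = as<double>(m["torsion_k"]);
  mod.eps = as<NumericMatrix>(m["contact_eps"]);
  mod.contact_range = as<double>(m["contact_range"]);
  mod.ev_radius = as<double>(m["ev_radius"]);
  mod.rep_k = as<double>(m["rep_k"]);
  mod.rep_cap = as<double>(m["rep_cap"]);
  mod.coulomb_k = as<double>(m["coulomb_k"]);
  mod.debye_len = as<double>(m["debye_length"]);
  mod.dielectric = as<double>(m["dielectric"]);
  mod.z_m = as<double>(m["z_membrane"]);
  mod.mem_range = as<double>(m["mem_range"]);
  mod.wall_k = as<double>(m["wall_k"]);
  mod.mem_eps = as<std::vector<double>>(m["mem_eps"]);
  return mod;
}

typedef std::vector<double> Coords; // 3n flat, xyz per bead

static inline double dist3(const Coords& x, int i, int j) {
  double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
         dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// ---- energy terms -----------------------------------------------------------

static double pair_contact(double r, int ti, int tj, const Model& m) {
  if (r >= m.contact_range) return 0.0;
  double e = -m.eps(ti - 1, tj - 1);
  if (r < m.ev_radius) {
    double reff = std::max(r, 0.1);
    double s = m.ev_radius / reff;
    double s2 = s * s;
    double rep = m.rep_k * (s2 * s2 * s2 - 1.0); // (ev/r)^6 - 1, finite
    e += std::min(rep, m.rep_cap);
  }
  return e;
}

static double pair_elec(double r, double qi, double qj, const Model& m) {
  if (qi == 0.0 || qj == 0.0) return 0.0;
  double reff = std::max(r, 0.1);
  return m.coulomb_k * qi * qj * std::exp(-reff / m.debye_len) /
         (m.dielectric * reff);
}

static inline bool nb_excluded(const Topo& t, int i, int j) {
  if (t.body_id[i] > 0 && t.body_id[i] == t.body_id[j]) return true;
  return t.excl.count(pkey(i, j, t.n)) > 0;
}

static double angle_at(const Coords& x, int a, int b, int c) {
  double v1[3], v2[3];
  for (int k = 0; k < 3; ++k) {
    v1[k] = x[3 * a + k] - x[3 * b + k];
    v2[k] = x[3 * c + k] - x[3 * b + k];
  }
  double n1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
  double n2 = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
  double cs = (v1[0] * v2[0] + v1[1] * v2[1] + v1[2] * v2[2]) / (n1 * n2);
  cs = std::max(-1.0, std::min(1.0, cs));
  return std::acos(cs);
}

static double dihedral_at(const Coords& x, int a, int b, int c, int d) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = x[3 * b + k] - x[3 * a + k];
    b2[k] = x[3 * c + k] - x[3 * b + k];
    b3[k] = x[3 * d + k] - x[3 * c + k];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  // collinear segments leave the dihedral undefined; take the trans
  // (zero-torsion-energy) convention so the extended chain is relaxed
  double s1 = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
  double s2 = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
  double sb1 = b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2];
  double sb2 = b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2];
  double sb3 = b3[0] * b3[0] + b3[1] * b3[1] + b3[2] * b3[2];
  if (s1 < 1e-12 * sb1 * sb2 || s2 < 1e-12 * sb2 * sb3) return M_PI;
  double m1[3];
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  for (int k = 0; k < 3; ++k) m1[k] = b2[k] / nb2;
  double mcr[3] = {n1[1] * m1[2] - n1[2] * m1[1], n1[2] * m1[0] - n1[0] * m1[2],
                   n1[0] * m1[1] - n1[1] * m1[0]};
  double xx = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double yy = mcr[0] * n2[0] + mcr[1] * n2[1] + mcr[2] * n2[2];
  return std::atan2(yy, xx);
}

struct EnergyParts {
  double bonded = 0, contact = 0, elec = 0, restraint = 0, surface = 0;
  double total() const { return bonded + contact + elec + restraint + surface; }
};

// mask == NULL: full energy. Otherwise only terms touching a moved bead
// (pair terms with >=1 moved member; all differences of unmoved-unmoved
// terms cancel in Metropolis deltas).
static EnergyParts energy_parts(const Coords& x, const Topo& t, const Model& m,
                                bool membrane, const std::vector<char>* mask) {
  EnergyParts e;
  // bonded
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = t.bonds(b, 0) - 1, j = t.bonds(b, 1) - 1;
    if (mask && !((*mask)[i] || (*mask)[j])) continue;
    double d = dist3(x, i, j) - m.bond_b0;
    e.bonded += 0.5 * m.bond_k * d * d;
  }
  for (int b = 0; b < t.angles.nrow(); ++b) {
    int i = t.angles(b, 0) - 1, j = t.angles(b, 1) - 1, k = t.angles(b, 2) - 1;
    if (mask && !((*mask)[i] || (*mask)[j] || (*mask)[k])) continue;
    double d = angle_at(x, i, j, k) - m.angle_theta0;
    e.bonded += 0.5 * m.angle_k * d * d;
  }
  if (m.torsion_k != 0.0) {
    for (int b = 0; b < t.torsions.nrow(); ++b) {
      int i = t.torsions(b, 0) - 1, j = t.torsions(b, 1) - 1,
          k = t.torsions(b, 2) - 1, l = t.torsions(b, 3) - 1;
      if (mask && !((*mask)[i] || (*mask)[j] || (*mask)[k] || (*mask)[l]))
        continue;
      e.bonded += m.torsion_k * (1.0 + std::cos(dihedral_at(x, i, j, k, l)));
    }
  }
  // nonbonded
  for (int i = 0; i < t.n; ++i) {
    for (int j = i + 1; j < t.n; ++j) {
      if (mask && !((*mask)[i] || (*mask)[j])) continue;
      if (nb_excluded(t, i, j)) continue;
      double r = dist3(x, i, j);
      if (r < m.contact_range) e.contact += pair_contact(r, t.rtype[i], t.rtype[j], m);
      e.elec += pair_elec(r, t.charge[i], t.charge[j], m);
    }
  }
  // membrane
  if (membrane) {
    for (int b = 0; b < t.restraints.nrow(); ++b) {
      int i = (int)t.restraints(b, 0) - 1;
      if (mask && !(*mask)[i]) continue;
      double dz = x[3 * i + 2] - t.restraints(b, 1);
      e.restraint += 0.5 * t.restraints(b, 2) * dz * dz;
    }
    for (int i = 0; i < t.n; ++i) {
      if (mask && !(*mask)[i]) continue;
      double z = x[3 * i + 2];
      if (z < m.z_m) {
        double d = m.z_m - z;
        e.surface += m.wall_k * d * d - m.mem_eps[t.rtype[i] - 1];
      } else {
        double dz = z - m.z_m;
        if (dz < 5.0 * m.mem_range) {
          double u = dz / m.mem_range;
          e.surface += -m.mem_eps[t.rtype[i] - 1] * std::exp(-u * u);
        }
      }
    }
  }
  return e;
}

static Coords mat_to_coords(const NumericMatrix& xm) {
  int n = xm.nrow();
  Coords x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = xm(i, k);
  return x;
}

static NumericMatrix coords_to_mat(const Coords& x) {
  int n = x.size() / 3;
  NumericMatrix xm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) xm(i, k) = x[3 * i + k];
  return xm;
}

// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix coords, List topo, List model,
                      bool membrane) {
  Topo t = parse_topo(topo);
  Model m = parse_model(model);
  if (coords.nrow() != t.n) stop("coordinate count does not match topology");
  Coords x = mat_to_coords(coords);
  EnergyParts e = energy_parts(x, t, m, membrane, nullptr);
  return List::create(
      _["bonded"] = e.bonded, _["contact"] = e.contact,
      _["electrostatic"] = e.elec, _["membrane_restraint"] = e.restraint,
      _["membrane_surface"] = e.surface, _["total"] = e.total());
}

// ---- moves ------------------------------------------------------------------

static void rand_axis(double* ax) {
  double n2;
  do {
    ax[0] = norm_rand(); ax[1] = norm_rand(); ax[2] = norm_rand();
    n2 = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  ax[0] /= n; ax[1] /= n; ax[2] /= n;
}

// Rodrigues rotation of bead set about `center` by `angle` around unit `ax`
static void rotate_beads(Coords& x, const std::vector<int>& beads,
                         const double* center, const double* ax, double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  for (int i : beads) {
    double v[3] = {x[3 * i] - center[0], x[3 * i + 1] - center[1],
                   x[3 * i + 2] - center[2]};
    double cr[3] = {ax[1] * v[2] - ax[2] * v[1], ax[2] * v[0] - ax[0] * v[2],
                    ax[0] * v[1] - ax[1] * v[0]};
    double dot = ax[0] * v[0] + ax[1] * v[1] + ax[2] * v[2];
    for (int k = 0; k < 3; ++k)
      x[3 * i + k] = center[k] + v[k] * c + cr[k] * s + ax[k] * dot * (1 - c);
  }
}

struct MCState {
  Coords x;
  double energy;
};

struct MoveStats {
  long attempted = 0, accepted = 0;
};

// One sweep: one attempted move per mobile degree of freedom.
static void mc_sweep_inner(MCState& st, const Topo& t, const Model& m,
                           bool membrane, double temperature, double amp_t,
                           double amp_r, double amp_p, MoveStats& stats) {
  double kT = KB * temperature;
  std::vector<char> mask(t.n, 0);
  Coords saved;
  std::vector<int> moved;

  auto attempt = [&](const std::vector<int>& beads,
                     const std::function<void()>& apply) {
    for (int i : beads) mask[i] = 1;
    EnergyParts before = energy_parts(st.x, t, m, membrane, &mask);
    saved.clear();
    for (int i : beads)
      for (int k = 0; k < 3; ++k) saved.push_back(st.x[3 * i + k]);
    apply();
    EnergyParts after = energy_parts(st.x, t, m, membrane, &mask);
    double dE = after.total() - before.total();
    stats.attempted++;
    bool acc = (dE <= 0.0) || (unif_rand() < std::exp(-dE / kT));
    if (acc) {
      st.energy += dE;
      stats.accepted++;
    } else {
      size_t p = 0;
      for (int i : beads)
        for (int k = 0; k < 3; ++k) st.x[3 * i + k] = saved[p++];
    }
    for (int i : beads) mask[i] = 0;
  };

  // rigid-body moves
  for (const auto& body : t.bodies) {
    bool translate = unif_rand() < 0.5;
    if (translate) {
      double d[3] = {amp_t * (2 * unif_rand() - 1), amp_t * (2 * unif_rand() - 1),
                     amp_t * (2 * unif_rand() - 1)};
      attempt(body, [&]() {
        for (int i : body)
          for (int k = 0; k < 3; ++k) st.x[3 * i + k] += d[k];
      });
    } else {
      double ax[3];
      rand_axis(ax);
      double ang = amp_r * (2 * unif_rand() - 1);
      double c[3] = {0, 0, 0};
      for (int i : body)
        for (int k = 0; k < 3; ++k) c[k] += st.x[3 * i + k];
      for (int k = 0; k < 3; ++k) c[k] /= body.size();
      attempt(body, [&]() { rotate_beads(st.x, body, c, ax, ang); });
    }
  }

  // linker-bead moves
  for (size_t l = 0; l < t.linkers.size(); ++l) {
    const auto& chain = t.linkers[l];
    bool start_free = t.anchor_start[l] < 0, end_free = t.anchor_end[l] < 0;
    for (size_t p = 0; p < chain.size(); ++p) {
      // pivot requires a free tail on one side of the bead
      bool can_end = end_free && p + 1 < chain.size();
      bool can_start = start_free && p > 0;
      bool pivot = (can_end || can_start) && unif_rand() < 0.5;
      if (!pivot) {
        int i = chain[p];
        double d[3] = {amp_t * (2 * unif_rand() - 1),
                       amp_t * (2 * unif_rand() - 1),
                       amp_t * (2 * unif_rand() - 1)};
        std::vector<int> one = {i};
        attempt(one, [&]() {
          for (int k = 0; k < 3; ++k) st.x[3 * i + k] += d[k];
        });
      } else {
        bool toward_end = can_end && (!can_start || unif_rand() < 0.5);
        std::vector<int> tail;
        if (toward_end)
          for (size_t q = p + 1; q < chain.size(); ++q) tail.push_back(chain[q]);
        else
          for (size_t q = 0; q < p; ++q) tail.push_back(chain[q]);
        double ax[3];
        rand_axis(ax);
        double ang = amp_p * (2 * unif_rand() - 1);
        double c[3] = {st.x[3 * chain[p]], st.x[3 * chain[p] + 1],
                       st.x[3 * chain[p] + 2]};
        attempt(tail, [&]() { rotate_beads(st.x, tail, c, ax, ang); });
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix init, List topo, List model, bool membrane,
                double temperature, int n_sweeps, int save_interval,
                double amp_t, double amp_r, double amp_p) {
  Topo t = parse_topo(topo);
  Model m = parse_model(model);
  MCState st{mat_to_coords(init), 0.0};
  st.energy = energy_parts(st.x, t, m, membrane, nullptr).total();
  MoveStats stats;
  int n_save = (save_interval > 0) ? n_sweeps / save_interval : 0;
  List frames(n_save);
  NumericVector energies(n_save), sweeps(n_save);
  int isave = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    mc_sweep_inner(st, t, m, membrane, temperature, amp_t, amp_r, amp_p, stats);
    if (save_interval > 0 && s % save_interval == 0) {
      st.energy = energy_parts(st.x, t, m, membrane, nullptr).total();
      if (!std::isfinite(st.energy))
        stop("non-finite energy at sweep %d", s);
      frames[isave] = coords_to_mat(st.x);
      energies[isave] = st.energy;
      sweeps[isave] = s;
      ++isave;
    }
    if (s % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["frames"] = frames, _["energy"] = energies,
                      _["sweep"] = sweeps, _["final"] = coords_to_mat(st.x),
                      _["final_energy"] = st.energy,
                      _["attempted"] = (double)stats.attempted,
                      _["accepted"] = (double)stats.accepted);
}

// Replica exchange: ladder slot r runs at temps[r]; swaps exchange
// configurations between adjacent slots. Saved frames come from all slots or
// from slot 0 (lowest temperature) only.
// [[Rcpp::export]]
List cpp_run_remc(List init_list, List topo, List model, bool membrane,
                  NumericVector temps, int n_sweeps, int save_interval,
                  int swap_period, double amp_t, double amp_r, double amp_p,
                  bool save_all) {
  Topo t = parse_topo(topo);
  Model m = parse_model(model);
  int R = temps.size();
  if (init_list.size() != R) stop("need one initial conformation per replica");
  std::vector<MCState> reps(R);
  std::vector<MoveStats> stats(R);
  for (int r = 0; r < R; ++r) {
    reps[r].x = mat_to_coords(as<NumericMatrix>(init_list[r]));
    reps[r].energy = energy_parts(reps[r].x, t, m, membrane, nullptr).total();
    if (!std::isfinite(reps[r].energy))
      stop("non-finite initial energy in replica %d", r + 1);
  }
  long swap_att = 0, swap_acc = 0;
  int saves_per_event = save_all ? R : 1;
  int n_events = (save_interval > 0) ? n_sweeps / save_interval : 0;
  List frames(n_events * saves_per_event);
  NumericVector energies(n_events * saves_per_event),
      sweeps(n_events * saves_per_event);
  IntegerVector slot(n_events * saves_per_event);
  int isave = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    for (int r = 0; r < R; ++r)
      mc_sweep_inner(reps[r], t, m, membrane, temps[r], amp_t, amp_r, amp_p,
                     stats[r]);
    if (R > 1 && swap_period > 0 && s % swap_period == 0) {
      for (int k = 0; k < R - 1; ++k) {
        int i = (int)std::floor(unif_rand() * (R - 1));
        if (i >= R - 1) i = R - 2;
        int j = i + 1;
        double bi = 1.0 / (KB * temps[i]), bj = 1.0 / (KB * temps[j]);
        double larg = (bi - bj) * (reps[i].energy - reps[j].energy);
        swap_att++;
        if (larg >= 0.0 || unif_rand() < std::exp(larg)) {
          std::swap(reps[i].x, reps[j].x);
          std::swap(reps[i].energy, reps[j].energy);
          swap_acc++;
        }
      }
    }
    if (save_interval > 0 && s % save_interval == 0) {
      for (int r = 0; r < R; ++r) {
        reps[r].energy = energy_parts(reps[r].x, t, m, membrane, nullptr).total();
        if (!std::isfinite(reps[r].energy))
          stop("non-finite energy in replica %d at sweep %d", r + 1, s);
      }
      if (save_all) {
        for (int r = 0; r < R; ++r) {
          frames[isave] = coords_to_mat(reps[r].x);
          energies[isave] = reps[r].energy;
          sweeps[isave] = s;
          slot[isave] = r + 1;
          ++isave;
        }
      } else {
        frames[isave] = coords_to_mat(reps[0].x);
        energies[isave] = reps[0].energy;
        sweeps[isave] = s;
        slot[isave] = 1;
        ++isave;
      }
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector att(R), acc(R);
  for (int r = 0; r < R; ++r) {
    att[r] = (double)stats[r].attempted;
    acc[r] = (double)stats[r].accepted;
  }
  return List::create(
      _["frames"] = frames, _["energy"] = energies, _["sweep"] = sweeps,
      _["slot"] = slot, _["move_attempted"] = att, _["move_accepted"] = acc,
      _["swap_attempted"] = (double)swap_att,
      _["swap_accepted"] = (double)swap_acc);
}
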