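// Discrete-step scheduler for the replicase-parasite multi-agent world.
//
// One step, in order: (i) advance time; (ii) decrement free-molecule
// lifetimes, complex dissociation clocks and (in "ticking" decay mode) the
// lifetimes of complexed members; (iii) remove expired free molecules and
// resolve in-complex decay; (iv) shuffle a snapshot of all entities and
// rebuild the neighborhood grid; (v) process each snapshot entity: clock
// dissociation, neighbor census, crowding removal, Brownian move, replication
// (complex) or complex formation (free molecule); (vi) entities created during
// the step occupy space immediately but act only from the next step.
//
// RNG consumption order (one private stream per engine): entity shuffle;
// then per free molecule: neighbor-set shuffle, one Box-Muller pair for the
// move, one uniform per reaction test, and on success Exp(K) then Exp(1-a);
// per complex: one Box-Muller pair, and on replication the offspring mutation
// draws (decision then offset, a before l), Exp(d) lifetime, placement angle.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;
using rpsim::Rng;

namespace {

const int SP_R = 0; // replicase
const int SP_P = 1; // parasite

struct Mol {
  double x, y, a, l, rlt;
  int id;
  signed char species; // SP_R / SP_P
  signed char state;   // 0 free, 1 complexed, 2 dead
};

struct Cx {
  double x, y, ttr, diss_rlt;
  int cat, tmpl;               // indices into mols
  double cat_rlt0, tmpl_rlt0;  // member lifetimes stored at formation
  bool alive;
};

struct Events {
  long decays_free = 0, decays_in_complex = 0, dissociations = 0,
       replications = 0, complex_formations = 0, overcrowd_removals = 0;
  void reset() { *this = Events(); }
};

// Uniform-grid cell list over the torus; cell edge >= collision distance so a
// 3x3 cell neighborhood always covers a radius-r_c disc. Cells carry the
// entity coordinates inline so a census never chases pointers for misses.
struct GEnt {
  double x, y;
  int h; // handle: m >= 0 molecule, -c-1 complex
};

struct Grid {
  int gx = 1, gy = 1;
  double csx = 1, csy = 1;
  std::vector<std::vector<GEnt>> cells;

  void configure(double W, double H, double rc) {
    gx = std::max(1, (int)std::floor(W / rc));
    gy = std::max(1, (int)std::floor(H / rc));
    csx = W / gx;
    csy = H / gy;
    cells.assign((size_t)gx * gy, {});
  }
  int cell_of(double x, double y) const {
    int ix = (int)(x / csx); if (ix >= gx) ix = gx - 1;
    int iy = (int)(y / csy); if (iy >= gy) iy = gy - 1;
    return iy * gx + ix;
  }
  void clear() {
    for (auto &c : cells) c.clear();
  }
  void insert(int h, double x, double y) {
    cells[cell_of(x, y)].push_back(GEnt{x, y, h});
  }
  void remove(int h, double x, double y) {
    auto &c = cells[cell_of(x, y)];
    for (size_t i = 0; i < c.size(); ++i)
      if (c[i].h == h) { c[i] = c.back(); c.pop_back(); return; }
    Rcpp::stop("internal: grid entry not found");
  }
};

struct Engine {
  // geometry
  double W, H;
  // kinetics
  double d, D, Dc, K, dt, radius, rc;
  int nmax;
  // mutation (effective per-species, per-attribute probabilities)
  double mu_aR, mu_lR, mu_aP, mu_lP, delta;
  int decay_mode; // 0 ticking, 1 frozen
  double offspring_offset;

  Rng rng;
  std::vector<Mol> mols;
  std::vector<Cx> cxs;
  double time = 0.0;
  long step_no = 0;
  int next_id = 1;
  Grid grid;

  // per-step records
  std::vector<double> sr[16]; // series columns
  std::vector<long> ev_rows[7];
  Events ev;
  bool extinct_R = false, extinct_P = false;

  std::vector<int> nbuf, rbuf, order;

  double wrapx(double x) const {
    double w = x - W * std::floor(x / W);
    if (w >= W) w -= W; if (w < 0) w = 0;
    return w;
  }
  double wrapy(double y) const {
    double w = y - H * std::floor(y / H);
    if (w >= H) w -= H; if (w < 0) w = 0;
    return w;
  }
  double dist2(double x1, double y1, double x2, double y2) const {
    double dx = std::fabs(x1 - x2); if (dx > 0.5 * W) dx = W - dx;
    double dy = std::fabs(y1 - y2); if (dy > 0.5 * H) dy = H - dy;
    return dx * dx + dy * dy;
  }

  void entity_xy(int h, double &x, double &y) const {
    if (h >= 0) { x = mols[h].x; y = mols[h].y; }
    else        { const Cx &c = cxs[-h - 1]; x = c.x; y = c.y; }
  }

  // all entities with center-to-center torus distance strictly below rc,
  // excluding the query handle; with out == nullptr only the count is taken
  int census(int h, double x, double y, std::vector<int> *out) const {
    if (out) out->clear();
    int n = 0;
    double r2 = rc * rc;
    int c0 = grid.cell_of(x, y);
    int ix0 = c0 % grid.gx;
    int iy0 = c0 / grid.gx;
    int seenx[3], seeny[3], nx = 0, ny = 0;
    for (int o = -1; o <= 1; ++o) {
      int ix = (ix0 + o + grid.gx) % grid.gx;
      bool dup = false;
      for (int k = 0; k < nx; ++k) if (seenx[k] == ix) dup = true;
      if (!dup) seenx[nx++] = ix;
      int iy = (iy0 + o + grid.gy) % grid.gy;
      dup = false;
      for (int k = 0; k < ny; ++k) if (seeny[k] == iy) dup = true;
      if (!dup) seeny[ny++] = iy;
    }
    for (int a = 0; a < ny; ++a)
      for (int b = 0; b < nx; ++b) {
        const auto &cell = grid.cells[(size_t)seeny[a] * grid.gx + seenx[b]];
        for (const GEnt &e : cell) {
          if (e.h == h) continue;
          if (dist2(x, y, e.x, e.y) < r2) {
            ++n;
            if (out) out->push_back(e.h);
          }
        }
      }
    return n;
  }

  void shuffle(std::vector<int> &v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = (int)rng.bounded((std::uint32_t)(i + 1));
      std::swap(v[i], v[j]);
    }
  }

  long live_molecules() const {
    long n = 0;
    for (const Mol &m : mols) if (m.state != 2) ++n;
    return n;
  }

  void counts(long &nRf, long &nPf, long &nRR, long &nRP) const {
    nRf = nPf = nRR = nRP = 0;
    for (const Mol &m : mols)
      if (m.state == 0) (m.species == SP_R ? nRf : nPf)++;
    for (const Cx &c : cxs)
      if (c.alive) (mols[c.tmpl].species == SP_R ? nRR : nRP)++;
  }

  void record_row() {
    long nRf, nPf, nRR, nRP;
    counts(nRf, nPf, nRR, nRP);
    double sa[2] = {0, 0}, sl[2] = {0, 0}, sa2[2] = {0, 0}, sl2[2] = {0, 0};
    long n[2] = {0, 0};
    for (const Mol &m : mols) {
      if (m.state == 2) continue;
      int s = m.species;
      n[s]++; sa[s] += m.a; sl[s] += m.l; sa2[s] += m.a * m.a; sl2[s] += m.l * m.l;
    }
    sr[0].push_back((double)step_no);
    sr[1].push_back(time);
    sr[2].push_back((double)nRf);
    sr[3].push_back((double)nPf);
    sr[4].push_back((double)nRR);
    sr[5].push_back((double)nRP);
    sr[6].push_back((double)(nRf + 2 * nRR + nRP));
    sr[7].push_back((double)(nPf + nRP));
    for (int s = 0; s < 2; ++s) {
      if (n[s] == 0) {
        for (int k = 0; k < 4; ++k) sr[8 + 4 * s + k].push_back(NA_REAL);
      } else {
        double ma = sa[s] / n[s], ml = sl[s] / n[s];
        double va = std::max(0.0, sa2[s] / n[s] - ma * ma);
        double vl = std::max(0.0, sl2[s] / n[s] - ml * ml);
        sr[8 + 4 * s].push_back(ma);
        sr[9 + 4 * s].push_back(std::sqrt(va));
        sr[10 + 4 * s].push_back(ml);
        sr[11 + 4 * s].push_back(std::sqrt(vl));
      }
    }
  }

  void record_events() {
    ev_rows[0].push_back(step_no);
    ev_rows[1].push_back(ev.decays_free);
    ev_rows[2].push_back(ev.decays_in_complex);
    ev_rows[3].push_back(ev.dissociations);
    ev_rows[4].push_back(ev.replications);
    ev_rows[5].push_back(ev.complex_formations);
    ev_rows[6].push_back(ev.overcrowd_removals);
  }

  int new_mol(signed char species, double x, double y, double a, double l,
              double rlt) {
    Mol m;
    m.x = x; m.y = y; m.a = a; m.l = l; m.rlt = rlt;
    m.id = next_id++; m.species = species; m.state = 0;
    mols.push_back(m);
    return (int)mols.size() - 1;
  }

  double mutate(double v, double mu) {
    if (mu <= 0.0) return v;
    if (rng.unif() < mu) {
      v += (2.0 * rng.unif() - 1.0) * delta;
      if (v < 0.0) v = 0.0;
      if (v > 1.0) v = 1.0;
    }
    return v;
  }

  // release both members of a complex as free molecules at the complex
  // position, with clocks per the decay mode
  void release(Cx &c) {
    Mol &r = mols[c.cat], &t = mols[c.tmpl];
    r.x = t.x = c.x; r.y = t.y = c.y;
    if (decay_mode == 1) { r.rlt = c.cat_rlt0; t.rlt = c.tmpl_rlt0; }
    r.state = t.state = 0;
    c.alive = false;
  }

  void kill_mol(int i) { mols[i].state = 2; }

  void process_free(int i) {
    Mol &m = mols[i];
    census(i, m.x, m.y, &nbuf);
    if ((int)nbuf.size() > nmax) {
      grid.remove(i, m.x, m.y);
      kill_mol(i);
      ev.overcrowd_removals += 1;
      return;
    }
    rbuf.assign(nbuf.begin(), nbuf.end()); // reaction loop uses pre-move census
    shuffle(rbuf);
    // Brownian move
    double g1, g2;
    rng.gauss_pair(g1, g2);
    double s = std::sqrt(2.0 * D * dt);
    double nxp = wrapx(m.x + s * g1), nyp = wrapy(m.y + s * g2);
    grid.remove(i, m.x, m.y);
    m.x = nxp; m.y = nyp;
    grid.insert(i, m.x, m.y);
    // complex formation with the first eligible neighbor passing the w test
    for (int h : rbuf) {
      if (h < 0) continue;               // complexes cannot react
      Mol &n = mols[h];
      if (n.state != 0) continue;        // stale: died or complexed meanwhile
      if (m.species == SP_P && n.species == SP_P) continue;
      int ti, ci;
      if (m.species == SP_P)      { ti = i; ci = h; } // initiating parasite is template
      else if (n.species == SP_P) { ti = h; ci = i; } // parasite partner is template
      else                        { ti = h; ci = i; } // R-R: non-initiator is template
      double w = mols[ti].a * (1.0 - mols[ti].l);
      if (rng.unif() < w) {
        Cx c;
        // minimal-image midpoint
        double dx = mols[h].x - m.x;
        if (dx > 0.5 * W) dx -= W; else if (dx < -0.5 * W) dx += W;
        double dy = mols[h].y - m.y;
        if (dy > 0.5 * H) dy -= H; else if (dy < -0.5 * H) dy += H;
        c.x = wrapx(m.x + 0.5 * dx);
        c.y = wrapy(m.y + 0.5 * dy);
        c.ttr = rng.rexp(K);
        c.diss_rlt = rng.rexp(1.0 - mols[ti].a);
        c.cat = ci; c.tmpl = ti;
        c.cat_rlt0 = mols[ci].rlt; c.tmpl_rlt0 = mols[ti].rlt;
        c.alive = true;
        mols[ci].state = 1; mols[ti].state = 1;
        grid.remove(i, m.x, m.y);
        grid.remove(h, mols[h].x, mols[h].y);
        cxs.push_back(c);
        grid.insert(-(int)cxs.size(), c.x, c.y);
        ev.complex_formations += 1;
        return;
      }
    }
  }

  void process_complex(int ci) {
    Cx &c = cxs[ci];
    int h = -ci - 1;
    int nn = census(h, c.x, c.y, nullptr);
    if (nn > nmax) {
      grid.remove(h, c.x, c.y);
      kill_mol(c.cat); kill_mol(c.tmpl);
      c.alive = false;
      ev.overcrowd_removals += 2;
      return;
    }
    double g1, g2;
    rng.gauss_pair(g1, g2);
    double s = std::sqrt(2.0 * Dc * dt);
    double nxp = wrapx(c.x + s * g1), nyp = wrapy(c.y + s * g2);
    grid.remove(h, c.x, c.y);
    c.x = nxp; c.y = nyp;
    grid.insert(h, c.x, c.y);
    c.ttr -= dt;
    if (c.ttr <= 0.0) {
      // replicate: offspring copies the template, then mutates
      signed char tsp = mols[c.tmpl].species;
      double a = mols[c.tmpl].a, l = mols[c.tmpl].l;
      if (tsp == SP_R) { a = mutate(a, mu_aR); l = mutate(l, mu_lR); }
      else             { a = mutate(a, mu_aP); l = mutate(l, mu_lP); }
      double rlt = rng.rexp(d);
      double th = 6.283185307179586476925286766559 * rng.unif();
      double ox = wrapx(c.x + offspring_offset * std::cos(th));
      double oy = wrapy(c.y + offspring_offset * std::sin(th));
      int oi = new_mol(tsp, ox, oy, a, l, rlt); // may reallocate mols
      grid.insert(oi, ox, oy);
      ev.replications += 1;
      // immediate post-replication dissociation
      Cx &c2 = cxs[ci]; // mols push_back may not invalidate cxs, but re-ref anyway
      release(c2);
      grid.remove(h, c2.x, c2.y);
      grid.insert(c2.cat, c2.x, c2.y);
      grid.insert(c2.tmpl, c2.x, c2.y);
    }
  }

  void do_step() {
    time += dt;
    step_no += 1;
    ev.reset();
    long live_before = live_molecules();

    // (ii) clock decrements
    for (Mol &m : mols)
      if (m.state == 0) m.rlt -= dt;
    for (Cx &c : cxs) {
      if (!c.alive) continue;
      c.diss_rlt -= dt;
      if (decay_mode == 0) { mols[c.cat].rlt -= dt; mols[c.tmpl].rlt -= dt; }
    }

    // (iii) expired free molecules decay
    for (Mol &m : mols)
      if (m.state == 0 && m.rlt <= 0.0) { m.state = 2; ev.decays_free += 1; }

    // (iii) in-complex decay (ticking mode): the expired member dies, the
    // partner is set free at the complex position with its remaining clock
    if (decay_mode == 0) {
      for (Cx &c : cxs) {
        if (!c.alive) continue;
        bool cd = mols[c.cat].rlt <= 0.0, td = mols[c.tmpl].rlt <= 0.0;
        if (!cd && !td) continue;
        if (cd) { kill_mol(c.cat); ev.decays_in_complex += 1; }
        if (td) { kill_mol(c.tmpl); ev.decays_in_complex += 1; }
        if (!cd) { Mol &p = mols[c.cat]; p.x = c.x; p.y = c.y; p.state = 0; }
        if (!td) { Mol &p = mols[c.tmpl]; p.x = c.x; p.y = c.y; p.state = 0; }
        c.alive = false;
      }
    }

    // (iv) snapshot, shuffle, rebuild grid
    order.clear();
    for (int i = 0; i < (int)mols.size(); ++i)
      if (mols[i].state == 0) order.push_back(i);
    for (int ci = 0; ci < (int)cxs.size(); ++ci)
      if (cxs[ci].alive) order.push_back(-ci - 1);
    shuffle(order);
    grid.clear();
    for (int h : order) {
      double x, y;
      entity_xy(h, x, y);
      grid.insert(h, x, y);
    }

    // (v) process entities in shuffled order
    for (int h : order) {
      if (h >= 0) {
        if (mols[h].state != 0) continue; // complexed or removed meanwhile
        process_free(h);
      } else {
        int ci = -h - 1;
        if (!cxs[ci].alive) continue;
        Cx &c = cxs[ci];
        if (c.diss_rlt <= 0.0) {
          // clock dissociation happens before any TTR decrement
          grid.remove(h, c.x, c.y);
          release(c);
          grid.insert(c.cat, c.x, c.y);
          grid.insert(c.tmpl, c.x, c.y);
          ev.dissociations += 1;
          continue;
        }
        process_complex(ci);
      }
    }

    // molecule-conservation ledger
    long live_after = live_molecules();
    long expected = live_before + ev.replications - ev.decays_free -
                    ev.decays_in_complex - ev.overcrowd_removals;
    if (live_after != expected)
      Rcpp::stop("internal: molecule ledger imbalance at step %ld", step_no);

    compact();
    record_row();
    record_events();
  }

  void compact() {
    size_t dead = 0;
    for (const Mol &m : mols) if (m.state == 2) ++dead;
    if (dead < 1024 && dead * 2 < mols.size()) return;
    std::vector<int> map(mols.size(), -1);
    std::vector<Mol> keep;
    keep.reserve(mols.size() - dead);
    for (size_t i = 0; i < mols.size(); ++i)
      if (mols[i].state != 2) { map[i] = (int)keep.size(); keep.push_back(mols[i]); }
    mols.swap(keep);
    std::vector<Cx> ckeep;
    for (Cx &c : cxs)
      if (c.alive) { c.cat = map[c.cat]; c.tmpl = map[c.tmpl]; ckeep.push_back(c); }
    cxs.swap(ckeep);
  }

  // returns number of steps executed; stops early on extinction
  long run(long nsteps, bool stop_on_extinction) {
    if (sr[0].empty()) { record_row(); record_events0(); }
    long done = 0;
    for (long s = 0; s < nsteps; ++s) {
      if (stop_on_extinction) {
        long nRf, nPf, nRR, nRP;
        counts(nRf, nPf, nRR, nRP);
        if (nRf + 2 * nRR + nRP == 0 || nPf + nRP == 0) break;
      }
      do_step();
      ++done;
      if (done % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return done;
  }

  void record_events0() {
    ev.reset();
    record_events();
  }
};

Engine *get(SEXP xp) {
  Rcpp::XPtr<Engine> p(xp);
  if (!p) Rcpp::stop("invalid engine pointer");
  return p.get();
}

} // namespace

// [[Rcpp::export(name = ".cpp_engine_new")]]
SEXP cpp_engine_new(double width, double height, List kin, List mut,
                    int decay_mode, double offspring_offset, double seed) {
  Engine *e = new Engine();
  e->W = width; e->H = height;
  e->d = as<double>(kin["d"]);
  e->D = as<double>(kin["D"]);
  e->Dc = as<double>(kin["D_complex"]);
  e->K = as<double>(kin["K"]);
  e->dt = as<double>(kin["dt"]);
  e->radius = as<double>(kin["radius"]);
  e->rc = 2.0 * e->radius;
  e->nmax = as<int>(kin["n_max"]);
  e->mu_aR = as<double>(mut["mu_a_R"]);
  e->mu_lR = as<double>(mut["mu_l_R"]);
  e->mu_aP = as<double>(mut["mu_a_P"]);
  e->mu_lP = as<double>(mut["mu_l_P"]);
  e->delta = as<double>(mut["delta"]);
  e->decay_mode = decay_mode;
  e->offspring_offset = offspring_offset;
  e->rng.seed((std::uint64_t)seed);
  e->grid.configure(e->W, e->H, e->rc);
  return Rcpp::XPtr<Engine>(e, true);
}

// [[Rcpp::export(name = ".cpp_engine_populate")]]
void cpp_engine_populate(SEXP xp, int n_replicases, int n_parasites,
                         std::string placement, double disc_radius,
                         double a_R0, double l_R0, double a_P0, double l_P0) {
  Engine *e = get(xp);
  double cx = e->W / 2.0, cy = e->H / 2.0;
  bool circle = placement == "circle";
  // replicases in the upper half-disc, parasites in the lower
  for (int k = 0; k < n_replicases + n_parasites; ++k) {
    bool isR = k < n_replicases;
    double x, y;
    if (circle) {
      double r = disc_radius * std::sqrt(e->rng.unif());
      double th = M_PI * e->rng.unif() + (isR ? 0.0 : M_PI);
      x = e->wrapx(cx + r * std::cos(th));
      y = e->wrapy(cy + r * std::sin(th));
    } else {
      x = e->W * e->rng.unif();
      y = e->H * e->rng.unif();
    }
    double rlt = e->rng.rexp(e->d);
    e->new_mol(isR ? SP_R : SP_P, x, y,
               isR ? a_R0 : a_P0, isR ? l_R0 : l_P0, rlt);
  }
}

// [[Rcpp::export(name = ".cpp_engine_set_state")]]
void cpp_engine_set_state(SEXP xp, DataFrame molecules, DataFrame complexes,
                          double time, double step, int next_id) {
  Engine *e = get(xp);
  e->mols.clear();
  e->cxs.clear();
  e->time = time;
  e->step_no = (long)step;
  IntegerVector id = molecules["id"], sp = molecules["species_code"];
  NumericVector x = molecules["x"], y = molecules["y"], a = molecules["a"],
                l = molecules["l"], rlt = molecules["rlt"];
  for (int i = 0; i < id.size(); ++i) {
    Mol m;
    m.id = id[i]; m.species = (signed char)sp[i];
    m.x = e->wrapx(x[i]); m.y = e->wrapy(y[i]);
    m.a = a[i]; m.l = l[i]; m.rlt = rlt[i]; m.state = 0;
    e->mols.push_back(m);
  }
  if (complexes.nrows() > 0) {
    NumericVector cxx = complexes["x"], cxy = complexes["y"],
                  ttr = complexes["ttr"], diss = complexes["diss_rlt"];
    IntegerVector cid = complexes["cat_id"], csp = complexes["cat_species_code"],
                  tid = complexes["tmpl_id"], tsp = complexes["tmpl_species_code"];
    NumericVector ca = complexes["cat_a"], cl = complexes["cat_l"],
                  crlt = complexes["cat_rlt"], crlt0 = complexes["cat_rlt0"],
                  ta = complexes["tmpl_a"], tl = complexes["tmpl_l"],
                  trlt = complexes["tmpl_rlt"], trlt0 = complexes["tmpl_rlt0"];
    for (int i = 0; i < complexes.nrows(); ++i) {
      if (csp[i] != SP_R) Rcpp::stop("complex catalyst must be a replicase");
      Cx c;
      c.x = e->wrapx(cxx[i]); c.y = e->wrapy(cxy[i]);
      c.ttr = ttr[i];
      c.diss_rlt = NumericVector::is_na(diss[i]) ? INFINITY : (double)diss[i];
      Mol mc; mc.id = cid[i]; mc.species = (signed char)csp[i];
      mc.x = c.x; mc.y = c.y; mc.a = ca[i]; mc.l = cl[i]; mc.rlt = crlt[i];
      mc.state = 1;
      e->mols.push_back(mc);
      c.cat = (int)e->mols.size() - 1;
      Mol mt; mt.id = tid[i]; mt.species = (signed char)tsp[i];
      mt.x = c.x; mt.y = c.y; mt.a = ta[i]; mt.l = tl[i]; mt.rlt = trlt[i];
      mt.state = 1;
      e->mols.push_back(mt);
      c.tmpl = (int)e->mols.size() - 1;
      c.cat_rlt0 = crlt0[i]; c.tmpl_rlt0 = trlt0[i];
      c.alive = true;
      e->cxs.push_back(c);
    }
  }
  e->next_id = next_id;
}

// [[Rcpp::export(name = ".cpp_engine_run")]]
List cpp_engine_run(SEXP xp, double nsteps, bool stop_on_extinction) {
  Engine *e = get(xp);
  long done = e->run((long)nsteps, stop_on_extinction);
  long nRf, nPf, nRR, nRP;
  e->counts(nRf, nPf, nRR, nRP);
  return List::create(
      _["steps_done"] = (double)done, _["step"] = (double)e->step_no,
      _["time"] = e->time, _["n_R_total"] = (double)(nRf + 2 * nRR + nRP),
      _["n_P_total"] = (double)(nPf + nRP));
}

// [[Rcpp::export(name = ".cpp_engine_series")]]
DataFrame cpp_engine_series(SEXP xp) {
  Engine *e = get(xp);
  return DataFrame::create(
      _["step"] = e->sr[0], _["time"] = e->sr[1],
      _["n_R_free"] = e->sr[2], _["n_P_free"] = e->sr[3],
      _["n_RR_complexes"] = e->sr[4], _["n_RP_complexes"] = e->sr[5],
      _["n_R_total"] = e->sr[6], _["n_P_total"] = e->sr[7],
      _["mean_a_R"] = e->sr[8], _["sd_a_R"] = e->sr[9],
      _["mean_l_R"] = e->sr[10], _["sd_l_R"] = e->sr[11],
      _["mean_a_P"] = e->sr[12], _["sd_a_P"] = e->sr[13],
      _["mean_l_P"] = e->sr[14], _["sd_l_P"] = e->sr[15]);
}

// [[Rcpp::export(name = ".cpp_engine_events")]]
DataFrame cpp_engine_events(SEXP xp) {
  Engine *e = get(xp);
  auto dbl = [](const std::vector<long> &v) {
    NumericVector o(v.size());
    for (size_t i = 0; i < v.size(); ++i) o[i] = (double)v[i];
    return o;
  };
  return DataFrame::create(
      _["step"] = dbl(e->ev_rows[0]), _["decays_free"] = dbl(e->ev_rows[1]),
      _["decays_in_complex"] = dbl(e->ev_rows[2]),
      _["dissociations"] = dbl(e->ev_rows[3]),
      _["replications"] = dbl(e->ev_rows[4]),
      _["complex_formations"] = dbl(e->ev_rows[5]),
      _["overcrowd_removals"] = dbl(e->ev_rows[6]));
}

// [[Rcpp::export(name = ".cpp_engine_state")]]
List cpp_engine_state(SEXP xp) {
  Engine *e = get(xp);
  long nm = 0;
  for (const Mol &m : e->mols) if (m.state == 0) ++nm;
  IntegerVector id(nm), sp(nm);
  NumericVector x(nm), y(nm), a(nm), l(nm), rlt(nm);
  long i = 0;
  for (const Mol &m : e->mols) {
    if (m.state != 0) continue;
    id[i] = m.id; sp[i] = m.species; x[i] = m.x; y[i] = m.y;
    a[i] = m.a; l[i] = m.l; rlt[i] = m.rlt;
    ++i;
  }
  long nc = 0;
  for (const Cx &c : e->cxs) if (c.alive) ++nc;
  NumericVector cx(nc), cy(nc), ttr(nc), diss(nc), ca(nc), cl(nc), crlt(nc),
      crlt0(nc), ta(nc), tl(nc), trlt(nc), trlt0(nc);
  IntegerVector cid(nc), csp(nc), tid(nc), tsp(nc);
  i = 0;
  for (const Cx &c : e->cxs) {
    if (!c.alive) continue;
    const Mol &mc = e->mols[c.cat], &mt = e->mols[c.tmpl];
    cx[i] = c.x; cy[i] = c.y; ttr[i] = c.ttr;
    diss[i] = std::isinf(c.diss_rlt) ? NA_REAL : c.diss_rlt;
    cid[i] = mc.id; csp[i] = mc.species; ca[i] = mc.a; cl[i] = mc.l;
    crlt[i] = mc.rlt; crlt0[i] = c.cat_rlt0;
    tid[i] = mt.id; tsp[i] = mt.species; ta[i] = mt.a; tl[i] = mt.l;
    trlt[i] = mt.rlt; trlt0[i] = c.tmpl_rlt0;
    ++i;
  }
  return List::create(
      _["molecules"] = DataFrame::create(
          _["id"] = id, _["species_code"] = sp, _["x"] = x, _["y"] = y,
          _["a"] = a, _["l"] = l, _["rlt"] = rlt),
      _["complexes"] = DataFrame::create(
          _["x"] = cx, _["y"] = cy, _["ttr"] = ttr, _["diss_rlt"] = diss,
          _["cat_id"] = cid, _["cat_species_code"] = csp, _["cat_a"] = ca,
          _["cat_l"] = cl, _["cat_rlt"] = crlt, _["cat_rlt0"] = crlt0,
          _["tmpl_id"] = tid, _["tmpl_species_code"] = tsp, _["tmpl_a"] = ta,
          _["tmpl_l"] = tl, _["tmpl_rlt"] = trlt, _["tmpl_rlt0"] = trlt0),
      _["time"] = e->time, _["step"] = (double)e->step_no,
      _["next_id"] = e->next_id);
}

// [[Rcpp::export(name = ".cpp_engine_counts")]]
NumericVector cpp_engine_counts(SEXP xp) {
  Engine *e = get(xp);
  long nRf, nPf, nRR, nRP;
  e->counts(nRf, nPf, nRR, nRP);
  return NumericVector::create(
      _["n_R_free"] = (double)nRf, _["n_P_free"] = (double)nPf,
      _["n_RR_complexes"] = (double)nRR, _["n_RP_complexes"] = (double)nRP,
      _["n_R_total"] = (double)(nRf + 2 * nRR + nRP),
      _["n_P_total"] = (double)(nPf + nRP));
}
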