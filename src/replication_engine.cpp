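// Event-driven (kinetic Monte Carlo) engine for whole-genome DNA
// replication with stochastic spontaneous origin firing, domino-like
// induced firing near active forks, a diffusible limiting factor, and
// fork annihilation / barrier absorption.
//
// All forks share one global speed v(t) (linear ramp to nu over `ramp`
// seconds), so a right-moving fork keeps a constant anchor u = x - s(t)
// and a left-moving fork a constant anchor w = x + s(t), where s(t) is
// the cumulative fork travel distance.  Ordered sets keyed on these
// anchors give O(log n) nearest-fork queries at any time without ever
// updating stored positions.

#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

// ---- fork speed schedule ---------------------------------------------------

struct SpeedSchedule {
  double nu;    // plateau speed, bp/s
  double ramp;  // ramp duration, s

  double speed(double t) const {
    if (ramp <= 0.0) return nu;
    return t >= ramp ? nu : nu * t / ramp;
  }
  // cumulative distance travelled by one fork from time 0 to t
  double dist(double t) const {
    if (ramp <= 0.0) return nu * t;
    if (t <= ramp) return 0.5 * nu * t * t / ramp;
    return nu * (t - 0.5 * ramp);
  }
  // inverse of dist(); d >= 0
  double inv(double d) const {
    if (ramp <= 0.0) return d / nu;
    double dramp = 0.5 * nu * ramp;
    if (d <= dramp) return std::sqrt(2.0 * d * ramp / nu);
    return d / nu + 0.5 * ramp;
  }
};

// ---- events ----------------------------------------------------------------

enum EventKind {
  EV_COLLISION = 0,
  EV_BARRIER = 1,
  EV_CROSSING = 2,
  EV_FACTOR = 3,
  EV_FORCED = 4
};

struct Event {
  double t;
  int kind;
  double pos;   // tie-break position
  int a, b;     // fork ids / payload
};

struct EventLater {
  bool operator()(const Event& x, const Event& y) const {
    if (x.t != y.t) return x.t > y.t;
    if (x.kind != y.kind) return x.kind > y.kind;
    return x.pos > y.pos;
  }
};

struct Fork {
  double anchor;  // u for right-movers, w for left-movers
  int dir;        // +1 right, -1 left
  int chrom;
  int zone;       // current zone index
  int firing;     // index into firing records
  bool alive;
};

struct Firing {
  double pos;
  double time;
  int mode;    // 0 spontaneous, 1 induced, 2 forced/initial
  int cls;     // zone class 0 EU, 1 FAC, 2 CON
  int chrom;
  double left_end, right_end;  // replicon boundaries, filled on fork removal
};

struct Engine {
  // genome
  std::vector<double> zone_start, zone_end;  // global coords, sorted
  std::vector<int> zone_class, zone_chrom;
  std::vector<double> barrier;               // n_chrom + 1
  double total_len;

  // parameters
  SpeedSchedule sp;
  double sigma, cutoff, di;
  double pclass[3];
  bool induced_on;
  double lmax, tau;
  double gauss_range;  // distance beyond which the Gaussian is < cutoff

  // origins
  std::vector<double> opos;
  std::vector<int> ozone;
  std::vector<int> ostate;  // 0 unfired, 1 fired, 2 passively replicated
  std::vector<int> cand;    // candidate pool (indices into opos)
  long n_spont_cand;        // candidates in classes with p_class > 0

  // dynamic state
  std::priority_queue<Event, std::vector<Event>, EventLater> heap;
  std::vector<Fork> forks;
  std::set<std::pair<double, int> > rset, lset;  // (anchor, fork id)
  std::vector<char> chrom_left_done;
  int capacity;      // floor(L(t)) at the last factor event, <= lmax
  int n_forks;
  double now, s_now;

  // bookkeeping
  double repl_by_class[3];
  int forks_by_class[3];
  std::vector<Firing> firings;
  std::mt19937_64 rng;

  // recording
  double rec_interval, next_rec;
  std::vector<double> rec_t;
  std::vector<double> rec_repl[3];
  std::vector<int> rec_forks[3];
  std::vector<int> rec_free;
  std::vector<double> snap_times;
  size_t snap_idx;
  std::vector<std::vector<double> > snap_pos;
  std::vector<std::vector<int> > snap_dir, snap_cls;

  double completion_time;
  bool complete;
  long n_events, n_offers;
  long pending_creators;  // unprocessed factor-release + forced events

  double runif01() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }

  int zone_of(double x) const {
    int lo = 0, hi = (int)zone_start.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (zone_start[mid] <= x) lo = mid; else hi = mid - 1;
    }
    return lo;
  }

  // current position helpers
  double fork_pos(const Fork& f) const {
    return f.dir > 0 ? f.anchor + s_now : f.anchor - s_now;
  }

  // nearest alive fork at current time with position <= x on the same
  // chromosome; returns id or -1
  int nearest_fork_left(double x, int chrom) const {
    double blo = barrier[chrom];
    int best = -1;
    double bestp = blo - 1.0;
    // right-movers: pos = u + s <= x  <=>  u <= x - s
    {
      auto it = rset.upper_bound(std::make_pair(x - s_now, INT32_MAX));
      if (it != rset.begin()) {
        --it;
        double p = it->first + s_now;
        if (p > blo && p > bestp) { best = it->second; bestp = p; }
      }
    }
    // left-movers: pos = w - s <= x  <=>  w <= x + s
    {
      auto it = lset.upper_bound(std::make_pair(x + s_now, INT32_MAX));
      if (it != lset.begin()) {
        --it;
        double p = it->first - s_now;
        if (p > blo && p > bestp) { best = it->second; bestp = p; }
      }
    }
    return best;
  }

  bool is_replicated(double x, int chrom) const {
    int id = nearest_fork_left(x, chrom);
    if (id < 0) return chrom_left_done[chrom] != 0;
    return forks[id].dir < 0;  // left-mover: replicated DNA on its right
  }

  // relative induced firing probability at x; sets `inhibited` if an
  // active same-chromosome fork is closer than di
  double induced_probability(double x, int chrom, bool& inhibited) const {
    inhibited = false;
    double reach = std::max(gauss_range, di);
    double blo = barrier[chrom], bhi = barrier[chrom + 1];
    double best = 0.0;
    // right-movers in [x - reach, x + reach]
    {
      auto it = rset.lower_bound(std::make_pair(x - reach - s_now, INT32_MIN));
      auto end = rset.upper_bound(std::make_pair(x + reach - s_now, INT32_MAX));
      for (; it != end; ++it) {
        double p = it->first + s_now;
        if (p <= blo || p >= bhi) continue;
        double d = std::fabs(x - p);
        if (d < di) { inhibited = true; return 0.0; }
        double g = std::exp(-0.5 * d * d / (sigma * sigma));
        if (g >= cutoff && g > best) best = g;
      }
    }
    {
      auto it = lset.lower_bound(std::make_pair(x - reach + s_now, INT32_MIN));
      auto end = lset.upper_bound(std::make_pair(x + reach + s_now, INT32_MAX));
      for (; it != end; ++it) {
        double p = it->first - s_now;
        if (p <= blo || p >= bhi) continue;
        double d = std::fabs(x - p);
        if (d < di) { inhibited = true; return 0.0; }
        double g = std::exp(-0.5 * d * d / (sigma * sigma));
        if (g >= cutoff && g > best) best = g;
      }
    }
    return best;
  }

  // advance per-class replicated-bp integration to time t; never moves
  // backwards (guards against sub-nanosecond float drift in event times)
  void advance(double t) {
    if (t <= now) return;
    double s_new = sp.dist(t);
    double ds = s_new - s_now;
    if (ds > 0.0) {
      for (int k = 0; k < 3; ++k) {
        repl_by_class[k] += ds * forks_by_class[k];
      }
    }
    now = t;
    s_now = s_new;
  }

  double total_replicated() const {
    return repl_by_class[0] + repl_by_class[1] + repl_by_class[2];
  }

  void flush_records(double upto) {
    while (next_rec <= upto) {
      advance(next_rec);
      push_record();
      next_rec += rec_interval;
    }
    while (snap_idx < snap_times.size() && snap_times[snap_idx] <= upto) {
      advance(snap_times[snap_idx]);
      push_snapshot();
      ++snap_idx;
    }
  }

  void push_record() {
    rec_t.push_back(now);
    for (int k = 0; k < 3; ++k) {
      rec_repl[k].push_back(repl_by_class[k]);
      rec_forks[k].push_back(forks_by_class[k]);
    }
    rec_free.push_back(std::max(0, capacity - n_forks));
  }

  void push_snapshot() {
    std::vector<double> ps;
    std::vector<int> ds, cs;
    for (size_t i = 0; i < forks.size(); ++i) {
      if (!forks[i].alive) continue;
      ps.push_back(fork_pos(forks[i]));
      ds.push_back(forks[i].dir);
      cs.push_back(zone_class[forks[i].zone]);
    }
    snap_pos.push_back(ps);
    snap_dir.push_back(ds);
    snap_cls.push_back(cs);
  }

  // ---- fork creation and event scheduling ---------------------------------

  void schedule_crossing(int id) {
    const Fork& f = forks[id];
    double blo = barrier[f.chrom], bhi = barrier[f.chrom + 1];
    if (f.dir > 0) {
      double b = zone_end[f.zone];
      if (b < bhi - 1e-9) {
        double t = sp.inv(b - f.anchor);
        heap.push(Event{t, EV_CROSSING, b, id, f.zone + 1});
      }
    } else {
      double b = zone_start[f.zone];
      if (b > blo + 1e-9) {
        double t = sp.inv(f.anchor - b);
        heap.push(Event{t, EV_CROSSING, b, id, f.zone - 1});
      }
    }
  }

  void schedule_motion(int id, int exclude = -1) {
    // collision with the nearest approaching partner, else barrier
    // arrival; `exclude` skips the sibling fork of a fresh pair (the two
    // siblings move apart and must never be paired with each other)
    const Fork& f = forks[id];
    double blo = barrier[f.chrom], bhi = barrier[f.chrom + 1];
    if (f.dir > 0) {
      // nearest left-mover strictly to the right: smallest w > x + s
      auto it = lset.upper_bound(std::make_pair(f.anchor + 2.0 * s_now,
                                                INT32_MAX));
      while (it != lset.end() && it->second == exclude) ++it;
      if (it != lset.end() && it->first - s_now < bhi &&
          it->first > f.anchor) {
        double meet_s = 0.5 * (it->first - f.anchor);
        double meet = f.anchor + meet_s;
        heap.push(Event{sp.inv(meet_s), EV_COLLISION, meet, id, it->second});
      } else {
        heap.push(Event{sp.inv(bhi - f.anchor), EV_BARRIER, bhi, id, -1});
      }
    } else {
      // nearest right-mover strictly to the left: largest u < x - s
      auto it = rset.lower_bound(std::make_pair(f.anchor - 2.0 * s_now,
                                                INT32_MIN));
      bool found = false;
      while (it != rset.begin()) {
        --it;
        if (it->second != exclude) { found = true; break; }
      }
      if (found && it->first + s_now > blo && it->first < f.anchor) {
        double meet_s = 0.5 * (f.anchor - it->first);
        double meet = f.anchor - meet_s;
        heap.push(Event{sp.inv(meet_s), EV_COLLISION, meet,
                        it->second, id});
      } else {
        heap.push(Event{sp.inv(f.anchor - blo), EV_BARRIER, blo, id, -1});
      }
    }
  }

  void create_fork_pair(double x, int chrom, int firing_idx) {
    int z = zone_of(x);
    // right-mover
    Fork fr;
    fr.anchor = x - s_now; fr.dir = +1; fr.chrom = chrom; fr.zone = z;
    fr.firing = firing_idx; fr.alive = true;
    forks.push_back(fr);
    int idr = (int)forks.size() - 1;
    // left-mover
    Fork fl;
    fl.anchor = x + s_now; fl.dir = -1; fl.chrom = chrom; fl.zone = z;
    fl.firing = firing_idx; fl.alive = true;
    forks.push_back(fl);
    int idl = (int)forks.size() - 1;
    // schedule before inserting, so the siblings do not pair with each
    // other (their anchors are excluded by the strict comparisons)
    rset.insert(std::make_pair(fr.anchor, idr));
    lset.insert(std::make_pair(fl.anchor, idl));
    schedule_motion(idr, idl);
    schedule_motion(idl, idr);
    schedule_crossing(idr);
    schedule_crossing(idl);
    n_forks += 2;
    forks_by_class[zone_class[z]] += 2;
  }

  void remove_fork(int id, double end_pos) {
    Fork& f = forks[id];
    f.alive = false;
    if (f.dir > 0) {
      rset.erase(std::make_pair(f.anchor, id));
      firings[f.firing].right_end = end_pos;
    } else {
      lset.erase(std::make_pair(f.anchor, id));
      firings[f.firing].left_end = end_pos;
    }
    --n_forks;
    --forks_by_class[zone_class[f.zone]];
  }

  // ---- firing --------------------------------------------------------------

  void fire(int oi, int mode) {
    ostate[oi] = 1;
    Firing rec;
    rec.pos = opos[oi];
    rec.time = now;
    rec.mode = mode;
    rec.cls = zone_class[ozone[oi]];
    rec.chrom = zone_chrom[ozone[oi]];
    rec.left_end = NA_REAL;
    rec.right_end = NA_REAL;
    firings.push_back(rec);
    create_fork_pair(opos[oi], rec.chrom, (int)firings.size() - 1);
  }

  // Offer candidates (uniformly, without replacement within the round)
  // until fewer than two factors are free or every candidate has been
  // offered once.  Candidates found passively replicated are dropped
  // lazily.  Firing consumes two factors and creates a fork pair.
  void attempt_firings() {
    // when induction is off, only candidates of a class with positive
    // spontaneous probability can ever fire; once none remain, a round
    // cannot fire anything and the scan is skipped
    if (!induced_on && n_spont_cand == 0) return;
    size_t i = 0;
    while (capacity - n_forks >= 2 && i < cand.size()) {
      size_t j = i + (size_t)(runif01() * (double)(cand.size() - i));
      if (j >= cand.size()) j = cand.size() - 1;
      std::swap(cand[i], cand[j]);
      int oi = cand[i];
      ++n_offers;
      int chrom = zone_chrom[ozone[oi]];
      if (ostate[oi] != 0 || is_replicated(opos[oi], chrom)) {
        if (ostate[oi] == 0) ostate[oi] = 2;
        drop_candidate(i, oi);
        continue;
      }
      bool inhibited = false;
      double pind = induced_on
        ? induced_probability(opos[oi], chrom, inhibited) : 0.0;
      double psp = inhibited ? 0.0 : pclass[zone_class[ozone[oi]]];
      double p = std::max(psp, pind);
      if (p > 0.0 && runif01() < p) {
        int mode = (psp >= pind) ? 0 : 1;
        drop_candidate(i, oi);
        fire(oi, mode);
      } else {
        ++i;
      }
    }
  }

  void drop_candidate(size_t i, int oi) {
    if (pclass[zone_class[ozone[oi]]] > 0.0) --n_spont_cand;
    cand[i] = cand.back();
    cand.pop_back();
  }

  // ---- event handlers ------------------------------------------------------

  void handle(const Event& ev) {
    switch (ev.kind) {
    case EV_COLLISION: {
      if (!forks[ev.a].alive || !forks[ev.b].alive) return;
      remove_fork(ev.a, ev.pos);
      remove_fork(ev.b, ev.pos);
      attempt_firings();
      break;
    }
    case EV_BARRIER: {
      if (!forks[ev.a].alive) return;
      const Fork f = forks[ev.a];
      remove_fork(ev.a, ev.pos);
      if (f.dir < 0) chrom_left_done[f.chrom] = 1;
      attempt_firings();
      break;
    }
    case EV_CROSSING: {
      if (!forks[ev.a].alive) return;
      Fork& f = forks[ev.a];
      --forks_by_class[zone_class[f.zone]];
      f.zone = ev.b;
      ++forks_by_class[zone_class[f.zone]];
      schedule_crossing(ev.a);
      break;
    }
    case EV_FACTOR: {
      --pending_creators;
      if (capacity < (int)lmax) {
        ++capacity;
        attempt_firings();
      }
      break;
    }
    case EV_FORCED: {
      --pending_creators;
      // deterministic-scenario firing: bypasses the factor limit
      int oi = ev.a;
      if (ostate[oi] == 0 && !is_replicated(opos[oi], zone_chrom[ozone[oi]])) {
        fire(oi, 2);
        for (size_t k = 0; k < cand.size(); ++k) {
          if (cand[k] == oi) { drop_candidate(k, oi); break; }
        }
      } else if (ostate[oi] == 0) {
        ostate[oi] = 2;
      }
      break;
    }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_replication_cpp")]]
List simulate_replication_cpp(
    NumericVector zone_gstart, NumericVector zone_gend,
    IntegerVector zone_class, IntegerVector zone_chrom,
    NumericVector barriers,
    NumericVector origin_pos,
    double lmax, double tau, double nu, double ramp,
    double sigma, double cutoff, double di,
    NumericVector p_class,
    bool induced_on, bool spontaneous_on,
    NumericVector forced_pos, NumericVector forced_time,
    double record_interval,
    NumericVector snapshot_times,
    int seed,
    double max_time) {

  Engine e;
  int nz = zone_gstart.size();
  e.zone_start.assign(zone_gstart.begin(), zone_gstart.end());
  e.zone_end.assign(zone_gend.begin(), zone_gend.end());
  e.zone_class.assign(zone_class.begin(), zone_class.end());
  e.zone_chrom.assign(zone_chrom.begin(), zone_chrom.end());
  e.barrier.assign(barriers.begin(), barriers.end());
  e.total_len = e.barrier.back();
  e.sp.nu = nu; e.sp.ramp = ramp;
  e.sigma = sigma; e.cutoff = cutoff; e.di = di;
  for (int k = 0; k < 3; ++k) {
    e.pclass[k] = spontaneous_on ? p_class[k] : 0.0;
  }
  e.induced_on = induced_on;
  e.lmax = lmax; e.tau = tau;
  e.gauss_range = (cutoff > 0.0 && cutoff < 1.0)
    ? sigma * std::sqrt(-2.0 * std::log(cutoff)) : 0.0;
  e.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);

  // origins (positions are pre-drawn in R, sorted)
  int n0 = origin_pos.size();
  e.opos.assign(origin_pos.begin(), origin_pos.end());
  e.ozone.resize(n0);
  e.ostate.assign(n0, 0);
  e.cand.resize(n0);
  e.n_spont_cand = 0;
  for (int i = 0; i < n0; ++i) {
    e.ozone[i] = e.zone_of(e.opos[i]);
    e.cand[i] = i;
    if (e.pclass[e.zone_class[e.ozone[i]]] > 0.0) ++e.n_spont_cand;
  }

  e.chrom_left_done.assign(e.barrier.size() - 1, 0);
  e.capacity = 0;
  e.n_forks = 0;
  e.now = 0.0; e.s_now = 0.0;
  for (int k = 0; k < 3; ++k) {
    e.repl_by_class[k] = 0.0;
    e.forks_by_class[k] = 0;
  }
  e.rec_interval = record_interval;
  e.next_rec = 0.0;
  e.snap_times.assign(snapshot_times.begin(), snapshot_times.end());
  std::sort(e.snap_times.begin(), e.snap_times.end());
  e.snap_idx = 0;
  e.complete = false;
  e.completion_time = NA_REAL;
  e.n_events = 0; e.n_offers = 0;
  e.pending_creators = 0;

  // factor-release schedule: one event at each floor-increment time of
  // L(t) = lmax (1 - exp(-t/tau)); the unreachable final increment is
  // granted where L(t) = lmax - 1/2
  int ilmax = (int)lmax;
  for (int k = 1; k < ilmax; ++k) {
    double t = -tau * std::log(1.0 - (double)k / lmax);
    e.heap.push(Event{t, EV_FACTOR, 0.0, k, -1});
    ++e.pending_creators;
  }
  if (ilmax >= 1) {
    double t = tau * std::log(2.0 * lmax);
    e.heap.push(Event{t, EV_FACTOR, 0.0, ilmax, -1});
    ++e.pending_creators;
  }

  // forced firings (deterministic scenarios, induced-only initial firing)
  for (int i = 0; i < forced_pos.size(); ++i) {
    // map to the nearest potential origin; exact-position virtual origins
    // are appended if no origin matches
    double x = forced_pos[i];
    int oi = -1;
    // binary search nearest origin within 1 bp
    int lo = 0, hi = n0 - 1;
    if (n0 > 0) {
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (e.opos[mid] < x) lo = mid + 1; else hi = mid;
      }
      for (int d = -1; d <= 0; ++d) {
        int k = lo + d;
        if (k >= 0 && k < n0 && std::fabs(e.opos[k] - x) < 0.5 &&
            e.ostate[k] == 0) { oi = k; break; }
      }
    }
    if (oi < 0) {
      e.opos.push_back(x);
      e.ozone.push_back(e.zone_of(x));
      e.ostate.push_back(0);
      oi = (int)e.opos.size() - 1;
    }
    e.heap.push(Event{forced_time[i], EV_FORCED, x, oi, -1});
    ++e.pending_creators;
  }

  // ---- main loop -----------------------------------------------------------
  long guard_counter = 0;
  while (!e.heap.empty()) {
    Event ev = e.heap.top();
    e.heap.pop();
    if (ev.t > max_time) break;
    e.flush_records(ev.t);
    e.advance(ev.t);
    e.handle(ev);
    ++e.n_events;
    if ((++guard_counter & 1023) == 0) Rcpp::checkUserInterrupt();
    if (e.n_forks == 0 &&
        e.total_replicated() >= e.total_len * (1.0 - 1e-9)) {
      e.complete = true;
      e.completion_time = e.now;
      break;
    }
    if (e.n_forks == 0 && e.capacity >= 2 && e.pending_creators == 0 &&
        e.total_replicated() < e.total_len * (1.0 - 1e-9)) {
      stop("replication cannot progress: no active forks and no origin "
           "with positive firing probability while DNA remains "
           "unreplicated");
    }
  }
  if (!e.complete && e.n_forks == 0 &&
      e.total_replicated() >= e.total_len * (1.0 - 1e-9)) {
    e.complete = true;
    e.completion_time = e.now;
  }
  if (e.complete) {
    // closing record at completion time (skip if the grid already hit it)
    e.flush_records(e.completion_time);
    e.advance(e.completion_time);
    if (e.rec_t.empty() || e.rec_t.back() != e.completion_time) {
      e.push_record();
    }
  }

  // ---- results -------------------------------------------------------------
  int nf = (int)e.firings.size();
  NumericVector fpos(nf), ftime(nf), flend(nf), frend(nf);
  IntegerVector fmode(nf), fcls(nf), fchrom(nf);
  for (int i = 0; i < nf; ++i) {
    fpos[i] = e.firings[i].pos;
    ftime[i] = e.firings[i].time;
    fmode[i] = e.firings[i].mode;
    fcls[i] = e.firings[i].cls;
    fchrom[i] = e.firings[i].chrom + 1;  // 1-based for R
    flend[i] = e.firings[i].left_end;
    frend[i] = e.firings[i].right_end;
  }

  int nr = (int)e.rec_t.size();
  DataFrame ts = DataFrame::create(
    _["time"] = NumericVector(e.rec_t.begin(), e.rec_t.end()),
    _["replicated_eu"] = NumericVector(e.rec_repl[0].begin(), e.rec_repl[0].end()),
    _["replicated_fac"] = NumericVector(e.rec_repl[1].begin(), e.rec_repl[1].end()),
    _["replicated_con"] = NumericVector(e.rec_repl[2].begin(), e.rec_repl[2].end()),
    _["forks_eu"] = IntegerVector(e.rec_forks[0].begin(), e.rec_forks[0].end()),
    _["forks_fac"] = IntegerVector(e.rec_forks[1].begin(), e.rec_forks[1].end()),
    _["forks_con"] = IntegerVector(e.rec_forks[2].begin(), e.rec_forks[2].end()),
    _["free_factors"] = IntegerVector(e.rec_free.begin(), e.rec_free.end())
  );
  (void)nr;

  List snaps(e.snap_pos.size());
  for (size_t i = 0; i < e.snap_pos.size(); ++i) {
    snaps[i] = DataFrame::create(
      _["position"] = NumericVector(e.snap_pos[i].begin(), e.snap_pos[i].end()),
      _["direction"] = IntegerVector(e.snap_dir[i].begin(), e.snap_dir[i].end()),
      _["class_index"] = IntegerVector(e.snap_cls[i].begin(), e.snap_cls[i].end())
    );
  }

  return List::create(
    _["firings"] = DataFrame::create(
      _["position"] = fpos, _["time"] = ftime, _["mode"] = fmode,
      _["class_index"] = fcls, _["chrom_index"] = fchrom,
      _["left_end"] = flend, _["right_end"] = frend),
    _["time_series"] = ts,
    _["snapshots"] = snaps,
    _["completion_time"] = e.completion_time,
    _["complete"] = e.complete,
    _["replicated_by_class"] = NumericVector::create(
      e.repl_by_class[0], e.repl_by_class[1], e.repl_by_class[2]),
    _["n_events"] = (double)e.n_events,
    _["n_offers"] = (double)e.n_offers
  );
}
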