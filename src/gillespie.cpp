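// Exact stochastic simulation (Gillespie algorithm) of the sex-structured
// host birth-death process with vertical symbiont transmission.
//
// The population is stored as a class table over (sex, modifier allele,
// carriage bitmask); individuals within a class are exchangeable. The event
// set is: birth (total rate b0 * n_females while at least one male is
// present; mother uniform among females, father uniform among males, newborn
// sex 1:1, carriage by the per-taxon transmission rule, sons inherit the
// father's Y allele), death (per class, count * (d0 + dprime * n) / w_eff),
// and horizontal uptake of the focal taxon (rate e0 per non-carrier).
//
// The draw sequence per step is fixed and mirrored line-for-line by the pure
// R reference engine in R/engine-r.R: u1 waiting time, u2 event selection
// against the cumulative rate vector (birth, deaths in class-table order,
// uptake), then event-specific draws (mother, father, offspring sex; or the
// uptaking class). Both engines consume the same R RNG stream, so identical
// seeds give identical trajectories; tests rely on this.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int ALLELE_MMINUS = 1;
const int ALLELE_MPLUS = 2;

double mask_weff(int mask, const NumericVector& w) {
  if (mask == 0) return 1.0;
  long double s = 0.0L;
  int k = 0;
  for (int i = 0; i < w.size(); ++i)
    if ((mask >> i) & 1) { s += w[i]; ++k; }
  return (double)(s / k);
}

} // namespace

// [[Rcpp::export]]
List sim_gillespie_cpp(IntegerVector sex0, IntegerVector allele0,
                       IntegerVector mask0, IntegerVector count0,
                       NumericVector w_list,
                       double b0, double d0, double dprime, double e0,
                       double t_max, double record_dt,
                       int term_mode, bool record_taxa,
                       double max_events) {
  const int n_taxa = w_list.size();
  std::vector<int> sex(sex0.begin(), sex0.end());
  std::vector<int> allele(allele0.begin(), allele0.end());
  std::vector<int> mask(mask0.begin(), mask0.end());
  std::vector<long> count(count0.begin(), count0.end());
  std::vector<double> weff;
  weff.reserve(sex.size() + 64);
  for (size_t i = 0; i < mask.size(); ++i) weff.push_back(mask_weff(mask[i], w_list));

  const int ncol = 8 + (record_taxa ? n_taxa : 0);
  const int nrcap = (int)std::floor(t_max / record_dt) + 3;
  NumericMatrix traj(nrcap, ncol);
  int irec = 0;

  auto record = [&](double tt) {
    if (irec >= nrcap) return;
    long n = 0, nF = 0, nplus = 0;
    long m[4] = {0, 0, 0, 0};
    for (size_t i = 0; i < count.size(); ++i) {
      if (count[i] <= 0) continue;
      n += count[i];
      bool car = mask[i] & 1;
      if (sex[i] == 0) nF += count[i];
      else {
        int j = (allele[i] == ALLELE_MMINUS ? 0 : 2) + (car ? 1 : 0);
        m[j] += count[i];
      }
      if (car) nplus += count[i];
    }
    traj(irec, 0) = tt;
    traj(irec, 1) = (double)n;
    traj(irec, 2) = (double)nF;
    traj(irec, 3) = (double)nplus;
    for (int j = 0; j < 4; ++j) traj(irec, 4 + j) = (double)m[j];
    if (record_taxa) {
      for (int k = 0; k < n_taxa; ++k) {
        long ck = 0;
        for (size_t i = 0; i < count.size(); ++i)
          if (count[i] > 0 && ((mask[i] >> k) & 1)) ck += count[i];
        traj(irec, 8 + k) = (double)ck;
      }
    }
    ++irec;
  };

  // 0 = running, 1 = loss, 2 = fixation, 3 = host extinction, 4 = timeout
  auto term_check = [&]() -> int {
    long n = 0, nplus = 0;
    int first_mask = -1;
    bool mono = true;
    for (size_t i = 0; i < count.size(); ++i) {
      if (count[i] <= 0) continue;
      n += count[i];
      if (mask[i] & 1) nplus += count[i];
      if (first_mask < 0) first_mask = mask[i];
      else if (mask[i] != first_mask) mono = false;
    }
    if (n == 0) return 3;
    if (term_mode == 2) return 0;
    if (term_mode == 1) {
      if (mono) return first_mask == 0 ? 1 : 2;
      return 0;
    }
    if (nplus == n) return 2;
    if (nplus == 0 && e0 == 0) return 1;
    return 0;
  };

  auto find_or_add = [&](int s, int a, int m) -> int {
    for (size_t i = 0; i < sex.size(); ++i)
      if (sex[i] == s && allele[i] == a && mask[i] == m) return (int)i;
    sex.push_back(s);
    allele.push_back(a);
    mask.push_back(m);
    count.push_back(0);
    weff.push_back(mask_weff(m, w_list));
    return (int)sex.size() - 1;
  };

  double t = 0.0, t_end = 0.0;
  long k = 1; // next recording index: records at k * record_dt
  double events = 0.0;
  std::vector<double> Dc;
  int outcome = term_check();
  record(0.0);

  while (outcome == 0) {
    // --- rates ---
    long n = 0, nF = 0, nM = 0, nnoncar = 0;
    for (size_t i = 0; i < count.size(); ++i) {
      if (count[i] <= 0) continue;
      n += count[i];
      if (sex[i] == 0) nF += count[i]; else nM += count[i];
      if (!(mask[i] & 1)) nnoncar += count[i];
    }
    double B = (nM > 0) ? b0 * (double)nF : 0.0;
    double dpc = d0 + dprime * (double)n;
    Dc.assign(count.size(), 0.0);
    long double sd = 0.0L;
    for (size_t i = 0; i < count.size(); ++i) {
      Dc[i] = (double)count[i] * dpc / weff[i];
      sd += Dc[i];
    }
    double sumD = (double)sd;
    double U = e0 * (double)nnoncar;
    double Rtot = B + sumD + U;
    if (!(Rtot > 0.0)) { outcome = 4; t_end = t; break; }

    // --- waiting time and trajectory recording ---
    double u1 = unif_rand();
    double tnew = t - std::log(u1) / Rtot;
    double tstop = tnew < t_max ? tnew : t_max;
    while ((double)k * record_dt <= tstop) {
      record((double)k * record_dt);
      ++k;
    }
    if (tnew >= t_max) {
      outcome = 4;
      t_end = t_max;
      if (irec == 0 || traj(irec - 1, 0) < t_max) record(t_max);
      break;
    }
    t = tnew;

    // --- event selection ---
    double u2 = unif_rand();
    double r = u2 * Rtot;
    if (r < B) {
      // birth
      double rm = unif_rand() * (double)nF;
      int mi = -1;
      for (size_t i = 0; i < count.size(); ++i) {
        if (sex[i] != 0 || count[i] <= 0) continue;
        if (rm < (double)count[i]) { mi = (int)i; break; }
        rm -= (double)count[i];
      }
      if (mi < 0)
        for (int i = (int)count.size() - 1; i >= 0; --i)
          if (sex[i] == 0 && count[i] > 0) { mi = i; break; }
      double rf = unif_rand() * (double)nM;
      int fi = -1;
      for (size_t i = 0; i < count.size(); ++i) {
        if (sex[i] != 1 || count[i] <= 0) continue;
        if (rf < (double)count[i]) { fi = (int)i; break; }
        rf -= (double)count[i];
      }
      if (fi < 0)
        for (int i = (int)count.size() - 1; i >= 0; --i)
          if (sex[i] == 1 && count[i] > 0) { fi = i; break; }
      int csex = (unif_rand() < 0.5) ? 0 : 1;
      int cmask = mask[mi] | (allele[fi] == ALLELE_MPLUS ? mask[fi] : 0);
      int callele = (csex == 1) ? allele[fi] : 0;
      int idx = find_or_add(csex, callele, cmask);
      ++count[idx];
    } else {
      r -= B;
      int di = -1;
      for (size_t i = 0; i < count.size(); ++i) {
        if (r < Dc[i]) { di = (int)i; break; }
        r -= Dc[i];
      }
      if (di >= 0) {
        --count[di];
      } else if (U > 0.0 && nnoncar > 0) {
        // horizontal uptake of the focal taxon by a uniform non-carrier
        double ru = unif_rand() * (double)nnoncar;
        int ui = -1;
        for (size_t i = 0; i < count.size(); ++i) {
          if ((mask[i] & 1) || count[i] <= 0) continue;
          if (ru < (double)count[i]) { ui = (int)i; break; }
          ru -= (double)count[i];
        }
        if (ui < 0)
          for (int i = (int)count.size() - 1; i >= 0; --i)
            if (!(mask[i] & 1) && count[i] > 0) { ui = i; break; }
        --count[ui];
        int idx = find_or_add(sex[ui], allele[ui], mask[ui] | 1);
        ++count[idx];
      } else {
        // floating fall-through: treat as death of the last occupied class
        for (int i = (int)count.size() - 1; i >= 0; --i)
          if (count[i] > 0) { --count[i]; break; }
      }
    }

    events += 1.0;
    if (events >= max_events) { outcome = 4; t_end = t; break; }
    outcome = term_check();
    if (outcome != 0) {
      t_end = t;
      if (irec == 0 || traj(irec - 1, 0) < t) record(t);
      break;
    }
  }
  if (outcome != 4 && events == 0.0) t_end = 0.0; // terminated at t = 0

  NumericMatrix out(irec, ncol);
  for (int i = 0; i < irec; ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = traj(i, j);

  return List::create(
    _["outcome"] = outcome,
    _["t_end"] = t_end,
    _["trajectory"] = out,
    _["sex"] = IntegerVector(sex.begin(), sex.end()),
    _["allele"] = IntegerVector(allele.begin(), allele.end()),
    _["mask"] = IntegerVector(mask.begin(), mask.end()),
    _["count"] = IntegerVector(count.begin(), count.end()),
    _["events"] = events);
}
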