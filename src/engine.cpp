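// Core update kernel for the on-lattice tumour model.
//
// State per lesion: per-site counts of sensitive (S) and resistant (R) cells
// on an L x L grid with per-site carrying capacity K (1 or 2), plus a static
// CAF mask. One simulated day processes every cell alive at the day's start
// exactly once, in a freshly shuffled order; daughters born today are not
// processed until tomorrow and dead cells vacate their slot immediately.
//
// Each lesion owns an independent mt19937_64 stream seeded from R, so
// seed-paired treatment arms and multi-lesion runs are bit-reproducible and
// per-lesion trajectories are independent of how many lesions run together.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lesion {
  int L = 0, K = 1;
  std::vector<int> nS, nR;   // per-site occupant counts, length L*L
  std::vector<char> caf;     // static fibroblast mask
  double rS = 0, rR = 0, dT = 0, deltaD = 0, m = 0, alpha = 1;
  std::mt19937_64 rng;
  std::vector<int> csite;    // alive cells: site index (column-major, 0-based)
  std::vector<char> ckind;   // 1 = S, 2 = R, 0 = dead (compacted daily)
  // per-day tallies
  long bS = 0, bR = 0, dnat = 0, ddrug = 0, mig = 0, blocked = 0;

  double u() { return (rng() >> 11) * 0x1.0p-53; }
  int ri(int n) {            // uniform integer in [0, n)
    int r = (int)(u() * n);
    return r < n ? r : n - 1;
  }
  int occ(int s) const { return nS[s] + nR[s]; }
  long S() const { long t = 0; for (int v : nS) t += v; return t; }
  long R() const { long t = 0; for (int v : nR) t += v; return t; }

  void build_cells() {
    csite.clear(); ckind.clear();
    for (int s = 0; s < L * L; ++s) {
      for (int c = 0; c < nS[s]; ++c) { csite.push_back(s); ckind.push_back(1); }
      for (int c = 0; c < nR[s]; ++c) { csite.push_back(s); ckind.push_back(2); }
    }
  }

  // von Neumann neighbours of site s; site index is (x-1)*L + (y-1)
  inline int neighbours(int s, int *nb) const {
    int y = s % L, x = s / L, n = 0;
    if (x > 0)     nb[n++] = s - L;  // west
    if (x < L - 1) nb[n++] = s + L;  // east
    if (y > 0)     nb[n++] = s - 1;  // north
    if (y < L - 1) nb[n++] = s + 1;  // south
    return n;
  }
};

void remove_cell(Lesion &le, int i) {
  int s = le.csite[i];
  if (le.ckind[i] == 1) le.nS[s]--; else le.nR[s]--;
  le.ckind[i] = 0;
}

// one simulated day for one lesion under a fixed dose
void step_day(Lesion &le, int dose, bool drug_after_space) {
  le.bS = le.bR = le.dnat = le.ddrug = le.mig = le.blocked = 0;
  const int n0 = (int)le.csite.size();
  std::vector<int> perm(n0);
  for (int i = 0; i < n0; ++i) perm[i] = i;
  for (int i = n0 - 1; i > 0; --i) {       // Fisher-Yates shuffle
    int j = le.ri(i + 1);
    std::swap(perm[i], perm[j]);
  }
  int nb[4], fsite[5], fcap[5];
  for (int pi = 0; pi < n0; ++pi) {
    const int i = perm[pi];
    const char k = le.ckind[i];
    if (!k) continue;
    const int s = le.csite[i];
    double rj = (k == 1) ? le.rS : le.rR;
    if (le.caf[s]) rj *= le.alpha;
    const int nn = le.neighbours(s, nb);

    if (le.m > 0 && le.u() < le.m) {       // migration attempt ends the turn
      int nf = 0;
      for (int q = 0; q < nn; ++q)
        if (le.occ(nb[q]) < le.K) fsite[nf++] = nb[q];
      if (nf > 0) {
        int t = fsite[le.ri(nf)];
        if (k == 1) { le.nS[s]--; le.nS[t]++; } else { le.nR[s]--; le.nR[t]++; }
        le.csite[i] = t;
        le.mig++;
      }
      continue;
    }
    if (le.u() >= rj + le.dT) continue;    // no event: cell stays

    if (le.u() >= rj / (rj + le.dT)) {     // natural death
      remove_cell(le, i);
      le.dnat++;
      continue;
    }
    // division attempt
    const bool drug = (k == 1) && (dose > 0) && (le.deltaD > 0);
    if (!drug_after_space && drug && le.u() < le.deltaD * dose) {
      remove_cell(le, i);
      le.ddrug++;
      continue;
    }
    // free capacity: slots in the VNHD, plus the cell's own spare slot if K > 1
    int F = 0, nsl = 0;
    for (int q = 0; q < nn; ++q) {
      int c = le.K - le.occ(nb[q]);
      if (c > 0) { fsite[nsl] = nb[q]; fcap[nsl] = c; ++nsl; F += c; }
    }
    if (le.K > 1) {
      int c = le.K - le.occ(s);
      if (c > 0) { fsite[nsl] = s; fcap[nsl] = c; ++nsl; F += c; }
    }
    if (F == 0) { le.blocked++; continue; }
    if (drug_after_space && drug && le.u() < le.deltaD * dose) {
      remove_cell(le, i);
      le.ddrug++;
      continue;
    }
    int r = le.ri(F), t = fsite[0];
    for (int q = 0; q < nsl; ++q) { if (r < fcap[q]) { t = fsite[q]; break; } r -= fcap[q]; }
    if (k == 1) { le.nS[t]++; le.bS++; } else { le.nR[t]++; le.bR++; }
    le.csite.push_back(t);
    le.ckind.push_back(k);
  }
  // compact the cell list: drop cells that died today
  size_t w = 0;
  for (size_t i = 0; i < le.csite.size(); ++i) {
    if (le.ckind[i]) { le.csite[w] = le.csite[i]; le.ckind[w] = le.ckind[i]; ++w; }
  }
  le.csite.resize(w);
  le.ckind.resize(w);
}

// mean (N_E, N_S, N_R) over focal cells of each kind; 6 values:
// S-focal E,S,R then R-focal E,S,R; NaN when no focal cell of that kind
void nbhd_means(const Lesion &le, double *out) {
  double acc[2][3] = {{0, 0, 0}, {0, 0, 0}};
  long cnt[2] = {0, 0};
  int nb[4];
  for (int s = 0; s < le.L * le.L; ++s) {
    if (le.occ(s) == 0) continue;
    const int nn = le.neighbours(s, nb);
    int cS = 0, cR = 0, cE = 0;
    for (int q = 0; q < nn; ++q) {
      cS += le.nS[nb[q]]; cR += le.nR[nb[q]];
      cE += le.K - le.occ(nb[q]);
    }
    for (int kind = 1; kind <= 2; ++kind) {
      int nf = (kind == 1) ? le.nS[s] : le.nR[s];
      if (!nf) continue;
      // for K > 1 the focal cell also sees the other slot(s) of its own site
      int oS = cS, oR = cR, oE = cE;
      if (le.K > 1) {
        oS += le.nS[s] - (kind == 1 ? 1 : 0);
        oR += le.nR[s] - (kind == 2 ? 1 : 0);
        oE += le.K - le.occ(s);
      }
      acc[kind - 1][0] += (double)nf * oE;
      acc[kind - 1][1] += (double)nf * oS;
      acc[kind - 1][2] += (double)nf * oR;
      cnt[kind - 1] += nf;
    }
  }
  for (int kind = 0; kind < 2; ++kind)
    for (int j = 0; j < 3; ++j)
      out[kind * 3 + j] = cnt[kind] ? acc[kind][j] / cnt[kind] : NA_REAL;
}

IntegerMatrix snapshot_codes(const Lesion &le) {
  // 0 empty, 1 S only, 2 R only, 3 mixed S+R (possible when K = 2)
  IntegerMatrix out(le.L, le.L);
  for (int s = 0; s < le.L * le.L; ++s) {
    int code = 0;
    if (le.nS[s] > 0 && le.nR[s] > 0) code = 3;
    else if (le.nS[s] > 0) code = 1;
    else if (le.nR[s] > 0) code = 2;
    out[s] = code;
  }
  return out;
}

Lesion lesion_from_list(const List &spec) {
  Lesion le;
  IntegerMatrix nS = spec["nS"], nR = spec["nR"];
  LogicalMatrix caf = spec["caf"];
  le.L = nS.nrow();
  if (nS.ncol() != le.L) stop("lattice must be square");
  le.K = as<int>(spec["K"]);
  le.nS.assign(nS.begin(), nS.end());
  le.nR.assign(nR.begin(), nR.end());
  le.caf.resize(le.L * le.L);
  for (int s = 0; s < le.L * le.L; ++s) {
    le.caf[s] = caf[s] ? 1 : 0;
    if (le.nS[s] < 0 || le.nR[s] < 0 || le.nS[s] + le.nR[s] > le.K)
      stop("site occupancy outside [0, K]");
  }
  le.rS = as<double>(spec["r_S"]);   le.rR = as<double>(spec["r_R"]);
  le.dT = as<double>(spec["d_T"]);   le.deltaD = as<double>(spec["delta_D"]);
  le.m = as<double>(spec["m"]);      le.alpha = as<double>(spec["alpha"]);
  le.rng.seed((uint64_t)as<double>(spec["seed"]));
  le.build_cells();
  return le;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".abm_run")]]
List abm_run(List lesions, double rho, double n0_ref, int strategy,
             double const_dose, int days, bool drug_check_after_space,
             bool record_nbhd, IntegerVector snapshot_days) {
  const int nles = lesions.size();
  if (nles < 1) stop("need at least one lesion");
  if (days < 0) stop("days must be >= 0");
  if (strategy != 0 && strategy != 1) stop("unknown strategy code");
  if (strategy == 0 && const_dose != 0 && const_dose != 1)
    stop("dose must be 0 or 1");

  std::vector<Lesion> les;
  les.reserve(nles);
  for (int l = 0; l < nles; ++l) les.push_back(lesion_from_list(lesions[l]));

  std::vector<NumericMatrix> ts;      // (days+1) x 3 : S, R, N
  std::vector<NumericMatrix> tal;     // days x 6
  std::vector<NumericMatrix> nbh;     // (days+1) x 6
  for (int l = 0; l < nles; ++l) {
    ts.emplace_back(days + 1, 3);
    tal.emplace_back(days, 6);
    nbh.emplace_back(record_nbhd ? days + 1 : 0, 6);
  }
  NumericVector dose_applied(days);

  std::vector<bool> want_snap(days + 1, false);
  for (int i = 0; i < snapshot_days.size(); ++i) {
    int d = snapshot_days[i];
    if (d < 0 || d > days) stop("snapshot day outside [0, days]");
    want_snap[d] = true;
  }
  List snaps;

  auto record = [&](int d) {
    for (int l = 0; l < nles; ++l) {
      long S = les[l].S(), R = les[l].R();
      ts[l](d, 0) = (double)S; ts[l](d, 1) = (double)R; ts[l](d, 2) = (double)(S + R);
      if (record_nbhd) {
        double v[6];
        nbhd_means(les[l], v);
        for (int j = 0; j < 6; ++j) nbh[l](d, j) = v[j];
      }
    }
    if (want_snap[d]) {
      List per(nles);
      for (int l = 0; l < nles; ++l) per[l] = snapshot_codes(les[l]);
      snaps.push_back(per, std::string("day") + std::to_string(d));
    }
  };

  record(0);
  int phase = 1; // AT controller starts in the "on" phase
  for (int d = 0; d < days; ++d) {
    double Ntot = 0;
    for (int l = 0; l < nles; ++l) Ntot += ts[l](d, 2);
    int dose;
    if (strategy == 0) {
      dose = (int)const_dose;
    } else {
      if (phase == 1 && Ntot < rho * n0_ref) phase = 0;
      else if (phase == 0 && Ntot >= n0_ref) phase = 1;
      dose = phase;
    }
    dose_applied[d] = dose;
    for (int l = 0; l < nles; ++l) {
      step_day(les[l], dose, drug_check_after_space);
      tal[l](d, 0) = (double)les[l].bS;
      tal[l](d, 1) = (double)les[l].bR;
      tal[l](d, 2) = (double)les[l].dnat;
      tal[l](d, 3) = (double)les[l].ddrug;
      tal[l](d, 4) = (double)les[l].mig;
      tal[l](d, 5) = (double)les[l].blocked;
    }
    record(d + 1);
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List lts(nles), ltal(nles), lnbh(nles), lgrid(nles);
  for (int l = 0; l < nles; ++l) {
    colnames(ts[l]) = CharacterVector::create("S", "R", "N");
    colnames(tal[l]) = CharacterVector::create(
        "births_S", "births_R", "deaths_natural", "deaths_drug",
        "migrations", "blocked_divisions");
    lts[l] = ts[l];
    ltal[l] = tal[l];
    if (record_nbhd) {
      colnames(nbh[l]) = CharacterVector::create(
          "S_NE", "S_NS", "S_NR", "R_NE", "R_NS", "R_NR");
      lnbh[l] = nbh[l];
    }
    IntegerMatrix gS(les[l].L, les[l].L), gR(les[l].L, les[l].L);
    for (int s = 0; s < les[l].L * les[l].L; ++s) { gS[s] = les[l].nS[s]; gR[s] = les[l].nR[s]; }
    lgrid[l] = List::create(_["nS"] = gS, _["nR"] = gR);
  }
  return List::create(
      _["ts"] = lts, _["dose"] = dose_applied, _["tallies"] = ltal,
      _["nbhd"] = lnbh, _["grids"] = lgrid, _["snapshots"] = snaps);
}

//' @noRd
// [[Rcpp::export(name = ".abm_step_replicates")]]
IntegerMatrix abm_step_replicates(List lesion, double dose, int n,
                                  bool drug_check_after_space, double seed) {
  // n independent one-day steps from the same initial state; each row is the
  // flattened (nS, nR) final state. Used by exact-enumeration oracle tests.
  Lesion proto = lesion_from_list(lesion);
  const int m = proto.L * proto.L;
  IntegerMatrix out(n, 2 * m);
  std::mt19937_64 master((uint64_t)seed);
  for (int rep = 0; rep < n; ++rep) {
    Lesion le = proto;
    le.rng.seed(master());
    step_day(le, (int)dose, drug_check_after_space);
    for (int s = 0; s < m; ++s) { out(rep, s) = le.nS[s]; out(rep, m + s) = le.nR[s]; }
    if (rep % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
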