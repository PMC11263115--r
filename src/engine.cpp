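// Core generational engine: meiosis with Poisson crossovers, infinite-sites
// deleterious mutation, selfing/outcrossing reproduction, fitness-weighted
// viability resampling, and the per-generation selfed/outcrossed offspring
// assay. All randomness comes from R's RNG so set.seed() governs everything.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  int N;
  double U, s, h, L;
  int n_z;
  double U_z, k, z_c, lambda;
};

struct Hap {
  std::vector<int> tr;      // trait alleles, each -1 (A) or +1 (a)
  std::vector<double> pos;  // sorted unique deleterious-mutation positions
};

struct Ind {
  Hap h1, h2;
  double z, alpha;
  int nhet, nhom;
  double w1, w2, w;
};

Params as_params(const List& p) {
  Params pm;
  pm.N = as<int>(p["N"]);
  pm.U = as<double>(p["U"]);
  pm.s = as<double>(p["s"]);
  pm.h = as<double>(p["h"]);
  pm.L = as<double>(p["L"]);
  pm.n_z = as<int>(p["n_z"]);
  pm.U_z = as<double>(p["U_z"]);
  pm.k = as<double>(p["k"]);
  pm.z_c = as<double>(p["z_c"]);
  pm.lambda = as<double>(p["lambda"]);
  return pm;
}

int runif_index(int n) {
  int i = static_cast<int>(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

double phenotype(const Hap& a, const Hap& b, int n_z) {
  long sum = 0;
  for (int t : a.tr) sum += t;
  for (int t : b.tr) sum += t;
  return static_cast<double>(sum) / n_z;
}

void zygosity(const std::vector<double>& p1, const std::vector<double>& p2,
              int& nhet, int& nhom) {
  std::size_t i = 0, j = 0;
  nhom = 0;
  while (i < p1.size() && j < p2.size()) {
    if (p1[i] == p2[j]) {
      ++nhom; ++i; ++j;
    } else if (p1[i] < p2[j]) {
      ++i;
    } else {
      ++j;
    }
  }
  nhet = static_cast<int>(p1.size() + p2.size()) - 2 * nhom;
}

bool is_trait_pos(double x, int n_z) {
  double v = x * n_z;
  return v == std::floor(v);
}

void derive(Ind& d, const Params& pm) {
  d.z = phenotype(d.h1, d.h2, pm.n_z);
  d.alpha = 1.0 / (1.0 + std::exp(-pm.k * (d.z - pm.z_c)));
  zygosity(d.h1.pos, d.h2.pos, d.nhet, d.nhom);
  d.w1 = std::exp(-pm.lambda * d.z * d.z);
  d.w2 = std::pow(1.0 - pm.h * pm.s, d.nhet) * std::pow(1.0 - pm.s, d.nhom);
  d.w = d.w1 * d.w2;
}

// One meiosis: Poisson(L) crossovers at U(0,1) breakpoints, a fair coin for
// the starting chromosome, then Poisson(U/2) new deleterious positions and
// Poisson(U_z/2) trait-allele flips. Returns the crossover count drawn.
int gamete(const Ind& p, const Params& pm, Hap& g) {
  int nco = static_cast<int>(R::rpois(pm.L));
  std::vector<double> br(nco);
  for (int c = 0; c < nco; ++c) br[c] = unif_rand();
  std::sort(br.begin(), br.end());
  bool start1 = unif_rand() < 0.5;

  g.tr.resize(pm.n_z);
  {
    std::size_t b = 0;
    for (int j = 0; j < pm.n_z; ++j) {
      double x = static_cast<double>(j) / pm.n_z;
      while (b < br.size() && br[b] <= x) ++b;
      bool from1 = ((b % 2) == 0) == start1;
      g.tr[j] = from1 ? p.h1.tr[j] : p.h2.tr[j];
    }
  }

  std::vector<double> keep1, keep2;
  auto take = [&](const std::vector<double>& v, bool want_h1,
                  std::vector<double>& out) {
    std::size_t b = 0;
    for (double x : v) {
      while (b < br.size() && br[b] <= x) ++b;
      bool from1 = ((b % 2) == 0) == start1;
      if (from1 == want_h1) out.push_back(x);
    }
  };
  take(p.h1.pos, true, keep1);
  take(p.h2.pos, false, keep2);
  g.pos.clear();
  g.pos.reserve(keep1.size() + keep2.size() + 4);
  std::merge(keep1.begin(), keep1.end(), keep2.begin(), keep2.end(),
             std::back_inserter(g.pos));

  int nm = static_cast<int>(R::rpois(pm.U / 2.0));
  for (int m = 0; m < nm; ++m) {
    double x;
    do {
      x = unif_rand();
    } while (is_trait_pos(x, pm.n_z) ||
             std::binary_search(g.pos.begin(), g.pos.end(), x));
    g.pos.insert(std::upper_bound(g.pos.begin(), g.pos.end(), x), x);
  }

  int nt = static_cast<int>(R::rpois(pm.U_z / 2.0));
  for (int m = 0; m < nt; ++m) {
    int loc = runif_index(pm.n_z);
    g.tr[loc] = -g.tr[loc];
  }
  return nco;
}

Ind offspring(const std::vector<Ind>& adults, const Params& pm) {
  int n = static_cast<int>(adults.size());
  int i = runif_index(n);
  double eps = unif_rand();
  bool selfed = eps < adults[i].alpha;
  Ind o;
  gamete(adults[i], pm, o.h1);
  if (selfed) {
    gamete(adults[i], pm, o.h2);
  } else {
    int j;
    do { j = runif_index(n); } while (j == i);
    gamete(adults[j], pm, o.h2);
  }
  derive(o, pm);
  return o;
}

bool select_adults(const std::vector<Ind>& juv, int N,
                   std::vector<Ind>& adults) {
  std::size_t n = juv.size();
  std::vector<double> cum(n);
  double tot = 0.0;
  for (std::size_t i = 0; i < n; ++i) {
    tot += juv[i].w;
    cum[i] = tot;
  }
  if (tot <= 0.0) return false;
  adults.clear();
  adults.reserve(N);
  for (int k = 0; k < N; ++k) {
    double u = unif_rand() * tot;
    std::size_t idx =
        std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (idx >= n) idx = n - 1;
    adults.push_back(juv[idx]);
  }
  return true;
}

// Per-adult assay: one selfed and one outcrossed offspring, w2 recorded.
void run_assay(const std::vector<Ind>& adults, const Params& pm,
               std::vector<double>& a, std::vector<double>& ws,
               std::vector<double>& wo) {
  int n = static_cast<int>(adults.size());
  a.resize(n); ws.resize(n); wo.resize(n);
  for (int i = 0; i < n; ++i) {
    Ind so, oo;
    gamete(adults[i], pm, so.h1);
    gamete(adults[i], pm, so.h2);
    derive(so, pm);
    gamete(adults[i], pm, oo.h1);
    int j;
    do { j = runif_index(n); } while (j == i);
    gamete(adults[j], pm, oo.h2);
    derive(oo, pm);
    a[i] = adults[i].alpha;
    ws[i] = so.w2;
    wo[i] = oo.w2;
  }
}

double vmean(const std::vector<double>& x) {
  double s = 0.0;
  for (double v : x) s += v;
  return s / x.size();
}

double vcov_pop(const std::vector<double>& x, const std::vector<double>& y) {
  double mx = vmean(x), my = vmean(y), s = 0.0;
  for (std::size_t i = 0; i < x.size(); ++i) s += (x[i] - mx) * (y[i] - my);
  return s / x.size();
}

double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  if (x.size() < 3) return NA_REAL;
  double vx = vcov_pop(x, x), vy = vcov_pop(y, y);
  if (vx <= 0.0 || vy <= 0.0) return NA_REAL;
  return vcov_pop(x, y) / std::sqrt(vx * vy);
}

double ols_slope(const std::vector<double>& x, const std::vector<double>& y) {
  if (x.size() < 2) return NA_REAL;
  double vx = vcov_pop(x, x);
  if (vx <= 0.0) return NA_REAL;
  return vcov_pop(x, y) / vx;
}

Ind ind_from_R(const List& il, const Params& pm) {
  Ind d;
  List h1 = il["hap1"], h2 = il["hap2"];
  IntegerVector t1 = h1["traits"], t2 = h2["traits"];
  NumericVector p1 = h1["pos"], p2 = h2["pos"];
  d.h1.tr.assign(t1.begin(), t1.end());
  d.h2.tr.assign(t2.begin(), t2.end());
  d.h1.pos.assign(p1.begin(), p1.end());
  d.h2.pos.assign(p2.begin(), p2.end());
  derive(d, pm);
  return d;
}

List hap_to_R(const Hap& h) {
  List out = List::create(_["traits"] = IntegerVector(h.tr.begin(), h.tr.end()),
                          _["pos"] = NumericVector(h.pos.begin(), h.pos.end()));
  out.attr("class") = "haplotype";
  return out;
}

List ind_to_R(const Ind& d) {
  List out = List::create(
      _["hap1"] = hap_to_R(d.h1), _["hap2"] = hap_to_R(d.h2), _["z"] = d.z,
      _["alpha"] = d.alpha, _["n_het"] = d.nhet, _["n_hom"] = d.nhom,
      _["homozygosity"] = (d.nhet + d.nhom) > 0
          ? static_cast<double>(d.nhom) / (d.nhom + d.nhet) : 0.0,
      _["w1"] = d.w1, _["w2"] = d.w2, _["w"] = d.w);
  out.attr("class") = "individual";
  return out;
}

std::vector<Ind> pop_from_R(const List& pop, const Params& pm) {
  List inds = pop["individuals"];
  std::vector<Ind> out;
  out.reserve(inds.size());
  for (int i = 0; i < inds.size(); ++i)
    out.push_back(ind_from_R(inds[i], pm));
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_gamete")]]
List cpp_gamete(IntegerVector tr1, NumericVector pos1, IntegerVector tr2,
                NumericVector pos2, List params) {
  Params pm = as_params(params);
  Ind p;
  p.h1.tr.assign(tr1.begin(), tr1.end());
  p.h2.tr.assign(tr2.begin(), tr2.end());
  p.h1.pos.assign(pos1.begin(), pos1.end());
  p.h2.pos.assign(pos2.begin(), pos2.end());
  Hap g;
  int nco = gamete(p, pm, g);
  List out = hap_to_R(g);
  out.attr("n_crossovers") = nco;
  return out;
}

// [[Rcpp::export(name = ".cpp_family_assay")]]
DataFrame cpp_family_assay(List pop, List params) {
  Params pm = as_params(params);
  std::vector<Ind> adults = pop_from_R(pop, pm);
  std::vector<double> a, ws, wo;
  run_assay(adults, pm, a, ws, wo);
  return DataFrame::create(_["alpha"] = a, _["w_self"] = ws, _["w_out"] = wo);
}

// [[Rcpp::export(name = ".cpp_run_sim")]]
List cpp_run_sim(List pop, List params, int generations, int record_every,
                 int assay_every) {
  Params pm = as_params(params);
  std::vector<Ind> adults = pop_from_R(pop, pm);
  int gen0 = as<int>(pop["generation"]);

  int nrec = generations / record_every;
  std::vector<double> c_gen, c_abar, c_valpha, c_mut, c_nhet, c_nhom, c_homo,
      c_delta0, c_r_nmut, c_r_wout, c_r_wself, c_r_fid, c_sl_wself, c_sl_wout;
  c_gen.reserve(nrec);

  int extinct_at = -1;
  std::vector<Ind> juv;
  juv.reserve(pm.N);

  for (int gen = 1; gen <= generations; ++gen) {
    juv.clear();
    for (int i = 0; i < pm.N; ++i) juv.push_back(offspring(adults, pm));
    if (!select_adults(juv, pm.N, adults)) {
      extinct_at = gen0 + gen;
      break;
    }

    if (gen % record_every != 0) continue;

    int n = static_cast<int>(adults.size());
    std::vector<double> av(n), nmut(n), nhet(n), nhom(n), homo(n);
    for (int i = 0; i < n; ++i) {
      av[i] = adults[i].alpha;
      nhet[i] = adults[i].nhet;
      nhom[i] = adults[i].nhom;
      nmut[i] = adults[i].nhet + 2.0 * adults[i].nhom;
      int tot = adults[i].nhet + adults[i].nhom;
      homo[i] = tot > 0 ? adults[i].nhom / static_cast<double>(tot) : 0.0;
    }
    c_gen.push_back(gen0 + gen);
    c_abar.push_back(vmean(av));
    c_valpha.push_back(vcov_pop(av, av));
    c_mut.push_back(vmean(nmut));
    c_nhet.push_back(vmean(nhet));
    c_nhom.push_back(vmean(nhom));
    c_homo.push_back(vmean(homo));

    if (gen % assay_every == 0) {
      std::vector<double> aa, ws, wo;
      run_assay(adults, pm, aa, ws, wo);
      double mwo = vmean(wo);
      c_delta0.push_back(mwo > 0.0 ? 1.0 - vmean(ws) / mwo : NA_REAL);
      c_r_nmut.push_back(pearson(av, nmut));
      c_r_wout.push_back(pearson(aa, wo));
      c_r_wself.push_back(pearson(aa, ws));
      std::vector<double> fa, fid;
      for (std::size_t i = 0; i < wo.size(); ++i) {
        if (wo[i] > 0.0) {
          fa.push_back(aa[i]);
          fid.push_back(1.0 - ws[i] / wo[i]);
        }
      }
      c_r_fid.push_back(pearson(fa, fid));
      c_sl_wself.push_back(ols_slope(aa, ws));
      c_sl_wout.push_back(ols_slope(aa, wo));
    } else {
      c_delta0.push_back(NA_REAL);
      c_r_nmut.push_back(pearson(av, nmut));
      c_r_wout.push_back(NA_REAL);
      c_r_wself.push_back(NA_REAL);
      c_r_fid.push_back(NA_REAL);
      c_sl_wself.push_back(NA_REAL);
      c_sl_wout.push_back(NA_REAL);
    }
  }

  DataFrame metrics = DataFrame::create(
      _["generation"] = c_gen, _["alpha_bar"] = c_abar,
      _["V_alpha"] = c_valpha, _["mean_mut_copies"] = c_mut,
      _["mean_n_het"] = c_nhet, _["mean_n_hom"] = c_nhom,
      _["mean_homozygosity"] = c_homo, _["delta0"] = c_delta0,
      _["corr_alpha_nmut"] = c_r_nmut, _["corr_alpha_wout"] = c_r_wout,
      _["corr_alpha_wself"] = c_r_wself, _["corr_alpha_famID"] = c_r_fid,
      _["slope_alpha_wself"] = c_sl_wself, _["slope_alpha_wout"] = c_sl_wout);

  List rinds(adults.size());
  for (std::size_t i = 0; i < adults.size(); ++i) rinds[i] = ind_to_R(adults[i]);
  List final_pop = List::create(
      _["individuals"] = rinds,
      _["generation"] = extinct_at >= 0 ? extinct_at : gen0 + generations);
  final_pop.attr("class") = "population";

  return List::create(_["metrics"] = metrics, _["final_population"] = final_pop,
                      _["extinct_at"] = extinct_at);
}
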