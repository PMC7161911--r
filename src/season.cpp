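// Daily season loop of the cassava simulator. Semantics mirror the R
// reference engine (simulate_season_reference) exactly; the test suite
// asserts agreement between the two.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".season_loop")]]
List season_loop(List forcing, NumericVector dtt_leaf_v, List par,
                 List opts) {
  // forcing (parameter-independent, precomputed in R)
  NumericVector rain = forcing["rain"], srad = forcing["srad"],
                et0 = forcing["et0"], dtt_node_v = forcing["dtt_node"],
                dtt_age_v = forcing["dtt_age"],
                ctt_node = forcing["ctt_node"], ctt_age = forcing["ctt_age"];
  NumericMatrix rw = forcing["rw"];
  NumericVector ll = forcing["ll"], dul = forcing["dul"],
                sat = forcing["sat"], dulll = forcing["dulll"];
  double Scn = forcing["Scn"], dr = forcing["dr"];
  int nw = forcing["nw"], nl = forcing["nl"];

  // genotype + species parameters
  double B01 = par["B01"], B12 = par["B12"], LAXS = par["LAXS"],
         SLAS = par["SLAS"], LLIFA = par["LLIFA"], LPEFR = par["LPEFR"],
         LNSLP = par["LNSLP"], NODWT = par["NODWT"], PARUE = par["PARUE"],
         KCAN = par["KCAN"];
  NumericVector brf = par["brf"];
  double r0 = par["r0"], h_app = par["h_app"], klog = par["klog"],
         mid0 = par["mid0"], midpl = par["midpl"], f0 = par["f0"],
         peak = par["peak"], decl = par["decl"], expdur = par["expdur"],
         fib = par["fib"], parf = par["parf"], germ_req = par["germ_req"],
         init_area = par["init_area"], stake_res = par["stake_reserve"];
  int max_branch = par["max_branch"];

  double density = opts["density"], s_sens = opts["s"], sg_sens = opts["s_g"];
  bool wl = opts["water_limited"], want_trace = opts["trace"];
  int nd = opts["season_days"];

  // state
  std::vector<double> wmm(dul.begin(), dul.end());   // field capacity
  bool germinated = false;
  double germ_tt = 0, crop_age = 0, branch_tt = 0;
  int branch_level = 0;
  double apex = density;
  NumericVector day_branch(max_branch, NA_REAL);
  double leafno = 0, lai = 0, max_lai = 0;
  double m_lam = 0, m_pet = 0, m_stem = 0, m_fib = 0, m_sto = 0,
         m_dead = 0, m_res = 0, init_mass = 0, supply_cum = 0;
  int nmax = nd + 10, n_coh = 0;
  std::vector<double> co_n(nmax), co_t0(nmax), co_ctt0(nmax),
      co_lf0(nmax), co_ca0(nmax), co_area(nmax), co_target(nmax);
  // cumulative leaf-development clock (depends on the genotype's TBLSZ)
  std::vector<double> ctt_lf(nw + 1, 0.0);
  for (int i = 0; i < nw; ++i) ctt_lf[i + 1] = ctt_lf[i] + dtt_leaf_v[i];
  std::vector<int> grow_set, live_set;
  grow_set.reserve(64);
  live_set.reserve(256);
  NumericMatrix tr = want_trace ? NumericMatrix(nd, 8) : NumericMatrix(0, 0);
  if (want_trace) std::fill(tr.begin(), tr.end(), NA_REAL);

  for (int i = 0; i < nw; ++i) {
    int day = i - 29;                      // days after planting
    // --- soil water balance (tipping bucket)
    double et = et0[i] * (0.15 + 0.85 * (1 - std::exp(-KCAN * lai)));
    double p = rain[i];
    double runoff = (p > 0.2 * Scn)
        ? (p - 0.2 * Scn) * (p - 0.2 * Scn) / (p + 0.8 * Scn) : 0.0;
    double inf = p - runoff;
    for (int l = 0; l < nl && inf > 0; ++l) {
      double add = std::min(inf, sat[l] - wmm[l]);
      wmm[l] += add;
      inf -= add;
    }
    for (int l = 0; l < nl; ++l) {
      double excess = wmm[l] - dul[l];
      if (excess > 0) {
        double flux = dr * excess;
        wmm[l] -= flux;
        if (l < nl - 1) {
          double take = std::min(flux, sat[l + 1] - wmm[l + 1]);
          wmm[l + 1] += take;
          wmm[l] += (flux - take);
        }
      }
    }
    if (et > 0) {
      double taken = 0;
      std::vector<double> take(nl), avail(nl);
      for (int l = 0; l < nl; ++l) {
        avail[l] = std::max(0.0, wmm[l] - ll[l]);
        take[l] = std::min(et * rw(i, l), avail[l]);
        taken += take[l];
      }
      double unmet = et - taken;
      if (unmet > 1e-12) {
        double sa = 0;
        for (int l = 0; l < nl; ++l) sa += avail[l] - take[l];
        if (sa > 0) {
          for (int l = 0; l < nl; ++l) {
            double a2 = avail[l] - take[l];
            take[l] += std::min(unmet * a2 / sa, a2);
          }
        }
      }
      for (int l = 0; l < nl; ++l) wmm[l] -= take[l];
    }
    if (day < 1) continue;

    double paw = 0;
    for (int l = 0; l < nl; ++l) paw += rw(i, l) * (wmm[l] - ll[l]) / dulll[l];
    double stress = wl ? std::min(1.0, std::max(0.0, paw / s_sens)) : 1.0;

    if (!germinated) {
      double sg = wl ? std::min(1.0, std::max(0.0, paw / sg_sens)) : 1.0;
      germ_tt += dtt_node_v[i] * sg;
      if (germ_tt >= germ_req) {
        germinated = true;
        n_coh = 1;
        co_n[0] = apex;
        co_area[0] = init_area;
        co_target[0] = LAXS * f0;
        co_t0[0] = mid0;
        co_ctt0[0] = ctt_node[i + 1];      // node clock starts next day
        co_lf0[0] = ctt_lf[i + 1];
        grow_set.push_back(0);
        leafno += apex;
        double lam = apex * init_area / SLAS;
        m_lam = lam;
        m_pet = lam * LPEFR / (1 - LPEFR);
        m_res = stake_res;
        init_mass = m_lam + m_pet + m_res;
        lai = apex * init_area / 1e4;
        if (lai > max_lai) max_lai = lai;
      }
      if (want_trace) {
        tr(day - 1, 0) = day; tr(day - 1, 1) = lai; tr(day - 1, 2) = stress;
        tr(day - 1, 3) = 0; tr(day - 1, 4) = 0; tr(day - 1, 5) = 0;
        tr(day - 1, 6) = 1; tr(day - 1, 7) = m_lam + m_pet + m_res;
      }
      continue;
    }

    double dtt_leaf = dtt_leaf_v[i], dtt_node = dtt_node_v[i];
    crop_age += dtt_leaf;
    branch_tt += dtt_node * stress;
    while (branch_level < max_branch &&
           branch_tt >= B01 + branch_level * B12) {
      apex *= brf[branch_level];
      day_branch[branch_level] = day;
      ++branch_level;
    }

    double n_new = apex * LNSLP * r0 / (1 + crop_age / h_app) *
                   dtt_leaf * stress;
    if (n_new > 0) {
      int k = n_coh++;
      co_n[k] = n_new;
      co_t0[k] = mid0 + midpl * (leafno / density);
      co_ctt0[k] = ctt_node[i];            // age 0 in today's demand
      co_lf0[k] = ctt_lf[i];
      co_target[k] = (crop_age <= peak)
          ? LAXS * (f0 + (1 - f0) * crop_age / peak)
          : LAXS * std::exp(-decl * (crop_age - peak));
      grow_set.push_back(k);
      leafno += n_new;
    }

    // leaves past their thermal expansion window stop growing and start
    // the LLIFA aging clock (whether or not carbon limited their area)
    for (size_t gi = 0; gi < grow_set.size();) {
      int k = grow_set[gi];
      if (ctt_lf[i] - co_lf0[k] >= expdur) {
        co_ca0[k] = ctt_age[i];
        live_set.push_back(k);
        grow_set.erase(grow_set.begin() + gi);
      } else {
        ++gi;
      }
    }
    // demands
    double lamina = 0;
    std::vector<double> pot_inc(grow_set.size());
    for (size_t gi = 0; gi < grow_set.size(); ++gi) {
      int k = grow_set[gi];
      double step = co_target[k] / expdur * dtt_leaf * stress;
      pot_inc[gi] = std::min(step, co_target[k] - co_area[k]);
      lamina += pot_inc[gi] * co_n[k];
    }
    lamina /= SLAS;
    double leaf_d = lamina / (1 - LPEFR);
    double stem_sum = 0;
    for (int k = 0; k < n_coh; ++k) {
      double e = std::exp(-klog * ((ctt_node[i] - co_ctt0[k]) - co_t0[k]));
      stem_sum += klog * NODWT * e / ((1 + e) * (1 + e)) * co_n[k];
    }
    double stem_d = stem_sum * dtt_node;
    double fib_d = fib * (leaf_d + stem_d);
    double total = leaf_d + stem_d + fib_d;

    double supply = parf * srad[i] * (1 - std::exp(-KCAN * lai)) *
                    PARUE * stress;
    // stake reserves cover early shortfall between demand and assimilation
    double draw = std::min(m_res, std::max(0.0, total - supply));
    m_res -= draw;
    double eff = supply + draw;
    double ratio;
    if (eff >= total) {
      ratio = 1;
      m_sto += eff - total;
    } else {
      ratio = (total > 0) ? eff / total : 1;
    }
    double dlai = 0;
    for (size_t gi = 0; gi < grow_set.size(); ++gi) {
      int k = grow_set[gi];
      double inc = pot_inc[gi] * ratio;
      co_area[k] += inc;
      dlai += inc * co_n[k];
    }
    lai += dlai / 1e4;
    m_lam += leaf_d * ratio * (1 - LPEFR);
    m_pet += leaf_d * ratio * LPEFR;
    m_stem += stem_d * ratio;
    m_fib += fib_d * ratio;
    supply_cum += supply;

    // senescence
    double dead_area = 0, dead_lam = 0;
    for (size_t li = 0; li < live_set.size();) {
      int k = live_set[li];
      if (ctt_age[i + 1] - co_ca0[k] > LLIFA) {
        dead_area += co_area[k] * co_n[k];
        live_set.erase(live_set.begin() + li);
      } else {
        ++li;
      }
    }
    if (dead_area > 0) {
      dead_lam = dead_area / SLAS;
      double dead_pet = dead_lam * LPEFR / (1 - LPEFR);
      lai = std::max(0.0, lai - dead_area / 1e4);
      m_lam -= dead_lam;
      m_pet -= dead_pet;
      m_dead += dead_lam + dead_pet;
    }
    if (lai > max_lai) max_lai = lai;
    if (want_trace) {
      tr(day - 1, 0) = day; tr(day - 1, 1) = lai; tr(day - 1, 2) = stress;
      tr(day - 1, 3) = supply; tr(day - 1, 4) = total;
      tr(day - 1, 5) = (eff >= total) ? eff - total : 0;
      tr(day - 1, 6) = ratio;
      tr(day - 1, 7) = m_lam + m_pet + m_stem + m_fib + m_sto + m_dead +
                       m_res;
    }
    if (!R_finite(lai) || !R_finite(m_lam + m_stem + m_sto))
      stop("non-finite crop state on day %d", day);
  }

  double total_mass = m_lam + m_pet + m_stem + m_fib + m_sto + m_dead +
                      m_res;
  List out = List::create(
      _["aboveground_biomass"] = 10 * (m_lam + m_pet + m_stem + m_dead),
      _["yield"] = 10 * m_sto,
      _["max_lai"] = max_lai,
      _["leaves_at_harvest"] = leafno / density,
      _["day_first_branch"] = day_branch[0],
      _["day_second_branch"] = day_branch[1],
      _["assimilation_total"] = supply_cum,
      _["balance_residual"] = (total_mass - init_mass) - supply_cum);
  if (want_trace) out["trace"] = tr;
  return out;
}
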