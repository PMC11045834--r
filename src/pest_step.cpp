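#include <Rcpp.h>
using namespace Rcpp;

static std::vector<double> &pest_scratch_d() {
  static std::vector<double> d;
  return d;
}

// [[Rcpp::export(name = ".free_pest_scratch")]]
void free_pest_scratch() {
  std::vector<double>().swap(pest_scratch_d());
}

// One day's pest-adult pass over the engine's preallocated individual
// buffers (first `n` slots are live).  In order:
//   1. remove adults whose death day has arrived, compacting the buffers
//      in place (creation order -- the protocol's id order -- preserved);
//   2. undirected movement: one truncated-exponential distance deviate per
//      survivor (id order), then one angle deviate per survivor, matching
//      runif(m) + runif(m) at the R level; components rounded half-even,
//      destinations clipped, boundary contacts counted.  Nothing is
//      consumed when d_max <= 0;
//   3. accumulate each laying female's expected eggs for the day (the
//      oviposition-rhythm table `ovi`, indexed by capped age) into the
//      dense per-cell capacity buffer `cap` (zeroed here; 0-based cell
//      index x + y * side).  No randomness: the Poisson egg draws happen
//      later in the day, after parasitism.
// The buffers are engine-private, so in-place mutation is safe.
// [[Rcpp::export(name = ".pest_day_cpp")]]
List pest_day_cpp(IntegerVector px, IntegerVector py, IntegerVector emerge,
                  IntegerVector death, LogicalVector female,
                  int n, int day, double beta, double d_max, int side,
                  int preovip, NumericVector ovi, NumericVector cap) {
  int m = 0, deaths = 0;
  for (int i = 0; i < n; ++i) {
    if (death[i] > day) {
      if (m != i) {
        px[m] = px[i]; py[m] = py[i];
        emerge[m] = emerge[i]; death[m] = death[i];
        female[m] = female[i];
      }
      ++m;
    } else {
      ++deaths;
    }
  }

  int contacts = 0;
  if (d_max > 0.0 && m > 0) {
    std::vector<double> &d = pest_scratch_d();   // reused across calls
    d.resize(m);
    double c1 = 1.0 - std::exp(-beta * d_max);
    for (int i = 0; i < m; ++i) {
      d[i] = -std::log(1.0 - unif_rand() * c1) / beta;
    }
    for (int i = 0; i < m; ++i) {
      double a = unif_rand() * 2.0 * M_PI;
      long xi = px[i] + (long) std::nearbyint(d[i] * std::cos(a));
      long yi = py[i] + (long) std::nearbyint(d[i] * std::sin(a));
      if (xi < 0 || xi >= side || yi < 0 || yi >= side) ++contacts;
      if (xi < 0) xi = 0; else if (xi >= side) xi = side - 1;
      if (yi < 0) yi = 0; else if (yi >= side) yi = side - 1;
      px[i] = (int) xi;
      py[i] = (int) yi;
    }
  }

  std::fill(cap.begin(), cap.end(), 0.0);
  int maxa = ovi.size() - 1;
  for (int i = 0; i < m; ++i) {
    if (female[i]) {
      int alpha = day - emerge[i] - preovip;
      if (alpha >= 0) {
        cap[px[i] + (R_xlen_t) py[i] * side] +=
          ovi[alpha > maxa ? maxa : alpha];
      }
    }
  }

  return List::create(_["n"] = m, _["deaths"] = deaths,
                      _["contacts"] = contacts);
}

// In-place append helpers for the engine's growable buffers (avoids the
// copy R makes when assigning into an environment-held vector).
// [[Rcpp::export(name = ".buf_fill_int")]]
void buf_fill_int(IntegerVector buf, int start, IntegerVector vals) {
  for (R_xlen_t i = 0; i < vals.size(); ++i) buf[start - 1 + i] = vals[i];
}

// [[Rcpp::export(name = ".buf_fill_lgl")]]
void buf_fill_lgl(LogicalVector buf, int start, LogicalVector vals) {
  for (R_xlen_t i = 0; i < vals.size(); ++i) buf[start - 1 + i] = vals[i];
}

// Allocate parasitized eggs across a cell's age classes, oldest class
// first, by sequential hypergeometric draws -- one call per (cell, class)
// pair with at least one egg, identical to the R-level protocol
// (stats::rhyper shares the stream of ::Rf_rhyper).  `cells` are 1-based
// cell indices in ascending order, `age_cols` the 1-based egg-matrix
// columns ordered oldest to youngest.  Updates the egg matrix and the
// per-cell total cache in place.
// [[Rcpp::export(name = ".remove_eggs_cpp")]]
void remove_eggs_cpp(IntegerMatrix egg_mat, IntegerVector egg_tot,
                     IntegerVector cells, IntegerVector taken,
                     IntegerVector age_cols) {
  int n_age = age_cols.size();
  int n_col = egg_mat.ncol();
  for (R_xlen_t ci = 0; ci < cells.size(); ++ci) {
    int cell = cells[ci] - 1;
    int need = taken[ci];
    long rem = 0;
    for (int t = 0; t < n_age; ++t) rem += egg_mat(cell, age_cols[t] - 1);
    for (int t = 0; t < n_age && need > 0; ++t) {
      int m_t = egg_mat(cell, age_cols[t] - 1);
      if (m_t == 0) continue;
      rem -= m_t;
      int take = (rem == 0) ? need
                            : (int) ::Rf_rhyper(m_t, (double) rem, need);
      if (take > 0) {
        egg_mat(cell, age_cols[t] - 1) = m_t - take;
        need -= take;
      }
    }
    long s = 0;
    for (int c2 = 0; c2 < n_col; ++c2) s += egg_mat(cell, c2);
    egg_tot[cell] = (int) s;
  }
}
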