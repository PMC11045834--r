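#include <Rcpp.h>
using namespace Rcpp;

// One day's parasitoid-adult pass over the engine's preallocated buffers
// (first `n` slots live).  In order:
//   1. remove adults whose death day has arrived (in-place compaction,
//      id order preserved);
//   2. host-directed movement: every survivor whose action disk holds at
//      least one unparasitized host egg draws one uniform deviate (id
//      order) mapped through the inverse CDF of the disk's per-cell egg
//      counts (candidate cells in the offset order supplied, ascending
//      cell index); survivors with empty disks then draw truncated-
//      exponential distances (id order) followed by angle deviates,
//      exactly matching the R-level runif calls.  Nothing is consumed for
//      the undirected block when d_max <= 0;
//   3. accumulate each active female's daily attack capacity (the theta-
//      scaled oviposition table `ovi`, indexed by capped age) into the
//      dense per-cell buffer `cap` (zeroed here), in id order.
// Weight tables for directed lookups are built per occupied cell in
// fixed-size chunks, and all scratch space is reused across calls, so
// temporary memory stays bounded regardless of the population size.
// `any_hosts` short-circuits the host-search machinery on days when the
// grid holds no unparasitized eggs at all (every wasp then moves
// undirected, which is also what the full computation would conclude).
namespace para_scratch {
  std::vector<int> occ_of_cell;
  std::vector<int> occ_cells;
  std::vector<int> wasp_occ;
  std::vector<double> tot;
  std::vector<double> u;
  std::vector<int> bucket_n;
  std::vector<int> bucket;
  std::vector<int> fill_pos;
  std::vector<double> cum;
  std::vector<int> und;
  std::vector<double> dist;
}

// Return the reusable movement scratch space to the allocator (called at
// the end of each replicate so long test sessions do not accumulate the
// high-water marks of large runs).
// [[Rcpp::export(name = ".free_para_scratch")]]
void free_para_scratch() {
  using namespace para_scratch;
  std::vector<int>().swap(occ_of_cell);
  std::vector<int>().swap(occ_cells);
  std::vector<int>().swap(wasp_occ);
  std::vector<double>().swap(tot);
  std::vector<double>().swap(u);
  std::vector<int>().swap(bucket_n);
  std::vector<int>().swap(bucket);
  std::vector<int>().swap(fill_pos);
  std::vector<double>().swap(cum);
  std::vector<int>().swap(und);
  std::vector<double>().swap(dist);
}

// [[Rcpp::export(name = ".para_day_cpp")]]
List para_day_cpp(IntegerVector qx, IntegerVector qy, IntegerVector emerge,
                  IntegerVector death, LogicalVector female,
                  int n, int day, IntegerVector egg_tot, int side,
                  IntegerVector offs_dx, IntegerVector offs_dy,
                  double beta, double d_max, int preovip,
                  NumericVector ovi, NumericVector cap, bool any_hosts) {
  using namespace para_scratch;

  // 1) compact deaths
  int m = 0, deaths = 0;
  for (int i = 0; i < n; ++i) {
    if (death[i] > day) {
      if (m != i) {
        qx[m] = qx[i]; qy[m] = qy[i];
        emerge[m] = emerge[i]; death[m] = death[i];
        female[m] = female[i];
      }
      ++m;
    } else {
      ++deaths;
    }
  }

  int contacts = 0;
  int n_off = offs_dx.size();
  std::fill(cap.begin(), cap.end(), 0.0);

  if (m > 0) {
    int n_dir = 0;
    if (any_hosts) {
      // 2a) occupied origin cells (dense map), per-cell total host weight
      size_t ncells = (size_t) side * side;
      if (occ_of_cell.size() != ncells) occ_of_cell.assign(ncells, -1);
      occ_cells.clear();
      wasp_occ.resize(m);
      for (int i = 0; i < m; ++i) {
        size_t cell = qx[i] + (size_t) qy[i] * side;
        if (occ_of_cell[cell] < 0) {
          occ_of_cell[cell] = (int) occ_cells.size();
          occ_cells.push_back((int) cell);
        }
        wasp_occ[i] = occ_of_cell[cell];
      }
      int nocc = (int) occ_cells.size();
      tot.assign(nocc, 0.0);
      for (int k = 0; k < nocc; ++k) {
        int x0 = occ_cells[k] % side, y0 = occ_cells[k] / side;
        double s = 0.0;
        for (int j = 0; j < n_off; ++j) {
          int xx = x0 + offs_dx[j], yy = y0 + offs_dy[j];
          if (xx >= 0 && xx < side && yy >= 0 && yy < side) {
            s += egg_tot[xx + (size_t) yy * side];
          }
        }
        tot[k] = s;
      }

      // 2b) directed draws, id order
      u.assign(m, -1.0);
      for (int i = 0; i < m; ++i) {
        if (tot[wasp_occ[i]] > 0.0) {
          u[i] = unif_rand() * tot[wasp_occ[i]];
          ++n_dir;
        }
      }

      // 2c) directed lookups, chunked over occupied cells (CSR bucketing)
      if (n_dir > 0) {
        bucket_n.assign(nocc + 1, 0);
        for (int i = 0; i < m; ++i) {
          if (u[i] >= 0.0) ++bucket_n[wasp_occ[i] + 1];
        }
        for (int k = 0; k < nocc; ++k) bucket_n[k + 1] += bucket_n[k];
        bucket.resize(bucket_n[nocc]);
        fill_pos.assign(bucket_n.begin(), bucket_n.end() - 1);
        for (int i = 0; i < m; ++i) {
          if (u[i] >= 0.0) bucket[fill_pos[wasp_occ[i]]++] = i;
        }
        const int chunk = 4096;
        cum.resize((size_t) std::min(chunk, nocc) * n_off);
        for (int k0 = 0; k0 < nocc; k0 += chunk) {
          int k1 = std::min(k0 + chunk, nocc);
          for (int k = k0; k < k1; ++k) {
            if (bucket_n[k + 1] == bucket_n[k]) continue; // no directed wasps
            int x0 = occ_cells[k] % side, y0 = occ_cells[k] / side;
            double s = 0.0;
            double *row = &cum[(size_t)(k - k0) * n_off];
            for (int j = 0; j < n_off; ++j) {
              int xx = x0 + offs_dx[j], yy = y0 + offs_dy[j];
              if (xx >= 0 && xx < side && yy >= 0 && yy < side) {
                s += egg_tot[xx + (size_t) yy * side];
              }
              row[j] = s;
            }
            for (int b = bucket_n[k]; b < bucket_n[k + 1]; ++b) {
              int i = bucket[b];
              double ui = u[i];
              int lo = 0, hi = n_off - 1;      // first j with row[j] > ui
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (row[mid] > ui) hi = mid; else lo = mid + 1;
              }
              qx[i] = x0 + offs_dx[lo];
              qy[i] = y0 + offs_dy[lo];
            }
          }
        }
      }
      // reset the dense map for the next call
      for (size_t k = 0; k < occ_cells.size(); ++k) {
        occ_of_cell[occ_cells[k]] = -1;
      }
    }

    // 2d) undirected fallback: distances (id order), then angles
    if (d_max > 0.0) {
      und.clear();
      if (any_hosts && n_dir > 0) {
        for (int i = 0; i < m; ++i) {
          if (u[i] < 0.0) und.push_back(i);
        }
      } else {
        und.resize(m);
        for (int i = 0; i < m; ++i) und[i] = i;
      }
      dist.resize(und.size());
      double c1 = 1.0 - std::exp(-beta * d_max);
      for (size_t k = 0; k < und.size(); ++k) {
        dist[k] = -std::log(1.0 - unif_rand() * c1) / beta;
      }
      for (size_t k = 0; k < und.size(); ++k) {
        int i = und[k];
        double a = unif_rand() * 2.0 * M_PI;
        long xi = qx[i] + (long) std::nearbyint(dist[k] * std::cos(a));
        long yi = qy[i] + (long) std::nearbyint(dist[k] * std::sin(a));
        if (xi < 0 || xi >= side || yi < 0 || yi >= side) ++contacts;
        if (xi < 0) xi = 0; else if (xi >= side) xi = side - 1;
        if (yi < 0) yi = 0; else if (yi >= side) yi = side - 1;
        qx[i] = (int) xi;
        qy[i] = (int) yi;
      }
    }

    // 3) attack-capacity accumulation (post-move positions, id order)
    int maxa = ovi.size() - 1;
    for (int i = 0; i < m; ++i) {
      if (female[i]) {
        int alpha = day - emerge[i] - preovip;
        if (alpha >= 0) {
          cap[qx[i] + (size_t) qy[i] * side] +=
            ovi[alpha > maxa ? maxa : alpha];
        }
      }
    }
  }

  return List::create(_["n"] = m, _["deaths"] = deaths,
                      _["contacts"] = contacts);
}

// Append emerging adults directly into the (pre-grown) buffers: for each
// cell group in order, the first `females[g]` individuals are female, and
// each adult draws a Normal life span via norm_rand() -- the same stream
// as an R-level rnorm(total) over the concatenated groups -- rounded
// half-even and floored at one day.  `emerge_day` dates the adults (the
// current day for emergence).
// [[Rcpp::export(name = ".append_emergents_cpp")]]
void append_emergents_cpp(IntegerVector px, IntegerVector py,
                          IntegerVector emerge, IntegerVector death,
                          LogicalVector female, int start,
                          IntegerVector cells, IntegerVector counts,
                          IntegerVector females, int emerge_day,
                          double mu, double sd, int side) {
  int pos = start - 1;
  for (R_xlen_t g = 0; g < cells.size(); ++g) {
    int x = (cells[g] - 1) % side;
    int y = (cells[g] - 1) / side;
    for (int j = 0; j < counts[g]; ++j) {
      double L = std::nearbyint(mu + sd * norm_rand());
      if (L < 1.0) L = 1.0;
      px[pos] = x;
      py[pos] = y;
      emerge[pos] = emerge_day;
      death[pos] = emerge_day + (int) L;
      female[pos] = j < females[g];
      ++pos;
    }
  }
}
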