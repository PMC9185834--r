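// Stochastic lattice engine: random sequential updating of movement and
// growth sweeps on a periodic hexagonal lattice, with column-density
// recording and an exact line-crossing flux tally.
//
// Random numbers come from R's generator (set.seed in R gives bit-identical
// runs).  Draw order per selection is fixed: selection index, acceptance
// uniform, destination choice (destination drawn only when accepted).

#include <Rcpp.h>
using namespace Rcpp;

static inline int floordiv(int a, int b) {
  int q = a / b;
  if ((a % b != 0) && ((a < 0) != (b < 0))) --q;
  return q;
}

static inline int imod(int a, int m) {
  int r = a % m;
  return r < 0 ? r + m : r;
}

// net crossing tally at vertical lines x*_k = (k + 3/4) * delta, k = 0..I-1.
// Positions are in quarter-spacing integer units; lines sit at 4k + 3.
static inline void tally_crossing(std::vector<double>& flux, int xsq, int xdq,
                                  int Lq, int I) {
  int dxq = xdq - xsq;
  if (dxq > Lq / 2) dxq -= Lq;
  if (dxq < -Lq / 2) dxq += Lq;
  if (dxq > 0) {
    int k = floordiv(xsq - 3, 4) + 1;        // first line strictly right of xs
    int lineq = 4 * k + 3;
    if (lineq > xsq && lineq < xsq + dxq) flux[imod(k, I)] += 1.0;
  } else if (dxq < 0) {
    int k = floordiv(xsq - 3, 4);            // first line strictly left of xs
    int lineq = 4 * k + 3;
    if (lineq < xsq && lineq > xsq + dxq) flux[imod(k, I)] -= 1.0;
  }
}

// [[Rcpp::export(name = ".run_lattice_engine")]]
List run_lattice_engine(IntegerVector occ0, int I, int J,
                        IntegerMatrix nbr_move, IntegerMatrix nbr_grow,
                        NumericVector g_tab, NumericVector f_tab,
                        double M, double P, int n_steps,
                        IntegerVector record_steps,
                        bool do_movement, bool do_growth,
                        int flux_start, int flux_end,
                        NumericVector xpos) {
  const int nsites = I * J;
  const int size_move = nbr_move.nrow();   // neighbours stored per column
  const int size_grow = nbr_grow.nrow();
  const int Lq = 4 * I;

  std::vector<int> occ(occ0.begin(), occ0.end());
  std::vector<int> agents;
  agents.reserve(nsites);
  for (int s = 0; s < nsites; ++s) if (occ[s]) agents.push_back(s);
  int Q = (int)agents.size();

  std::vector<int> xq(nsites);
  for (int s = 0; s < nsites; ++s)
    xq[s] = (int)std::lround(4.0 * xpos[s]);

  const int n_rec = record_steps.size();
  NumericMatrix col_density(n_rec, I);
  NumericVector total_density(n_rec);
  IntegerVector q_record(n_rec);
  std::vector<double> flux(I, 0.0);
  long moves = 0, births = 0, deaths = 0;

  const int* nbm = nbr_move.begin();
  const int* nbg = nbr_grow.begin();

  int rec = 0;
  auto record = [&](int step) {
    while (rec < n_rec && record_steps[rec] == step) {
      std::vector<double> colsum(I, 0.0);
      for (int s = 0; s < nsites; ++s) colsum[s % I] += occ[s];
      double tot = 0.0;
      for (int i = 0; i < I; ++i) {
        col_density(rec, i) = colsum[i] / J;
        tot += colsum[i];
      }
      total_density[rec] = tot / nsites;
      q_record[rec] = Q;
      ++rec;
    }
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    const bool tally = flux_start >= 0 && step > flux_start && step <= flux_end;

    if (do_movement && Q > 0) {
      const int n_draws = Q;  // Q is constant through the movement sweep
      for (int d = 0; d < n_draws; ++d) {
        int idx = (int)(unif_rand() * Q);
        if (idx >= Q) idx = Q - 1;
        const int s = agents[idx];
        const int* nb = nbm + (size_t)s * size_move;
        int k = 0;
        for (int t = 0; t < size_move; ++t) k += occ[nb[t] - 1];
        const double pmove = M * g_tab[k];
        const double u = unif_rand();
        if (u < pmove) {
          const int nv = size_move - k;
          if (nv == 0) continue;  // G(1) > 0 with no vacancy: abort silently
          int pick = (int)(unif_rand() * nv);
          if (pick >= nv) pick = nv - 1;
          int dest = -1;
          for (int t = 0; t < size_move; ++t) {
            if (!occ[nb[t] - 1] && pick-- == 0) { dest = nb[t] - 1; break; }
          }
          occ[s] = 0;
          occ[dest] = 1;
          agents[idx] = dest;
          ++moves;
          if (tally) tally_crossing(flux, xq[s], xq[dest], Lq, I);
        }
      }
    }

    if (do_growth && P > 0.0 && Q > 0) {
      const int n_draws = Q;  // evaluated at sweep start
      for (int d = 0; d < n_draws && Q > 0; ++d) {
        int idx = (int)(unif_rand() * Q);
        if (idx >= Q) idx = Q - 1;
        const int s = agents[idx];
        const int* nb = nbg + (size_t)s * size_grow;
        int k = 0;
        for (int t = 0; t < size_grow; ++t) k += occ[nb[t] - 1];
        const double f = f_tab[k];
        const double u = unif_rand();
        if (f > 0.0) {
          if (u < P * f) {
            const int nv = size_grow - k;
            if (nv == 0) continue;
            int pick = (int)(unif_rand() * nv);
            if (pick >= nv) pick = nv - 1;
            int dest = -1;
            for (int t = 0; t < size_grow; ++t) {
              if (!occ[nb[t] - 1] && pick-- == 0) { dest = nb[t] - 1; break; }
            }
            occ[dest] = 1;
            if ((int)agents.size() > Q) agents[Q] = dest;
            else agents.push_back(dest);
            ++Q;
            ++births;
          }
        } else if (f < 0.0) {
          if (u < P * (-f)) {
            occ[s] = 0;
            agents[idx] = agents[Q - 1];
            --Q;
            ++deaths;
          }
        }
      }
      agents.resize(Q);
    }

    record(step);
  }

  return List::create(
    _["col_density"] = col_density,
    _["total_density"] = total_density,
    _["Q"] = q_record,
    _["final_occ"] = IntegerVector(occ.begin(), occ.end()),
    _["moves"] = (double)moves,
    _["births"] = (double)births,
    _["deaths"] = (double)deaths,
    _["flux_net"] = NumericVector(flux.begin(), flux.end()));
}
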