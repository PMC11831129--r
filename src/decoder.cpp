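// Compiled core of the recursive Bayesian ideal observer.
//
// The per-bin update couples the current and previous latent stimulus
// position through the temporal kernel, so the likelihood must be
// evaluated for every (orientation, position, transition-offset) triple.
// Cells whose receptive field sees neither position fire at baseline and
// contribute a hypothesis-independent constant, so only "active" cells
// (nonzero overlap at either end of the transition) are touched. All
// log-rate differences are position-pair dependent but spike-independent,
// hence precomputed once per configuration; each bin then reduces to
// sparse dot products with the spike vector plus a log-sum-exp over the
// transition support.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct DecoderTables {
  int nx, ny, npos, ncells, nori, K;
  double dt, mu0, logmu0;
  std::vector<int> offx, offy;
  std::vector<double> logT;
  // active cells per position (CSR, sorted)
  std::vector<int> act_start, act_idx;
  // per (p, k) pair: union of active cells at both ends (CSR)
  std::vector<std::size_t> pair_start;
  std::vector<int> union_idx;
  std::vector<double> dlog;    // (log mu - log mu0), laid out entry*nori + l
  std::vector<double> sumdmu;  // sum(mu - mu0), laid out (p*K + k)*nori + l
  // first-bin tables (previous frame blank): parallel to act CSR
  std::vector<double> enter_dlog;    // entry*nori + l
  std::vector<double> enter_sumdmu;  // p*nori + l
};

static inline int wrap(int i, int n) { int r = i % n; return r < 0 ? r + n : r; }

// [[Rcpp::export]]
SEXP build_decoder_tables_cpp(NumericVector O, int nx, int ny, int ncells,
                              int nori, IntegerVector offx,
                              IntegerVector offy, NumericVector logT,
                              double r0, double dr, double w, double cs,
                              double dt, double rate_floor) {
  if (nori < 1 || nori > 8) stop("between 1 and 8 orientations supported");
  DecoderTables* T = new DecoderTables();
  T->nx = nx; T->ny = ny; T->npos = nx * ny; T->ncells = ncells;
  T->nori = nori; T->K = offx.size(); T->dt = dt;
  const double mu0 = std::max(r0, rate_floor) * dt;
  T->mu0 = mu0; T->logmu0 = std::log(mu0);
  T->offx.assign(offx.begin(), offx.end());
  T->offy.assign(offy.begin(), offy.end());
  T->logT.assign(logT.begin(), logT.end());
  const int npos = T->npos, K = T->K;
  const double* Op = O.begin();
  const double gain = cs * dr;

  // active cells per position: cells whose rate can differ from baseline
  // there (nonzero overlap for some orientation). With zero gain the
  // stimulus never moves any rate, so no cell is active and every
  // likelihood is exactly the baseline constant.
  T->act_start.assign(npos + 1, 0);
  for (int p = 0; p < npos; ++p) {
    if (gain > 0.0) {
      for (int i = 0; i < ncells; ++i) {
        bool on = false;
        for (int l = 0; l < nori && !on; ++l)
          on = Op[p + (std::size_t)npos * (i + (std::size_t)ncells * l)] > 1e-9;
        if (on) T->act_idx.push_back(i);
      }
    }
    T->act_start[p + 1] = (int)T->act_idx.size();
  }

  // first-bin tables: previous frame is blank (overlap 0)
  T->enter_dlog.resize((std::size_t)T->act_idx.size() * nori);
  T->enter_sumdmu.assign((std::size_t)npos * nori, 0.0);
  for (int p = 0; p < npos; ++p) {
    for (int e = T->act_start[p]; e < T->act_start[p + 1]; ++e) {
      int i = T->act_idx[e];
      for (int l = 0; l < nori; ++l) {
        double onow = Op[p + (std::size_t)npos * (i + (std::size_t)ncells * l)];
        double mu = std::max(rate_floor, r0 + gain * onow) * dt;
        T->enter_dlog[(std::size_t)e * nori + l] = std::log(mu) - T->logmu0;
        T->enter_sumdmu[(std::size_t)p * nori + l] += mu - mu0;
      }
    }
  }

  // pairwise tables over (position, transition offset)
  T->pair_start.assign((std::size_t)npos * K + 1, 0);
  T->sumdmu.assign((std::size_t)npos * K * nori, 0.0);
  std::vector<int> un; un.reserve(ncells);
  for (int p = 0; p < npos; ++p) {
    int ix = p % nx, iy = p / nx;
    for (int k = 0; k < K; ++k) {
      int jx = wrap(ix - T->offx[k], nx), jy = wrap(iy - T->offy[k], ny);
      int q = jx + nx * jy;  // previous position
      // sorted union of act[p] and act[q]
      un.clear();
      int a = T->act_start[p], ae = T->act_start[p + 1];
      int b = T->act_start[q], be = T->act_start[q + 1];
      while (a < ae || b < be) {
        if (b >= be || (a < ae && T->act_idx[a] < T->act_idx[b]))
          un.push_back(T->act_idx[a++]);
        else if (a >= ae || T->act_idx[b] < T->act_idx[a])
          un.push_back(T->act_idx[b++]);
        else { un.push_back(T->act_idx[a]); ++a; ++b; }
      }
      std::size_t pk = (std::size_t)p * K + k;
      for (std::size_t u = 0; u < un.size(); ++u) {
        int i = un[u];
        T->union_idx.push_back(i);
        for (int l = 0; l < nori; ++l) {
          std::size_t base = (std::size_t)npos * (i + (std::size_t)ncells * l);
          double onow = Op[p + base];
          double oprev = Op[q + base];
          double mu = std::max(rate_floor,
                               r0 + gain * (onow - w * oprev)) * dt;
          T->dlog.push_back(std::log(mu) - T->logmu0);
          T->sumdmu[pk * nori + l] += mu - mu0;
        }
      }
      T->pair_start[pk + 1] = T->union_idx.size();
    }
  }
  // dlog was pushed entry-major already (entry*nori + l order)
  XPtr<DecoderTables> ptr(T, true);
  return ptr;
}

// [[Rcpp::export]]
bool cpp_ptr_is_null(SEXP p) {
  return R_ExternalPtrAddr(p) == nullptr;
}

// [[Rcpp::export]]
List decode_spikes_cpp(SEXP ptr_, IntegerMatrix spikes) {
  XPtr<DecoderTables> ptr(ptr_);
  const DecoderTables& T = *ptr;
  const int npos = T.npos, nori = T.nori, K = T.K, ncells = T.ncells;
  if (spikes.nrow() != ncells)
    stop("spike matrix has %d rows but the decoder expects %d cells",
         spikes.nrow(), ncells);
  const int nbins = spikes.ncol();
  const std::size_t NS = (std::size_t)nori * npos;

  std::vector<double> lp(NS, -std::log((double)nori * npos));
  std::vector<double> newlp(NS);
  std::vector<double> sig(ncells);
  std::vector<double> ent(nori);
  NumericMatrix marginals(nori, nbins);
  NumericVector log_norm(nbins);
  double cum = 0.0;

  for (int t = 0; t < nbins; ++t) {
    double base = 0.0;
    for (int i = 0; i < ncells; ++i) {
      double s = (double)spikes(i, t);
      sig[i] = s;
      base += s * T.logmu0 - T.mu0 - R::lgammafn(s + 1.0);
    }
    const bool first = (t == 0);
    for (int p = 0; p < npos; ++p) {
      // streaming log-sum-exp over the transition support, all
      // orientations in one pass over each pair's active-cell union
      double m[8], ssum[8];
      for (int l = 0; l < nori; ++l) { m[l] = -INFINITY; ssum[l] = 0.0; }
      if (first) {
        for (int l = 0; l < nori; ++l) ent[l] = 0.0;
        for (int e = T.act_start[p]; e < T.act_start[p + 1]; ++e) {
          double s = sig[T.act_idx[e]];
          if (s != 0.0)
            for (int l = 0; l < nori; ++l)
              ent[l] += s * T.enter_dlog[(std::size_t)e * nori + l];
        }
        for (int l = 0; l < nori; ++l)
          ent[l] -= T.enter_sumdmu[(std::size_t)p * nori + l];
      }
      const int ix = p % T.nx, iy = p / T.nx;
      for (int k = 0; k < K; ++k) {
        const int jx = wrap(ix - T.offx[k], T.nx);
        const int jy = wrap(iy - T.offy[k], T.ny);
        const int q = jx + T.nx * jy;
        const double w0 = T.logT[k];
        const std::size_t pk = (std::size_t)p * K + k;
        double acc[8];
        if (first) {
          for (int l = 0; l < nori; ++l) acc[l] = ent[l];
        } else {
          for (int l = 0; l < nori; ++l) acc[l] = 0.0;
          const std::size_t e0 = T.pair_start[pk], e1 = T.pair_start[pk + 1];
          for (std::size_t e = e0; e < e1; ++e) {
            double s = sig[T.union_idx[e]];
            if (s != 0.0) {
              const double* dl = &T.dlog[e * nori];
              for (int l = 0; l < nori; ++l) acc[l] += s * dl[l];
            }
          }
          const double* sd = &T.sumdmu[pk * nori];
          for (int l = 0; l < nori; ++l) acc[l] -= sd[l];
        }
        for (int l = 0; l < nori; ++l) {
          double v = w0 + lp[(std::size_t)l * npos + q] + acc[l];
          if (v > m[l]) {
            ssum[l] = ssum[l] * std::exp(m[l] - v) + 1.0;
            m[l] = v;
          } else {
            ssum[l] += std::exp(v - m[l]);
          }
        }
      }
      for (int l = 0; l < nori; ++l)
        newlp[(std::size_t)l * npos + p] = m[l] + std::log(ssum[l]);
    }
    // renormalize in the log domain
    double gmax = -INFINITY;
    for (std::size_t j = 0; j < NS; ++j)
      if (newlp[j] > gmax) gmax = newlp[j];
    if (!std::isfinite(gmax))
      stop("posterior mass vanished at bin %d; check the rate floor", t + 1);
    double z = 0.0;
    for (std::size_t j = 0; j < NS; ++j) z += std::exp(newlp[j] - gmax);
    const double lz = gmax + std::log(z);
    for (std::size_t j = 0; j < NS; ++j) lp[j] = newlp[j] - lz;
    cum += lz + base;
    log_norm[t] = cum;
    for (int l = 0; l < nori; ++l) {
      double s = 0.0;
      for (int p = 0; p < npos; ++p) s += std::exp(lp[(std::size_t)l * npos + p]);
      marginals(l, t) = s;
    }
  }

  NumericVector fin(NS);
  for (std::size_t j = 0; j < NS; ++j) fin[j] = std::exp(lp[j]);
  return List::create(_["marginals"] = marginals, _["final"] = fin,
                      _["log_norm"] = log_norm);
}
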