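// Gibbs samplers for two-cluster Bayesian genotype assignment
// (no-admixture and admixture models). Alleles arrive as an
// individuals x (2 * loci) integer matrix, dense-coded 1..J_l per locus,
// 0 = missing. Allele frequencies get a symmetric Dirichlet(lambda)
// prior; under the admixture model each individual's ancestry vector q
// gets a Dirichlet(alpha) prior, with alpha optionally sampled by a
// log-scale random-walk Metropolis step under a uniform prior.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static void rdirichlet_row(NumericVector& out, const NumericVector& shape) {
  double tot = 0.0;
  const int n = shape.size();
  for (int j = 0; j < n; ++j) {
    out[j] = R::rgamma(shape[j], 1.0);
    tot += out[j];
  }
  if (tot <= 0.0) { // numerically degenerate; fall back to uniform
    for (int j = 0; j < n; ++j) out[j] = 1.0 / n;
  } else {
    for (int j = 0; j < n; ++j) out[j] /= tot;
  }
}

// sample an index 0..(K-1) proportional to w (unnormalized, nonnegative)
static int sample_prop(const std::vector<double>& w) {
  double tot = 0.0;
  for (double v : w) tot += v;
  double u = R::unif_rand() * tot;
  double acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}

// draw cluster allele frequencies P[k][l] ~ Dirichlet(lambda + counts)
static void draw_freqs(std::vector<std::vector<NumericVector> >& P,
                       const std::vector<std::vector<NumericVector> >& counts,
                       double lambda, int K, int L,
                       const IntegerVector& n_alleles) {
  for (int k = 0; k < K; ++k) {
    for (int l = 0; l < L; ++l) {
      NumericVector shape(n_alleles[l]);
      for (int j = 0; j < n_alleles[l]; ++j) {
        shape[j] = lambda + counts[k][l][j];
      }
      rdirichlet_row(P[k][l], shape);
    }
  }
}

// [[Rcpp::export(name = ".gibbs_cluster_cpp")]]
List gibbs_cluster_cpp(IntegerMatrix alleles, IntegerVector n_alleles,
                       int K, int burn_in, int reps, double lambda,
                       double alpha, bool admixture, bool sample_alpha,
                       double alpha_max) {
  const int I = alleles.nrow();
  const int L = n_alleles.size();
  if (alleles.ncol() != 2 * L) stop("alleles matrix must have 2 * L columns");

  // state
  std::vector<std::vector<NumericVector> > P(K), cnt(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    cnt[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l] = NumericVector(n_alleles[l]);
      cnt[k][l] = NumericVector(n_alleles[l]);
    }
  }
  std::vector<int> z(I);                 // no-admixture labels
  NumericMatrix q(I, K);                 // admixture ancestry
  IntegerMatrix origin(I, 2 * L);        // admixture copy origins
  for (int i = 0; i < I; ++i) {
    z[i] = (int)std::floor(R::unif_rand() * K);
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { q(i, k) = R::rgamma(1.0, 1.0); tot += q(i, k); }
    for (int k = 0; k < K; ++k) q(i, k) /= tot;
    for (int c = 0; c < 2 * L; ++c) {
      origin(i, c) = (int)std::floor(R::unif_rand() * K);
    }
  }

  NumericMatrix Q_acc(I, K);
  std::vector<std::vector<NumericVector> > P_acc(K);
  for (int k = 0; k < K; ++k) {
    P_acc[k].resize(L);
    for (int l = 0; l < L; ++l) P_acc[k][l] = NumericVector(n_alleles[l]);
  }
  double alpha_acc = 0.0;
  int alpha_accept = 0;
  std::vector<double> w(K);

  const int total = burn_in + reps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // --- allele counts given current assignments
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(cnt[k][l].begin(), cnt[k][l].end(), 0.0);
    for (int i = 0; i < I; ++i) {
      for (int c = 0; c < 2 * L; ++c) {
        int a = alleles(i, c);
        if (a == 0) continue;
        int l = c / 2;
        int k = admixture ? origin(i, c) : z[i];
        cnt[k][l][a - 1] += 1.0;
      }
    }
    draw_freqs(P, cnt, lambda, K, L, n_alleles);

    if (!admixture) {
      // --- labels given frequencies
      for (int i = 0; i < I; ++i) {
        std::vector<double> ll(K, 0.0);
        for (int c = 0; c < 2 * L; ++c) {
          int a = alleles(i, c);
          if (a == 0) continue;
          int l = c / 2;
          for (int k = 0; k < K; ++k) {
            ll[k] += std::log(P[k][l][a - 1] + 1e-300);
          }
        }
        double m = ll[0];
        for (int k = 1; k < K; ++k) m = std::max(m, ll[k]);
        for (int k = 0; k < K; ++k) w[k] = std::exp(ll[k] - m);
        z[i] = sample_prop(w);
        if (sweep >= burn_in) {
          double tot = 0.0;
          for (int k = 0; k < K; ++k) tot += w[k];
          for (int k = 0; k < K; ++k) Q_acc(i, k) += w[k] / tot;
        }
      }
    } else {
      // --- copy origins given q and frequencies, then q given origins
      for (int i = 0; i < I; ++i) {
        std::vector<double> copies(K, 0.0);
        for (int c = 0; c < 2 * L; ++c) {
          int a = alleles(i, c);
          if (a == 0) continue;
          int l = c / 2;
          for (int k = 0; k < K; ++k) w[k] = q(i, k) * P[k][l][a - 1];
          int o = sample_prop(w);
          origin(i, c) = o;
          copies[o] += 1.0;
        }
        NumericVector shape(K);
        for (int k = 0; k < K; ++k) shape[k] = alpha + copies[k];
        NumericVector qi(K);
        rdirichlet_row(qi, shape);
        for (int k = 0; k < K; ++k) q(i, k) = qi[k];
        if (sweep >= burn_in) {
          for (int k = 0; k < K; ++k) Q_acc(i, k) += q(i, k);
        }
      }
      if (sample_alpha) {
        // RW Metropolis on log(alpha), uniform(0, alpha_max) prior
        double prop = alpha * std::exp(R::norm_rand() * 0.3);
        if (prop > 0.0 && prop < alpha_max) {
          double sum_log_q = 0.0;
          for (int i = 0; i < I; ++i)
            for (int k = 0; k < K; ++k)
              sum_log_q += std::log(q(i, k) + 1e-300);
          auto lp = [&](double a) {
            return I * (R::lgammafn(K * a) - K * R::lgammafn(a)) +
                   (a - 1.0) * sum_log_q;
          };
          // include the log-scale proposal Jacobian
          double log_ratio = lp(prop) - lp(alpha) +
            std::log(prop) - std::log(alpha);
          if (std::log(R::unif_rand()) < log_ratio) {
            alpha = prop;
            ++alpha_accept;
          }
        }
      }
    }

    if (sweep >= burn_in) {
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int j = 0; j < n_alleles[l]; ++j)
            P_acc[k][l][j] += P[k][l][j];
      alpha_acc += alpha;
    }
  }

  for (int i = 0; i < I; ++i)
    for (int k = 0; k < K; ++k) Q_acc(i, k) /= reps;
  List P_mean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < n_alleles[l]; ++j)
        pm(k, j) = P_acc[k][l][j] / reps;
    P_mean[l] = pm;
  }
  return List::create(_["Q"] = Q_acc, _["freqs"] = P_mean,
                      _["alpha"] = alpha_acc / reps,
                      _["alpha_accept_rate"] =
                        sample_alpha ? (double)alpha_accept / total : NA_REAL);
}
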