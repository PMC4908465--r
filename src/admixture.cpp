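// Gibbs sampler for the K-cluster admixture model on unlinked
// multilocus genotypes. Per sweep: latent cluster origins Z of each
// allele copy, individual admixture proportions q (Dirichlet with
// shared hyperparameter alpha, Metropolis-updated on the log scale),
// and cluster allele frequencies P, either with independent
// Dirichlet(lambda) priors or correlated around an ancestral vector PA
// with per-cluster drift F (Dirichlet(PA*(1-F)/F)), PA and F updated
// by Metropolis. Missing copies (coded 0) contribute nothing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int sample_cat(const double *w, int K, double tot) {
  double u = R::unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// log density of Dirichlet(par) at p (both length A), with p floored
static double ldirichlet(const double *p, const double *par, int A) {
  double s = 0.0, sum_par = 0.0;
  for (int a = 0; a < A; ++a) {
    sum_par += par[a];
    s += (par[a] - 1.0) * std::log(p[a]) - R::lgammafn(par[a]);
  }
  return s + R::lgammafn(sum_par);
}

// [[Rcpp::export]]
List admix_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                 int burnin, int reps, int thin, bool correlated,
                 double lambda, double alpha_init, double alpha_max,
                 double alpha_logstep, double f_init, double f_step,
                 double pa_step) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");
  int Amax = 0;
  for (int l = 0; l < L; ++l) Amax = std::max(Amax, (int)n_alleles[l]);
  const int PFLAT = L * Amax;
  const double PFLOOR = 1e-9;

  std::vector<int> Z(n * L * 2, 0);
  std::vector<double> P((size_t)K * PFLAT, 0.0);
  std::vector<double> PA(PFLAT, 0.0);
  std::vector<double> Fk(K, f_init);
  std::vector<double> q((size_t)n * K, 1.0 / K);
  std::vector<double> nkla((size_t)K * PFLAT, 0.0);
  std::vector<double> mik((size_t)n * K, 0.0);
  double alpha = alpha_init;

  // ancestral start: observed sample frequencies (with pseudocount)
  for (int l = 0; l < L; ++l) {
    std::vector<double> cnt(n_alleles[l], 1.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = geno(i, 2 * l + c);
        if (a > 0) cnt[a - 1] += 1.0;
      }
    double tot = 0.0;
    for (int a = 0; a < n_alleles[l]; ++a) tot += cnt[a];
    for (int a = 0; a < n_alleles[l]; ++a) {
      PA[l * Amax + a] = cnt[a] / tot;
      for (int k = 0; k < K; ++k) P[(size_t)k * PFLAT + l * Amax + a] = cnt[a] / tot;
    }
  }
  // random initial assignments
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c)
        Z[(i * L + l) * 2 + c] = (int)std::floor(R::unif_rand() * K);

  const int nsamp = reps / thin;
  NumericVector q_samp((R_xlen_t)nsamp * n * K);
  NumericVector loglik(nsamp), alpha_tr(nsamp);
  NumericMatrix f_tr(nsamp, K);
  int isamp = 0;
  std::vector<double> w(K);

  for (int sweep = 0; sweep < burnin + reps; ++sweep) {
    // --- Z update, accumulating counts ---
    std::fill(nkla.begin(), nkla.end(), 0.0);
    std::fill(mik.begin(), mik.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *qi = &q[(size_t)i * K];
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = qi[k] * P[(size_t)k * PFLAT + l * Amax + (a - 1)];
            tot += w[k];
          }
          int k = (tot > 0) ? sample_cat(w.data(), K, tot)
                            : (int)std::floor(R::unif_rand() * K);
          Z[(i * L + l) * 2 + c] = k;
          nkla[(size_t)k * PFLAT + l * Amax + (a - 1)] += 1.0;
          mik[(size_t)i * K + k] += 1.0;
        }
      }
    }
    // --- q update ---
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + mik[(size_t)i * K + k], 1.0);
        q[(size_t)i * K + k] = std::max(g, 1e-12);
        tot += q[(size_t)i * K + k];
      }
      for (int k = 0; k < K; ++k) q[(size_t)i * K + k] /= tot;
    }
    // --- P update ---
    for (int k = 0; k < K; ++k) {
      double prior_scale = correlated ? (1.0 - Fk[k]) / Fk[k] : 0.0;
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        int A = n_alleles[l];
        for (int a = 0; a < A; ++a) {
          double prior = correlated ? PA[l * Amax + a] * prior_scale : lambda;
          double g = R::rgamma(prior + nkla[(size_t)k * PFLAT + l * Amax + a], 1.0);
          P[(size_t)k * PFLAT + l * Amax + a] = g;
          tot += g;
        }
        for (int a = 0; a < A; ++a) {
          double &p = P[(size_t)k * PFLAT + l * Amax + a];
          p = std::max(p / tot, PFLOOR);
        }
      }
    }
    if (correlated) {
      // --- PA update: move mass between two alleles per locus ---
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        if (A < 2) continue;
        int a1 = (int)std::floor(R::unif_rand() * A);
        int a2 = (int)std::floor(R::unif_rand() * (A - 1));
        if (a2 >= a1) ++a2;
        double d = R::norm_rand() * pa_step;
        double pa1 = PA[l * Amax + a1] + d, pa2 = PA[l * Amax + a2] - d;
        if (pa1 < 1e-6 || pa2 < 1e-6 || pa1 > 1.0 || pa2 > 1.0) continue;
        double lr = 0.0;
        for (int k = 0; k < K; ++k) {
          double sc = (1.0 - Fk[k]) / Fk[k];
          const double p1 = P[(size_t)k * PFLAT + l * Amax + a1];
          const double p2 = P[(size_t)k * PFLAT + l * Amax + a2];
          lr += (pa1 * sc - 1.0) * std::log(p1) - R::lgammafn(pa1 * sc)
              + (pa2 * sc - 1.0) * std::log(p2) - R::lgammafn(pa2 * sc);
          double old1 = PA[l * Amax + a1], old2 = PA[l * Amax + a2];
          lr -= (old1 * sc - 1.0) * std::log(p1) - R::lgammafn(old1 * sc)
              + (old2 * sc - 1.0) * std::log(p2) - R::lgammafn(old2 * sc);
        }
        if (std::log(R::unif_rand()) < lr) {
          PA[l * Amax + a1] = pa1;
          PA[l * Amax + a2] = pa2;
        }
      }
      // --- F update per cluster ---
      for (int k = 0; k < K; ++k) {
        double fp = Fk[k] + R::norm_rand() * f_step;
        if (fp < 1e-4) fp = 2e-4 - fp;       // reflect at the bounds
        if (fp > 0.999) fp = 1.998 - fp;
        if (fp < 1e-4 || fp > 0.999) continue;
        double lr = 0.0;
        double sc_new = (1.0 - fp) / fp, sc_old = (1.0 - Fk[k]) / Fk[k];
        for (int l = 0; l < L; ++l) {
          int A = n_alleles[l];
          std::vector<double> par_new(A), par_old(A);
          for (int a = 0; a < A; ++a) {
            par_new[a] = PA[l * Amax + a] * sc_new;
            par_old[a] = PA[l * Amax + a] * sc_old;
          }
          const double *pk = &P[(size_t)k * PFLAT + l * Amax];
          lr += ldirichlet(pk, par_new.data(), A)
              - ldirichlet(pk, par_old.data(), A);
        }
        if (std::log(R::unif_rand()) < lr) Fk[k] = fp;
      }
    }
    // --- alpha update (Metropolis on log alpha, uniform prior) ---
    if (K > 1) {
      double ap = alpha * std::exp(R::norm_rand() * alpha_logstep);
      if (ap > 0 && ap < alpha_max) {
        double lr = std::log(ap / alpha);  // Jacobian of the log-scale walk
        lr += n * (R::lgammafn(K * ap) - K * R::lgammafn(ap)
                   - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        double slq = 0.0;
        for (size_t t = 0; t < (size_t)n * K; ++t) slq += std::log(q[t]);
        lr += (ap - alpha) * slq;
        if (std::log(R::unif_rand()) < lr) alpha = ap;
      }
    }
    // --- record ---
    int post = sweep - burnin + 1;
    if (post > 0 && post % thin == 0 && isamp < nsamp) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        const double *qi = &q[(size_t)i * K];
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += qi[k] * P[(size_t)k * PFLAT + l * Amax + (a - 1)];
            ll += std::log(std::max(s, 1e-300));
          }
      }
      loglik[isamp] = ll;
      alpha_tr[isamp] = alpha;
      for (int k = 0; k < K; ++k) f_tr(isamp, k) = Fk[k];
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
          q_samp[(R_xlen_t)isamp + (R_xlen_t)nsamp * (i + (R_xlen_t)n * k)] =
            q[(size_t)i * K + k];
      ++isamp;
    }
  }
  q_samp.attr("dim") = IntegerVector::create(nsamp, n, K);
  return List::create(_["q_samples"] = q_samp, _["loglik"] = loglik,
                      _["alpha"] = alpha_tr, _["f"] = f_tr);
}
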