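// E-step of the local haplotype-cluster HMM on unphased genotypes.
//
// Hidden state at each locus: the ordered pair of cluster memberships of the
// two haplotypes of an individual (K^2 states; emission is symmetric so the
// likelihood equals the unordered-pair model). Transitions factorise per
// haplotype: with probability rho[l] a haplotype "jumps" and picks a new
// cluster from alpha[l, ], otherwise it stays. Chromosome starts reset the
// chain (both haplotypes draw from alpha[l, ]).
//
// The factorised transition lets every forward/backward update run in
// O(K^2) instead of O(K^4).

#include <Rcpp.h>
using namespace Rcpp;

static inline double emit(int g, double t1, double t2) {
  switch (g) {
  case 0: return (1.0 - t1) * (1.0 - t2);
  case 1: return t1 * (1.0 - t2) + (1.0 - t1) * t2;
  case 2: return t1 * t2;
  default: return 1.0; // missing
  }
}

// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(IntegerMatrix geno,      // n_ind x L, -1 = missing
               NumericMatrix theta,     // L x K
               NumericMatrix alpha,     // L x K
               NumericVector rho,       // length L (ignored at chr starts)
               LogicalVector chr_start, // length L
               bool want_post) {
  const int n = geno.nrow(), L = geno.ncol(), K = theta.ncol();
  NumericMatrix A1(L, K), A0(L, K), JD(L, K);
  NumericVector JC(L);
  NumericVector post; // n x L x K flattened
  if (want_post) post = NumericVector(Dimension(n, L, K));
  double loglik = 0.0;

  std::vector<double> Fbuf((size_t)L * K * K); // scaled forward matrices
  std::vector<double> cvec(L);
  std::vector<double> B((size_t)K * K), Bnext((size_t)K * K), C((size_t)K * K);
  std::vector<double> tmp((size_t)K * K);
  std::vector<double> f1(K), f2(K), u(K), w(K), e((size_t)K * K);

  for (int i = 0; i < n; ++i) {
    // ---------- forward ----------
    for (int l = 0; l < L; ++l) {
      double *F = &Fbuf[(size_t)l * K * K];
      const int g = geno(i, l);
      // emission matrix at l
      for (int k1 = 0; k1 < K; ++k1)
        for (int k2 = 0; k2 < K; ++k2)
          e[k1 * K + k2] = emit(g, theta(l, k1), theta(l, k2));
      if (chr_start[l]) {
        for (int k1 = 0; k1 < K; ++k1)
          for (int k2 = 0; k2 < K; ++k2)
            F[k1 * K + k2] = alpha(l, k1) * alpha(l, k2) * e[k1 * K + k2];
      } else {
        const double *Fp = &Fbuf[(size_t)(l - 1) * K * K];
        const double r = rho[l];
        // G(j1,k2) = (1-r) Fp(j1,k2) + r alpha(j1) s(k2),  s = colsums
        for (int k2 = 0; k2 < K; ++k2) {
          double s = 0.0;
          for (int k1 = 0; k1 < K; ++k1) s += Fp[k1 * K + k2];
          f2[k2] = s;
        }
        for (int j1 = 0; j1 < K; ++j1)
          for (int k2 = 0; k2 < K; ++k2)
            tmp[j1 * K + k2] =
              (1.0 - r) * Fp[j1 * K + k2] + r * alpha(l, j1) * f2[k2];
        // M(j1,j2) = (1-r) G(j1,j2) + r rowsum_G(j1) alpha(j2)
        for (int j1 = 0; j1 < K; ++j1) {
          double rs = 0.0;
          for (int k2 = 0; k2 < K; ++k2) rs += tmp[j1 * K + k2];
          for (int j2 = 0; j2 < K; ++j2)
            F[j1 * K + j2] =
              ((1.0 - r) * tmp[j1 * K + j2] + r * rs * alpha(l, j2)) *
              e[j1 * K + j2];
        }
      }
      double c = 0.0;
      for (int s = 0; s < K * K; ++s) c += F[s];
      if (c <= 0) stop("zero forward probability at locus %d", l + 1);
      for (int s = 0; s < K * K; ++s) F[s] /= c;
      cvec[l] = c;
      loglik += std::log(c);
    }
    // ---------- backward + accumulators ----------
    std::fill(B.begin(), B.end(), 1.0);
    for (int l = L - 1; l >= 0; --l) {
      const double *F = &Fbuf[(size_t)l * K * K];
      const int g = geno(i, l);
      // posterior at l
      double tot = 0.0;
      for (int s = 0; s < K * K; ++s) {
        tmp[s] = F[s] * B[s];
        tot += tmp[s];
      }
      for (int s = 0; s < K * K; ++s) tmp[s] /= tot;
      // cluster marginals (expected haplotypes per cluster)
      for (int k1 = 0; k1 < K; ++k1) {
        double m = 0.0;
        for (int k2 = 0; k2 < K; ++k2)
          m += tmp[k1 * K + k2] + tmp[k2 * K + k1];
        if (want_post) post[i + (size_t)n * (l + (size_t)L * k1)] = m;
        if (chr_start[l]) JD(l, k1) += m;
      }
      // emission expectations
      if (g >= 0) {
        for (int k1 = 0; k1 < K; ++k1)
          for (int k2 = 0; k2 < K; ++k2) {
            const double P = tmp[k1 * K + k2];
            if (P <= 0) continue;
            if (g == 0) {
              A0(l, k1) += P; A0(l, k2) += P;
            } else if (g == 2) {
              A1(l, k1) += P; A1(l, k2) += P;
            } else {
              const double t1 = theta(l, k1), t2 = theta(l, k2);
              const double den = t1 * (1 - t2) + (1 - t1) * t2;
              const double w1 = den > 0 ? t1 * (1 - t2) / den : 0.5;
              A1(l, k1) += P * w1;       A0(l, k1) += P * (1 - w1);
              A1(l, k2) += P * (1 - w1); A0(l, k2) += P * w1;
            }
          }
      }
      // jump expectations on the interval (l-1, l)
      if (!chr_start[l]) {
        const double *Fp = &Fbuf[(size_t)(l - 1) * K * K];
        const double r = rho[l];
        for (int k = 0; k < K; ++k) { f1[k] = 0.0; f2[k] = 0.0; }
        for (int k1 = 0; k1 < K; ++k1)
          for (int k2 = 0; k2 < K; ++k2) {
            f1[k1] += Fp[k1 * K + k2];
            f2[k2] += Fp[k1 * K + k2];
          }
        // e * B at l
        for (int k1 = 0; k1 < K; ++k1)
          for (int k2 = 0; k2 < K; ++k2)
            C[k1 * K + k2] = emit(g, theta(l, k1), theta(l, k2)) *
              B[k1 * K + k2];
        for (int j = 0; j < K; ++j) {
          u[j] = (1.0 - r) * f2[j] + r * alpha(l, j); // G over hap2
          w[j] = (1.0 - r) * f1[j] + r * alpha(l, j); // G over hap1
        }
        double jc = 0.0;
        for (int j1 = 0; j1 < K; ++j1) {
          double s = 0.0;
          for (int j2 = 0; j2 < K; ++j2) s += C[j1 * K + j2] * u[j2];
          const double jd1 = r * alpha(l, j1) * s / cvec[l];
          JD(l, j1) += jd1;
          jc += jd1;
        }
        for (int j2 = 0; j2 < K; ++j2) {
          double s = 0.0;
          for (int j1 = 0; j1 < K; ++j1) s += C[j1 * K + j2] * w[j1];
          const double jd2 = r * alpha(l, j2) * s / cvec[l];
          JD(l, j2) += jd2;
          jc += jd2;
        }
        JC[l] += jc;
      }
      // backward recursion to l-1
      if (l > 0) {
        if (chr_start[l]) {
          // chain restarts: B_{l-1}(k1,k2) = sum over init states of
          // alpha alpha e B / c_l (independent of k1,k2)
          double s = 0.0;
          for (int j1 = 0; j1 < K; ++j1)
            for (int j2 = 0; j2 < K; ++j2)
              s += alpha(l, j1) * alpha(l, j2) *
                emit(g, theta(l, j1), theta(l, j2)) * B[j1 * K + j2];
          s /= cvec[l];
          std::fill(Bnext.begin(), Bnext.end(), s);
        } else {
          const double r = rho[l];
          for (int k1 = 0; k1 < K; ++k1)
            for (int k2 = 0; k2 < K; ++k2)
              C[k1 * K + k2] = emit(g, theta(l, k1), theta(l, k2)) *
                B[k1 * K + k2];
          // (T C): rows
          for (int j2 = 0; j2 < K; ++j2) {
            double s = 0.0;
            for (int j1 = 0; j1 < K; ++j1) s += alpha(l, j1) * C[j1 * K + j2];
            u[j2] = s;
          }
          for (int k1 = 0; k1 < K; ++k1)
            for (int j2 = 0; j2 < K; ++j2)
              tmp[k1 * K + j2] = (1.0 - r) * C[k1 * K + j2] + r * u[j2];
          // (. T^T): columns
          for (int k1 = 0; k1 < K; ++k1) {
            double s = 0.0;
            for (int j2 = 0; j2 < K; ++j2) s += tmp[k1 * K + j2] * alpha(l, j2);
            w[k1] = s;
          }
          for (int k1 = 0; k1 < K; ++k1)
            for (int k2 = 0; k2 < K; ++k2)
              Bnext[k1 * K + k2] =
                ((1.0 - r) * tmp[k1 * K + k2] + r * w[k1]) / cvec[l];
        }
        std::swap(B, Bnext);
      }
    }
  }
  List out = List::create(_["loglik"] = loglik, _["A1"] = A1, _["A0"] = A0,
                          _["JD"] = JD, _["JC"] = JC);
  if (want_post) out["post"] = post;
  return out;
}
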