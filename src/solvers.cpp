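#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-loss (squared hinge) linear SVM
//
//   min_W  (1/2) W'W + omega * sum_j max(1 - W'x_j c_j, 0)^2
//
// solved in the dual (Hsieh et al., ICML 2008): box constraint alpha_i >= 0
// with no upper bound, diagonal shift D_ii = 1/(2*omega).
//
// Xt is the transposed design matrix in CSC form (columns = training
// points), passed as its p/i/x slots so no Matrix headers are needed.
// The visiting order is a random permutation drawn from a fixed-seed
// xorshift generator: runs are deterministic for a given data ordering.
//
// [[Rcpp::export]]
List dcd_l2_svm(IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                int n_features, NumericVector y, double omega,
                double tol, int max_iter) {
  const int n = Xp.size() - 1;
  NumericVector w(n_features);
  std::vector<double> alpha(n, 0.0), qii(n);
  const double diag = 0.5 / omega;

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int p = Xp[i]; p < Xp[i + 1]; ++p) s += Xx[p] * Xx[p];
    qii[i] = s + diag;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t state = 88172645463325252ULL; // fixed seed: deterministic solver

  int iter = 0;
  bool converged = false;
  double pgmax = 0.0, pgmin = 0.0;
  for (iter = 0; iter < max_iter && !converged; ++iter) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates shuffle
      state ^= state << 13; state ^= state >> 7; state ^= state << 17;
      int j = (int)(state % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    pgmax = -HUGE_VAL; pgmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      const double ci = y[i];
      double wx = 0.0;
      for (int p = Xp[i]; p < Xp[i + 1]; ++p) wx += w[Xi[p]] * Xx[p];
      const double G = ci * wx - 1.0 + alpha[i] * diag;
      double PG = G;
      if (alpha[i] == 0.0 && G > 0.0) PG = 0.0; // at the bound, pushing out
      if (PG > pgmax) pgmax = PG;
      if (PG < pgmin) pgmin = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        const double d = (a_new - alpha[i]) * ci;
        if (d != 0.0)
          for (int p = Xp[i]; p < Xp[i + 1]; ++p) w[Xi[p]] += d * Xx[p];
        alpha[i] = a_new;
      }
    }
    if (pgmax - pgmin < tol) converged = true;
  }

  return List::create(_["w"] = w,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iter"] = iter,
                      _["converged"] = converged,
                      _["pg_gap"] = pgmax - pgmin);
}

// Sample a nucleotide sequence from an order-m Markov chain.
//
// cumprob has 4^order rows (contexts, base-4 encoded, most significant
// first) and 3 columns: cumulative probability of bases A, A+C, A+C+G.
// Uses R's RNG so results follow set.seed().
//
// [[Rcpp::export]]
IntegerVector markov_generate(NumericMatrix cumprob, int order, int length) {
  RNGScope scope;
  IntegerVector out(length);
  const int nctx = cumprob.nrow();
  const int carry = (order > 0) ? nctx / 4 : 1; // 4^(order-1)

  int ctx = 0;
  int start = 0;
  if (order > 0) {
    ctx = (int)(unif_rand() * nctx);
    if (ctx == nctx) --ctx;
    // emit the initial context's bases (most significant first)
    int m = std::min(order, length);
    for (int j = 0; j < m; ++j) {
      int shift = 2 * (order - 1 - j);
      out[j] = (ctx >> shift) & 3;
    }
    start = m;
  }
  for (int i = start; i < length; ++i) {
    const double u = unif_rand();
    int b = 0;
    if (u > cumprob(ctx, 0)) ++b;
    if (u > cumprob(ctx, 1)) ++b;
    if (u > cumprob(ctx, 2)) ++b;
    out[i] = b;
    if (order > 0) ctx = (ctx % carry) * 4 + b;
  }
  return out;
}
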