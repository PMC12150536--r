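// Fused computation of the two pairwise (N^2) loss terms and their
// gradient w.r.t. the embedding Z: structural BCE against the binary
// adjacency and the spatial InfoNCE over neighbor sets. Shares the
// Z Z^T product between both terms; called once per training epoch
// (or per batch block).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// fast double-precision exp via 2^k * P(r) range reduction; |error|
// ~1e-13 relative, adequate for the bounded cosine/temperature
// arguments (|x| <= 1/tau) it is used with
static inline double fastExp(double x) {
  static const double log2e = 1.4426950408889634074;
  static const double ln2hi = 6.93147180369123816490e-01;
  static const double ln2lo = 1.90821492927058770002e-10;
  const double kd = std::nearbyint(x * log2e);
  const int k = static_cast<int>(kd);
  const double r = (x - kd * ln2hi) - kd * ln2lo;
  // degree-10 Taylor on |r| <= ln(2)/2
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 +
             r * (1.0 / 24 + r * (1.0 / 120 + r * (1.0 / 720 +
             r * (1.0 / 5040 + r * (1.0 / 40320 + r * (1.0 / 362880 +
             r * (1.0 / 3628800))))))))));
  return std::ldexp(p, k);
}

// [[Rcpp::export(name = ".pairLossGradsCpp")]]
Rcpp::List pairLossGradsCpp(const arma::mat& Z, const arma::mat& A,
                            const arma::mat& Aneg, double tau,
                            bool doBce, bool doNce, double eps) {
  const uword n = Z.n_rows;
  const double n2 = static_cast<double>(n) * static_cast<double>(n);
  mat S = Z * Z.t();
  double ls = 0.0, lc = 0.0;
  mat dZ(n, Z.n_cols, fill::zeros);

  if (doBce) {
    // single pass: sigmoid for the gradient, softplus for the loss
    // (clamping the logit reproduces probability clamping at eps)
    const double lim = std::log((1.0 - eps) / eps);
    mat PmA(n, n);
    double acc = 0.0;
    const double* sp = S.memptr();
    const double* ap = A.memptr();
    double* op = PmA.memptr();
    const uword nn = S.n_elem;
    const double elim = std::exp(-lim);
    for (uword t = 0; t < nn; ++t) {
      const double s = sp[t];
      const double sc = s > lim ? lim : (s < -lim ? -lim : s);
      double p, softplus;
      if (s >= 0) {
        const double e = std::exp(-s);
        p = 1.0 / (1.0 + e);
        softplus = s <= lim ? sc + std::log1p(e)
                            : lim + std::log1p(elim);
      } else {
        const double e = std::exp(s);
        p = e / (1.0 + e);
        softplus = s >= -lim ? std::log1p(e) : std::log1p(elim);
      }
      acc += softplus - ap[t] * sc;
      op[t] = p - ap[t];
    }
    ls = acc / n2;
    dZ += (2.0 / n2) * (PmA * Z);
  }

  if (doNce) {
    vec nrm = sqrt(sum(square(Z), 1));
    nrm.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    mat Zh = Z.each_col() / nrm;
    mat C = S / (nrm * nrm.t());
    mat E(n, n);
    {
      const double* cp_ = C.memptr();
      double* ep_ = E.memptr();
      const double itau = 1.0 / tau;
      const uword nn = C.n_elem;
      for (uword t = 0; t < nn; ++t) ep_[t] = fastExp(cp_[t] * itau);
    }
    mat posE = A % E;
    mat negE = Aneg % E;
    vec pos = sum(posE, 1);
    vec den = sum(negE, 1);
    uvec valid = find((pos > 0) % (den > 0));
    const double m = static_cast<double>(valid.n_elem);
    if (m > 0) {
      lc = -accu(log(pos(valid) / den(valid))) / m;
      // per-anchor-row coefficients; zero for skipped spots
      vec cp(n, fill::zeros), cn(n, fill::zeros);
      for (uword t = 0; t < valid.n_elem; ++t) {
        const uword i = valid(t);
        cp(i) = 1.0 / (pos(i) * m * tau);
        cn(i) = 1.0 / (den(i) * m * tau);
      }
      mat G = negE.each_col() % cn - posE.each_col() % cp;
      mat M = G + G.t();
      mat R = M * Zh;
      vec s = sum(M % C, 1);
      R -= Zh.each_col() % s;
      dZ += R.each_col() / nrm;
    }
  }

  return Rcpp::List::create(Rcpp::Named("L_S") = ls,
                            Rcpp::Named("L_con") = lc,
                            Rcpp::Named("dZ") = dZ);
}
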