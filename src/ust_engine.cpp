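// Hot path of the iterative estimation loop for soft-thresholding penalties.
// Mirrors the reference R implementation in R/path_engine.R (mspls_core):
// step (a) unit-variance LVs, (b) inner coefficients with response
// overwrite, (c) LV re-estimation, (d) mode-A / soft-threshold updates with
// unit-norm sign-aligned weights, (e) CRT on the normalized weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec normalize_sign(vec w) {
  double nrm = norm(w, 2);
  if (nrm == 0.0) Rcpp::stop("cannot normalize an all-zero weight vector");
  w /= nrm;
  if (w(index_max(abs(w))) < 0) w = -w;
  return w;
}

// [[Rcpp::export(name = ".ust_engine")]]
Rcpp::List ust_engine(const Rcpp::List& X_list,
                      const Rcpp::List& expl_list,
                      const Rcpp::List& resp_list,
                      const Rcpp::LogicalVector& modeB,
                      const Rcpp::NumericVector& lambda1,
                      const Rcpp::List& w_init,
                      double gamma, int max_iter) {
  const int Q = X_list.size();
  std::vector<mat> X(Q);
  std::vector<vec> w(Q);
  std::vector<uvec> expl(Q), resp(Q);
  for (int q = 0; q < Q; ++q) {
    X[q] = Rcpp::as<mat>(X_list[q]);
    w[q] = Rcpp::as<vec>(w_init[q]);
    expl[q] = Rcpp::as<uvec>(expl_list[q]);   // 0-based
    resp[q] = Rcpp::as<uvec>(resp_list[q]);
  }
  const int n = X[0].n_rows;
  mat Z(n, Q);
  mat Theta(Q, Q);
  std::vector<double> crt_trace;
  bool converged = false;
  int it = 0;

  auto compute_Z = [&]() {
    for (int q = 0; q < Q; ++q) {
      vec z = X[q] * w[q];
      double s = std::sqrt(dot(z, z) / (n - 1));
      if (s < 1e-12) Rcpp::stop("degenerate latent variable (constant score)");
      Z.col(q) = z / s;
    }
  };
  auto compute_Theta = [&]() {
    Theta.zeros();
    mat G = Z.t() * Z;
    for (int q = 0; q < Q; ++q) {
      if (expl[q].n_elem > 0) {
        vec th;
        bool ok = solve(th, G.submat(expl[q], expl[q]),
                        G.submat(expl[q], uvec{(unsigned) q}));
        if (!ok) Rcpp::stop("collinear latent variables among explanatory "
                            "sources of block %d", q + 1);
        Theta.submat(expl[q], uvec{(unsigned) q}) = th;
      }
    }
    for (int q = 0; q < Q; ++q) {
      if (resp[q].n_elem > 0)
        Theta.submat(resp[q], uvec{(unsigned) q}) =
          G.submat(resp[q], uvec{(unsigned) q}) / (n - 1);
    }
  };

  while (it < max_iter) {
    ++it;
    compute_Z();                       // step (a)
    compute_Theta();                   // step (b)
    mat Zt = Z * Theta;                // step (c)
    double crt = 0.0;                  // steps (d) + (e)
    for (int q = 0; q < Q; ++q) {
      vec zt = Zt.col(q);
      vec wq;
      if (modeB[q]) {
        vec c = X[q].t() * zt;
        double thr = lambda1[q] / 2.0;
        wq = sign(c) % clamp(abs(c) - thr, 0.0, datum::inf);
        if (!any(wq != 0.0))
          Rcpp::stop("block %d: lambda1 too large: empty model (all weights "
                     "thresholded to zero)", q + 1);
      } else {
        double ss = dot(zt, zt);
        if (ss == 0.0)
          Rcpp::stop("re-estimated LV of block %d is identically zero", q + 1);
        wq = (X[q].t() * zt) / ss;
      }
      wq = normalize_sign(wq);
      crt += accu(square(wq - w[q]));
      w[q] = wq;
    }
    crt_trace.push_back(crt);
    if (crt < gamma) { converged = true; break; }
  }
  compute_Z();                         // final scores
  compute_Theta();
  Rcpp::List wout(Q);
  for (int q = 0; q < Q; ++q) wout[q] = Rcpp::wrap(w[q]);
  return Rcpp::List::create(
    Rcpp::Named("weights") = wout,
    Rcpp::Named("scores") = Z,
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("crt_trace") = Rcpp::wrap(crt_trace));
}
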