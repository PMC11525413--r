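// Marginal negative log-likelihood of the latent-variable count regression
// model.  The latent variables are integrated out of the case-wise
// likelihood with a tensor-product Gauss-Hermite rule: standard-normal
// product nodes arrive as data and are mapped onto the latent scale by
// mu_eta + chol(Sigma_eta) %*% z inside the objective, so the grid follows
// the current latent-distribution parameters at every iteration and the
// weights never involve the latent density itself.
//
// Parameterization (free scale): error variances and latent SDs on the log
// scale, the correlation factor through a row-normalised unit lower
// triangle, NB dispersion as log(size).  Fixed-reliability indicators get
// their error variance recomputed from the loading (and latent variance)
// here, so the constraint tracks its drivers during optimization.

#include <TMB.hpp>

template<class Type>
Type objective_function<Type>::operator() ()
{
  DATA_VECTOR(y);         // n counts
  DATA_MATRIX(Z);         // n x (m+1), leading constant column
  DATA_MATRIX(W);         // n x q indicator matrix (q = 0 allowed)
  DATA_IVECTOR(load_lat); // q, 0-based latent index of each indicator
  DATA_INTEGER(family);   // 0 = poisson, 1 = nb2
  DATA_MATRIX(nodes);     // G x p standard-normal product nodes
  DATA_VECTOR(logw);      // G log product weights
  DATA_IVECTOR(gi_k);     // active latent-latent products, first index
  DATA_IVECTOR(gi_l);     //   second index (0-based, k < l)
  DATA_IVECTOR(om_lat);   // active latent-manifest products, latent index
  DATA_IVECTOR(om_cov);   //   column of Z (0-based)
  DATA_IVECTOR(rel_idx);  // indicators with fixed-reliability error variance
  DATA_VECTOR(rel_val);   //   the reliabilities

  PARAMETER_VECTOR(beta);      // m+1
  PARAMETER_VECTOR(gamma);     // p
  PARAMETER_VECTOR(gammaI);    // length(gi_k)
  PARAMETER_VECTOR(omega);     // length(om_lat)
  PARAMETER_VECTOR(nu);        // q
  PARAMETER_VECTOR(lambda);    // q
  PARAMETER_VECTOR(logtheta);  // q
  PARAMETER_VECTOR(mu_eta);    // p
  PARAMETER_VECTOR(logsd_eta); // p
  PARAMETER_VECTOR(corr_tr);   // p(p-1)/2 unconstrained
  PARAMETER(logdisp);          // log NB size (mapped off for poisson)

  int n = y.size();
  int q = W.cols();
  int p = mu_eta.size();
  int G = nodes.rows();

  vector<Type> theta(q);
  for (int k = 0; k < q; k++) theta(k) = exp(logtheta(k));
  for (int t = 0; t < rel_idx.size(); t++) {
    int k = rel_idx(t);
    Type veta = exp(Type(2.0) * logsd_eta(load_lat(k)));
    theta(k) = lambda(k) * lambda(k) * veta *
               (Type(1.0) / rel_val(t) - Type(1.0));
  }

  // chol(Sigma_eta) = D Lc, Lc a row-normalised unit lower triangle
  matrix<Type> L(p, p);
  if (p > 0) L.setZero();
  {
    int idx = 0;
    for (int i = 0; i < p; i++) {
      Type ss = Type(1.0);
      for (int j = 0; j < i; j++) {
        L(i, j) = corr_tr(idx++);
        ss += L(i, j) * L(i, j);
      }
      L(i, i) = Type(1.0);
      Type sc = exp(logsd_eta(i)) / sqrt(ss);
      for (int j = 0; j <= i; j++) L(i, j) *= sc;
    }
  }

  // latent-scale nodes: E = nodes %*% t(L) + mu_eta
  matrix<Type> E(G, p);
  for (int g = 0; g < G; g++)
    for (int d = 0; d < p; d++) {
      Type acc = mu_eta(d);
      for (int j = 0; j <= d; j++) acc += L(d, j) * nodes(g, j);
      E(g, d) = acc;
    }

  // Indicator-block log-density, collapsed per latent:
  //   sum_k log N(w_ik; nu_k + lambda_k eta_d(k), theta_k)
  //     = K + sum_d [ A(i,d) + B(i,d) eta_d + C(d) eta_d^2 ]
  // so the node loop costs O(n G p) instead of O(n G q).
  matrix<Type> A(n, p), B(n, p);
  if (p > 0) { A.setZero(); B.setZero(); }
  vector<Type> C(p);
  if (p > 0) C.setZero();
  Type K = Type(0.0);
  for (int k = 0; k < q; k++) {
    int d = load_lat(k);
    K -= Type(0.5) * log(Type(2.0) * Type(M_PI) * theta(k));
    C(d) -= lambda(k) * lambda(k) / (Type(2.0) * theta(k));
    for (int i = 0; i < n; i++) {
      Type a = W(i, k) - nu(k);
      A(i, d) -= a * a / (Type(2.0) * theta(k));
      B(i, d) += a * lambda(k) / theta(k);
    }
  }

  vector<Type> zb = Z * beta;   // n
  vector<Type> s(G);            // node-only structural part
  for (int g = 0; g < G; g++) {
    Type v = Type(0.0);
    for (int d = 0; d < p; d++) v += gamma(d) * E(g, d);
    for (int t = 0; t < gi_k.size(); t++)
      v += gammaI(t) * E(g, gi_k(t)) * E(g, gi_l(t));
    s(g) = v;
  }

  // per-row outcome constants (lgamma terms stay out of the node loop)
  Type k_nb = exp(logdisp);
  vector<Type> ycon(n);
  for (int i = 0; i < n; i++) {
    if (family == 0)
      ycon(i) = -lgamma(y(i) + Type(1.0));
    else
      ycon(i) = lgamma(y(i) + k_nb) - lgamma(k_nb) - lgamma(y(i) + Type(1.0))
              + k_nb * logdisp;
  }

  Type nll = Type(0.0);
  vector<Type> tmp(G);
  for (int i = 0; i < n; i++) {
    for (int g = 0; g < G; g++) {
      Type pi = zb(i) + s(g);
      for (int t = 0; t < om_lat.size(); t++)
        pi += omega(t) * Z(i, om_cov(t)) * E(g, om_lat(t));
      Type ly;
      if (family == 0) {
        ly = y(i) * pi - exp(pi) + ycon(i);
      } else {
        // NB2: ycon + y*pi - (y + k) * log(k + mu)
        ly = ycon(i) + y(i) * pi -
             (y(i) + k_nb) * logspace_add(logdisp, pi);
      }
      Type lw = K;
      for (int d = 0; d < p; d++)
        lw += A(i, d) + B(i, d) * E(g, d) + C(d) * E(g, d) * E(g, d);
      tmp(g) = logw(g) + ly + lw;
    }
    // log-sum-exp over nodes (taped max, valid for all parameter values)
    Type m = tmp(0);
    for (int g = 1; g < G; g++) m = CppAD::CondExpGt(tmp(g), m, tmp(g), m);
    Type se = Type(0.0);
    for (int g = 0; g < G; g++) se += exp(tmp(g) - m);
    nll -= m + log(se);
  }
  return nll;
}
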