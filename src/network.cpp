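#include <Rcpp.h>
using namespace Rcpp;

// Compiled form of a mass-action reaction network.
//
// Rate laws are signed sums of monomials: each term contributes
//   coef * prod(conc[species indices])
// to the rate of one reaction, where coef already carries the sign and the
// product of all rate constants of that term.  The state derivative is
// S %*% v plus, for an open (flow-coupled) system, an exchange term
// alpha * D_j * (c_blood_j - c_j) for every mobile species j.

struct CompiledNetwork {
  int nspecies;
  int nreactions;
  // rate-law terms, flattened
  std::vector<double> tcoef;   // signed constant product per term
  std::vector<int>    trxn;    // 0-based reaction index per term
  std::vector<int>    tsp_ptr; // offsets into tsp_idx (length nterms+1)
  std::vector<int>    tsp_idx; // 0-based species indices (with multiplicity)
  // stoichiometric matrix, triplet form
  std::vector<int>    smi, smj;
  std::vector<double> smv;
  // flow coupling
  std::vector<int>    mobile;  // 0/1 per species
  std::vector<double> D;       // diffusion-convection constant per species
  std::vector<double> cblood;  // reservoir concentration per species
};

static CompiledNetwork* get_net(SEXP xp) {
  Rcpp::XPtr<CompiledNetwork> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cn_compile(int nspecies, int nreactions,
                NumericVector tcoef, IntegerVector trxn,
                IntegerVector tsp_ptr, IntegerVector tsp_idx,
                IntegerVector smi, IntegerVector smj, NumericVector smv,
                IntegerVector mobile, NumericVector D, NumericVector cblood) {
  CompiledNetwork* net = new CompiledNetwork();
  net->nspecies = nspecies;
  net->nreactions = nreactions;
  net->tcoef.assign(tcoef.begin(), tcoef.end());
  net->trxn.assign(trxn.begin(), trxn.end());
  net->tsp_ptr.assign(tsp_ptr.begin(), tsp_ptr.end());
  net->tsp_idx.assign(tsp_idx.begin(), tsp_idx.end());
  net->smi.assign(smi.begin(), smi.end());
  net->smj.assign(smj.begin(), smj.end());
  net->smv.assign(smv.begin(), smv.end());
  net->mobile.assign(mobile.begin(), mobile.end());
  net->D.assign(D.begin(), D.end());
  net->cblood.assign(cblood.begin(), cblood.end());
  Rcpp::XPtr<CompiledNetwork> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cn_rates(SEXP xp, NumericVector y) {
  CompiledNetwork* net = get_net(xp);
  NumericVector v(net->nreactions);
  const int nterms = (int)net->tcoef.size();
  for (int t = 0; t < nterms; ++t) {
    double m = net->tcoef[t];
    for (int k = net->tsp_ptr[t]; k < net->tsp_ptr[t + 1]; ++k)
      m *= y[net->tsp_idx[k]];
    v[net->trxn[t]] += m;
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cn_rhs(SEXP xp, NumericVector y, double alpha) {
  CompiledNetwork* net = get_net(xp);
  const int n = net->nspecies;
  std::vector<double> v(net->nreactions, 0.0);
  const int nterms = (int)net->tcoef.size();
  for (int t = 0; t < nterms; ++t) {
    double m = net->tcoef[t];
    for (int k = net->tsp_ptr[t]; k < net->tsp_ptr[t + 1]; ++k)
      m *= y[net->tsp_idx[k]];
    v[net->trxn[t]] += m;
  }
  NumericVector dy(n);
  const int nnz = (int)net->smi.size();
  for (int z = 0; z < nnz; ++z)
    dy[net->smi[z]] += net->smv[z] * v[net->smj[z]];
  if (alpha > 0.0) {
    for (int i = 0; i < n; ++i)
      if (net->mobile[i])
        dy[i] += alpha * net->D[i] * (net->cblood[i] - y[i]);
  }
  return dy;
}

// Analytic Jacobian of the RHS.  d(rate_j)/d(c_i) for a monomial term is the
// sum over occurrences of species i of the product of the remaining factors,
// which handles repeated species (multiplicity) automatically.
// [[Rcpp::export]]
NumericMatrix cn_jac(SEXP xp, NumericVector y, double alpha) {
  CompiledNetwork* net = get_net(xp);
  const int n = net->nspecies;
  const int nr = net->nreactions;
  // dv[j, i] = d v_j / d c_i, stored dense (nr x n)
  std::vector<double> dv((size_t)nr * n, 0.0);
  const int nterms = (int)net->tcoef.size();
  for (int t = 0; t < nterms; ++t) {
    const int j = net->trxn[t];
    const int a = net->tsp_ptr[t], b = net->tsp_ptr[t + 1];
    for (int k = a; k < b; ++k) {
      double m = net->tcoef[t];
      for (int l = a; l < b; ++l)
        if (l != k) m *= y[net->tsp_idx[l]];
      dv[(size_t)j + (size_t)nr * net->tsp_idx[k]] += m;
    }
  }
  NumericMatrix J(n, n);
  const int nnz = (int)net->smi.size();
  for (int i = 0; i < n; ++i) {
    for (int z = 0; z < nnz; ++z) {
      const double d = dv[(size_t)net->smj[z] + (size_t)nr * i];
      if (d != 0.0) J(net->smi[z], i) += net->smv[z] * d;
    }
  }
  if (alpha > 0.0) {
    for (int i = 0; i < n; ++i)
      if (net->mobile[i]) J(i, i) -= alpha * net->D[i];
  }
  return J;
}
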