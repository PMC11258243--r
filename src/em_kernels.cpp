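// Hot-loop kernels for the collective EM procedure (physics-mode decoder).
// The R code owns the algorithm; these kernels only fuse the per-batch
// network forward pass, the realization-weighted likelihood/gradient
// accumulation, and the backward pass, with math identical to the R
// reference implementations (verified in the test suite).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
  bool tanh_act;
};

Net unpack_net(const List& net) {
  Net n;
  List W = net["W"], b = net["b"];
  for (int l = 0; l < W.size(); ++l) {
    n.W.push_back(as<arma::mat>(W[l]));
    n.b.push_back(as<arma::vec>(b[l]));
  }
  std::string act = as<std::string>(net["activation"]);
  n.tanh_act = (act == "tanh");
  return n;
}

arma::mat act_apply(const arma::mat& Z, bool tanh_act) {
  if (tanh_act) return arma::tanh(Z);
  arma::mat A = Z;
  A.for_each([](arma::mat::elem_type& v) { if (v < 0) v = std::exp(v) - 1.0; });
  return A;
}

// forward with cached layer inputs; acts[l] is the input to layer l
arma::mat forward_cache(const Net& n, const arma::mat& X,
                        std::vector<arma::mat>& acts) {
  arma::mat A = X;
  size_t L = n.W.size();
  acts.resize(L);
  for (size_t l = 0; l < L; ++l) {
    acts[l] = A;
    arma::mat Z = A * n.W[l];
    Z.each_row() += n.b[l].t();
    A = (l + 1 < L) ? act_apply(Z, n.tanh_act) : Z;
  }
  return A;
}

// backward; returns flattened gradient in mlp_flatten order (all W column
// major, then all b)
arma::vec backward_flat(const Net& n, const std::vector<arma::mat>& acts,
                        const arma::mat& dY) {
  size_t L = n.W.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  arma::mat delta = dY;
  for (size_t li = L; li-- > 0;) {
    gW[li] = acts[li].t() * delta;
    gb[li] = arma::sum(delta, 0).t();
    if (li > 0) {
      arma::mat dA = delta * n.W[li].t();
      const arma::mat& H = acts[li];
      if (n.tanh_act) {
        delta = dA % (1.0 - H % H);
      } else {
        arma::mat dfun = H;
        dfun.for_each([](arma::mat::elem_type& v) { v = (v > 0) ? 1.0 : v + 1.0; });
        delta = dA % dfun;
      }
    }
  }
  size_t tot = 0;
  for (size_t l = 0; l < L; ++l) tot += gW[l].n_elem + gb[l].n_elem;
  arma::vec out(tot);
  size_t pos = 0;
  for (size_t l = 0; l < L; ++l) {
    out.subvec(pos, pos + gW[l].n_elem - 1) = arma::vectorise(gW[l]);
    pos += gW[l].n_elem;
  }
  for (size_t l = 0; l < L; ++l) {
    out.subvec(pos, pos + gb[l].n_elem - 1) = gb[l];
    pos += gb[l].n_elem;
  }
  return out;
}

} // namespace

//' @title Batched network forward pass (internal)
//' @description Internal C++ kernel; see [mlp_forward()] for the reference
//'   implementation it mirrors.
//' @param net an `mlp` object.
//' @param X input matrix.
//' @return output matrix.
//' @keywords internal
// [[Rcpp::export(.cpp_mlp_forward)]]
arma::mat cpp_mlp_forward(List net, const arma::mat& X) {
  Net n = unpack_net(net);
  arma::mat A = X;
  size_t L = n.W.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = A * n.W[l];
    Z.each_row() += n.b[l].t();
    A = (l + 1 < L) ? act_apply(Z, n.tanh_act) : Z;
  }
  return A;
}

// Fused physics-mode batch computation.
//
// EdgeB: (g * nb) x p input rows, slot-major (slot j occupies rows
//   [(j-1)*nb, j*nb)); already input-normalized.
// tgt: nb x d targets; mass: nb; phi: nZ x g (1-based types);
// post: either ns x nZ posterior weights (compute_post = false) or ignored
//   and recomputed from log_prior (length nZ) with rows grouped as
//   ns = nb / Tn node-sims, time fastest.
// Returns: loss (weighted squared-error term), flat gradients per net,
//   posterior matrix (ns x nZ) and the per-realization log-likelihood
//   matrix L (ns x nZ, Gaussian constant included).
// [[Rcpp::export(.cpp_phys_grad)]]
List cpp_phys_grad(List nets, const arma::mat& EdgeB, const arma::mat& tgt,
                   const arma::vec& mass, const arma::imat& phi,
                   const arma::mat& post_in, const arma::vec& log_prior,
                   bool compute_post, int Tn, double sigma2, int d_out) {
  const int K = nets.size();
  const int g = phi.n_cols;
  const int nZ = phi.n_rows;
  const int nb = tgt.n_rows;
  const int ns = nb / Tn;
  const double cst = -0.5 * d_out * std::log(2.0 * M_PI * sigma2);

  std::vector<Net> net(K);
  std::vector<std::vector<arma::mat>> acts(K);
  std::vector<arma::mat> out(K);
  for (int k = 0; k < K; ++k) {
    net[k] = unpack_net(nets[k]);
    out[k] = forward_cache(net[k], EdgeB, acts[k]);
  }

  // per-realization predictions and log-likelihoods
  std::vector<arma::mat> preds(nZ);
  arma::mat L(ns, nZ);
  for (int z = 0; z < nZ; ++z) {
    arma::mat s(nb, d_out, arma::fill::zeros);
    for (int j = 0; j < g; ++j) {
      int k = phi(z, j) - 1;
      s += out[k].rows(j * nb, (j + 1) * nb - 1);
    }
    s.each_col() /= mass;
    s -= tgt;
    preds[z] = s;                       // residuals, actually
    arma::vec sq = arma::sum(arma::square(s), 1);
    arma::mat sqm(sq.memptr(), Tn, ns); // time fastest within node-sim
    L.col(z) = (cst * Tn - arma::sum(sqm, 0).t() / (2.0 * sigma2));
  }

  arma::mat post;
  if (compute_post) {
    arma::mat lp = L;
    lp.each_row() += log_prior.t();
    arma::vec m = arma::max(lp, 1);
    lp.each_col() -= m;
    post = arma::exp(lp);
    post.each_col() /= arma::sum(post, 1);
  } else {
    post = post_in;
  }

  // gradient accumulation
  double loss = 0.0;
  std::vector<arma::mat> dY(K);
  for (int k = 0; k < K; ++k) dY[k] = arma::mat(g * nb, d_out, arma::fill::zeros);
  for (int z = 0; z < nZ; ++z) {
    arma::vec w(nb);
    for (int a = 0; a < ns; ++a) {
      w.subvec(a * Tn, (a + 1) * Tn - 1).fill(post(a, z));
    }
    const arma::mat& R = preds[z];
    loss += arma::accu(w % arma::sum(arma::square(R), 1)) / (2.0 * sigma2);
    arma::mat wR = R;
    wR.each_col() %= (w / (sigma2 * mass));
    for (int j = 0; j < g; ++j) {
      int k = phi(z, j) - 1;
      dY[k].rows(j * nb, (j + 1) * nb - 1) += wR;
    }
  }

  List grads(K);
  for (int k = 0; k < K; ++k) {
    grads[k] = backward_flat(net[k], acts[k], dY[k]);
  }
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["post"] = post, _["L"] = L);
}
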