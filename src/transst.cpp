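// Inner loops for the spatial GMM (ICM-EM) and the Potts lattice
// sampler. Both use R's RNG so results are reproducible via set.seed()
// on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the K-state Potts model on a height x width rook
// lattice: P(z_i = k | rest) proportional to exp(-beta * #{neighbors != k}).
// Runs `nchains` independent chains from i.i.d. uniform initial states,
// `sweeps` full sequential sweeps each; returns the end states
// (nchains x n, labels 1..K, sites in row-major lattice order).
// [[Rcpp::export]]
IntegerMatrix potts_gibbs_cpp(int height, int width, int K, double beta,
                              int sweeps, int nchains) {
  const int n = height * width;
  IntegerMatrix out(nchains, n);
  std::vector<std::vector<int>> nbr(n);
  for (int r = 0; r < height; ++r) {
    for (int c = 0; c < width; ++c) {
      int i = r * width + c;
      if (r > 0) nbr[i].push_back(i - width);
      if (r < height - 1) nbr[i].push_back(i + width);
      if (c > 0) nbr[i].push_back(i - 1);
      if (c < width - 1) nbr[i].push_back(i + 1);
    }
  }
  std::vector<int> z(n);
  std::vector<double> w(K);
  for (int ch = 0; ch < nchains; ++ch) {
    for (int i = 0; i < n; ++i)
      z[i] = (int)std::floor(unif_rand() * K);
    for (int s = 0; s < sweeps; ++s) {
      for (int i = 0; i < n; ++i) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          int agree = 0;
          for (int j : nbr[i]) if (z[j] == k) ++agree;
          // -beta * (deg - agree); constant -beta*deg cancels in the
          // normalization, keep it for clarity at this scale
          w[k] = std::exp(-beta * (double)((int)nbr[i].size() - agree));
          tot += w[k];
        }
        double u = unif_rand() * tot, acc = 0.0;
        int knew = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += w[k];
          if (u <= acc) { knew = k; break; }
        }
        z[i] = knew;
      }
    }
    for (int i = 0; i < n; ++i) out(ch, i) = z[i] + 1;
  }
  return out;
}

static void mstep_moments(const arma::mat& V, const arma::ivec& z, int K,
                          arma::mat& mu, arma::cube& Sig, double ridge,
                          double min_eig, int& n_ridge) {
  const int q = V.n_cols;
  for (int k = 0; k < K; ++k) {
    arma::uvec idx = arma::find(z == k + 1);
    arma::mat Vk = V.rows(idx);
    mu.row(k) = arma::mean(Vk, 0);
    arma::mat C;
    if (idx.n_elem > 1) {
      arma::mat D = Vk.each_row() - mu.row(k);
      C = (D.t() * D) / (double)idx.n_elem;
    } else {
      C = arma::eye(q, q);
    }
    C = 0.5 * (C + C.t());
    double ev = arma::min(arma::eig_sym(C));
    if (ev < min_eig) {
      C += (ridge + std::max(0.0, -ev)) * arma::eye(q, q);
      ++n_ridge;
    }
    Sig.slice(k) = C;
  }
}

static arma::mat log_dens(const arma::mat& V, const arma::mat& mu,
                          const arma::cube& Sig) {
  const int n = V.n_rows, q = V.n_cols, K = mu.n_rows;
  arma::mat L(n, K);
  const double c0 = -0.5 * q * std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    arma::mat R = arma::chol(Sig.slice(k));
    arma::mat D = V.each_row() - mu.row(k);
    arma::mat Y = arma::solve(arma::trimatl(R.t()), D.t());
    L.col(k) = c0 - arma::accu(arma::log(R.diag()))
      - 0.5 * arma::sum(arma::square(Y), 0).t();
  }
  return L;
}

// ICM-EM for the spatial GMM with a Potts label prior.
// V: n x q factors; nbr_idx/nbr_ptr: 0-based CSR neighbor lists of the
// symmetrized knn graph; labels_init: 1..K. Alternates (a) ICM sweeps
// z_i = argmax_k [log N(v_i; mu_k, Sigma_k) - beta * #{j in N_i: z_j != k}]
// until stable (max icm_sweeps), and (b) moment M-steps from the hard
// labels, until the labels stop changing or max_iter. Empty components
// are re-seeded at the point with the lowest max-responsibility.
// [[Rcpp::export]]
List icm_em_cpp(const arma::mat& V, const arma::ivec& nbr_idx,
                const arma::ivec& nbr_ptr, int K, double beta,
                arma::ivec labels, int max_iter, int icm_sweeps,
                double ridge, double min_eig) {
  const int n = V.n_rows, q = V.n_cols;
  arma::mat mu(K, q);
  arma::cube Sig(q, q, K);
  int n_ridge = 0, n_reseed = 0;
  arma::mat L(n, K);
  std::vector<double> joint_trace;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // (b') moments from current hard labels, with empty-class re-seeding
    for (int k = 0; k < K; ++k) {
      if (arma::accu(labels == k + 1) == 0) {
        // lowest max-responsibility point = worst-fit point under the
        // current score matrix (fall back to farthest from overall mean)
        int worst = 0;
        if (iter > 0) {
          arma::vec best = arma::max(L, 1);
          worst = (int)best.index_min();
        } else {
          arma::rowvec m = arma::mean(V, 0);
          arma::vec d2 = arma::sum(arma::square(V.each_row() - m), 1);
          worst = (int)d2.index_max();
        }
        labels(worst) = k + 1;
        ++n_reseed;
      }
    }
    mstep_moments(V, labels, K, mu, Sig, ridge, min_eig, n_ridge);
    L = log_dens(V, mu, Sig);

    // (a) ICM sweeps
    arma::ivec before = labels;
    for (int s = 0; s < icm_sweeps; ++s) {
      bool changed = false;
      for (int i = 0; i < n; ++i) {
        int deg = nbr_ptr(i + 1) - nbr_ptr(i);
        int best_k = 0;
        double best_s = -arma::datum::inf;
        for (int k = 0; k < K; ++k) {
          int agree = 0;
          for (int t = nbr_ptr(i); t < nbr_ptr(i + 1); ++t)
            if (labels(nbr_idx(t)) == k + 1) ++agree;
          double sc = L(i, k) - beta * (double)(deg - agree);
          if (sc > best_s) { best_s = sc; best_k = k; }  // ties keep smaller k
        }
        if (labels(i) != best_k + 1) { labels(i) = best_k + 1; changed = true; }
      }
      if (!changed) break;
    }

    // joint objective: sum_i L(i, z_i) - (beta/2) * sum_i disagree(i, z_i)
    double jo = 0.0;
    for (int i = 0; i < n; ++i) {
      int zi = labels(i);
      jo += L(i, zi - 1);
      int agree = 0;
      for (int t = nbr_ptr(i); t < nbr_ptr(i + 1); ++t)
        if (labels(nbr_idx(t)) == zi) ++agree;
      jo -= 0.5 * beta * (double)(nbr_ptr(i + 1) - nbr_ptr(i) - agree);
    }
    joint_trace.push_back(jo);

    if (arma::all(before == labels)) { converged = true; break; }
  }

  // refresh moments and densities at the final labels
  mstep_moments(V, labels, K, mu, Sig, ridge, min_eig, n_ridge);
  L = log_dens(V, mu, Sig);

  // responsibilities: softmax_k [L(i,k) - beta * disagree(i,k)];
  // pseudo-likelihood: sum_i log[ sum_k N_ik exp(-beta d_ik)
  //                               / sum_k exp(-beta d_ik) ]
  arma::mat resp(n, K);
  double pll = 0.0;
  for (int i = 0; i < n; ++i) {
    arma::rowvec s(K);
    double lse_prior = 0.0;
    arma::rowvec pr(K);
    for (int k = 0; k < K; ++k) {
      int agree = 0;
      for (int t = nbr_ptr(i); t < nbr_ptr(i + 1); ++t)
        if (labels(nbr_idx(t)) == k + 1) ++agree;
      double d = (double)(nbr_ptr(i + 1) - nbr_ptr(i) - agree);
      s(k) = L(i, k) - beta * d;
      pr(k) = -beta * d;
    }
    double m = s.max();
    arma::rowvec e = arma::exp(s - m);
    resp.row(i) = e / arma::accu(e);
    double mp = pr.max();
    lse_prior = mp + std::log(arma::accu(arma::exp(pr - mp)));
    pll += m + std::log(arma::accu(e)) - lse_prior;
  }

  return List::create(
    _["labels"] = IntegerVector(labels.begin(), labels.end()),
    _["means"] = mu, _["covs"] = Sig, _["responsibilities"] = resp,
    _["pseudo_loglik"] = pll,
    _["joint_trace"] = NumericVector(joint_trace.begin(), joint_trace.end()),
    _["n_iter"] = iter + 1, _["converged"] = converged,
    _["n_ridge"] = n_ridge, _["n_reseed"] = n_reseed);
}
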