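// Multivariate Brownian-motion likelihood (Felsenstein pruning) and the
// reversible-jump MCMC over branch/clade rate-scalar configurations.
//
// Conventions shared with the R wrappers:
//  * nodes are 0-based here: tips 0..ntip-1, internals ntip..ntip+nnode-1;
//  * `post0` lists edge indices in postorder (children before parents);
//  * `g` is the per-edge log effective scalar; when `center` is true the
//    likelihood uses g - mean(g), fixing the geometric mean of effective
//    scalars to 1 (relative rates; the trait covariance R absorbs scale);
//  * a clade event with focal edge e covers cover[e] (the edges strictly
//    below e's child node, excluding e itself); a branch event covers {e}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

namespace {

struct TreeData {
  int ntip, nnode, nedge, p;
  arma::imat edge;   // nedge x 2, 0-based node ids
  arma::vec tlen;
  arma::ivec post;   // 0-based edge indices, postorder
  arma::mat X;       // ntip x p
};

// Pruning log-likelihood of the variable-rates multivariate BM model.
// Contrast k with scalar variance V contributes
//   -0.5 * (p*(log(2*pi) + log V) + log|R| + d' R^{-1} d / V).
double pruning_loglik(const TreeData& td, const arma::vec& g,
                      const arma::mat& Rinv, double logdetR,
                      const arma::vec& root, bool center) {
  const int N = td.ntip + td.nnode;
  const int p = td.p;
  double gbar = center ? arma::mean(g) : 0.0;
  arma::mat m(N, p, arma::fill::zeros);
  arma::vec v(N, arma::fill::zeros);
  std::vector<char> has(N, 0);
  double ll = 0.0;
  for (int k = 0; k < td.nedge; ++k) {
    const int e = td.post(k);
    const int par = td.edge(e, 0), ch = td.edge(e, 1);
    arma::rowvec mm;
    double mv;
    if (ch < td.ntip) { mm = td.X.row(ch); mv = 0.0; }
    else              { mm = m.row(ch);    mv = v(ch); }
    const double vb = std::exp(g(e) - gbar) * td.tlen(e);
    const double Vmsg = mv + vb;
    if (!has[par]) {
      m.row(par) = mm; v(par) = Vmsg; has[par] = 1;
    } else {
      double Vs = v(par) + Vmsg;
      if (Vs < 1e-12) Vs = 1e-12;  // guard: coincident zero-length children
      const arma::rowvec d = mm - m.row(par);
      const double qf = arma::as_scalar(d * Rinv * d.t());
      ll += -0.5 * (p * (LOG2PI + std::log(Vs)) + logdetR + qf / Vs);
      m.row(par) = (Vmsg * m.row(par) + v(par) * mm) / Vs;
      v(par) = v(par) * Vmsg / Vs;
    }
  }
  const int rootnode = td.edge(td.post(td.nedge - 1), 0);
  double Vr = v(rootnode);
  if (Vr < 1e-12) Vr = 1e-12;
  const arma::rowvec d = m.row(rootnode) - root.t();
  const double qf = arma::as_scalar(d * Rinv * d.t());
  ll += -0.5 * (p * (LOG2PI + std::log(Vr)) + logdetR + qf / Vr);
  return ll;
}

TreeData make_tree_data(const IntegerMatrix& edge0, const NumericVector& tlen,
                        const IntegerVector& post0, int ntip,
                        const NumericMatrix& X) {
  TreeData td;
  td.nedge = edge0.nrow();
  td.ntip = ntip;
  td.p = X.ncol();
  td.edge.set_size(td.nedge, 2);
  for (int i = 0; i < td.nedge; ++i) {
    td.edge(i, 0) = edge0(i, 0);
    td.edge(i, 1) = edge0(i, 1);
  }
  int maxnode = td.edge.max();
  td.nnode = maxnode + 1 - ntip;
  td.tlen = as<arma::vec>(tlen);
  td.post = as<arma::ivec>(post0);
  td.X = as<arma::mat>(X);
  return td;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_pruning_loglik")]]
double cpp_pruning_loglik(IntegerMatrix edge0, NumericVector tlen,
                          IntegerVector post0, int ntip, NumericMatrix X,
                          NumericVector g, NumericMatrix R, NumericVector root,
                          bool center) {
  TreeData td = make_tree_data(edge0, tlen, post0, ntip, X);
  arma::mat Rm = as<arma::mat>(R);
  arma::mat Rinv;
  if (!arma::inv_sympd(Rinv, Rm))
    stop("trait covariance R is not positive definite");
  double sign, logdetR;
  arma::log_det(logdetR, sign, Rm);
  if (sign <= 0) stop("trait covariance R is not positive definite");
  return pruning_loglik(td, as<arma::vec>(g), Rinv, logdetR,
                        as<arma::vec>(root), center);
}

namespace {

struct Event {
  int type;   // 0 = branch, 1 = clade
  int edge;
  double logr;
};

struct RState {
  arma::mat L;      // lower-triangular Cholesky of R
  arma::mat Rinv;
  double logdetR;
  void refresh() {
    arma::mat R = L * L.t();
    arma::inv_sympd(Rinv, R);
    double sign;
    arma::log_det(logdetR, sign, R);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_rjmcmc")]]
List cpp_rjmcmc(IntegerMatrix edge0, NumericVector tlen, IntegerVector post0,
                int ntip, NumericMatrix X, List cover0, LogicalVector clade_ok,
                int iterations, int thin, double poisson_mean,
                double scalar_sd, NumericVector move_probs,
                double step_scalar, double step_R, double step_root,
                double theta_prior_sd, double root_prior_sd,
                NumericVector init_theta, NumericVector init_root,
                bool prior_only) {
  TreeData td = make_tree_data(edge0, tlen, post0, ntip, X);
  const int nedge = td.nedge, p = td.p;

  // coverage sets per potential clade-focal edge
  std::vector<std::vector<int>> cover(nedge);
  for (int e = 0; e < nedge; ++e) {
    IntegerVector cv = cover0[e];
    cover[e] = as<std::vector<int>>(cv);
  }
  std::vector<char> cladeok(nedge);
  int n_clade_slots = 0;
  for (int e = 0; e < nedge; ++e) {
    cladeok[e] = clade_ok[e] ? 1 : 0;
    if (cladeok[e]) ++n_clade_slots;
  }
  const int S = nedge + n_clade_slots;  // total (edge, type) slots

  // state
  std::vector<Event> events;
  std::vector<char> occ_branch(nedge, 0), occ_clade(nedge, 0);
  arma::vec g(nedge, arma::fill::zeros);

  const int ntheta = p * (p + 1) / 2;
  arma::vec theta = as<arma::vec>(init_theta);
  arma::vec root = as<arma::vec>(init_root);
  // theta layout: diagonals (log scale) first, then row-major lower off-diags
  auto build_L = [&](const arma::vec& th) {
    arma::mat L(p, p, arma::fill::zeros);
    for (int i = 0; i < p; ++i) L(i, i) = std::exp(th(i));
    int k = p;
    for (int i = 1; i < p; ++i)
      for (int j = 0; j < i; ++j) L(i, j) = th(k++);
    return L;
  };
  RState rs;
  rs.L = build_L(theta);
  rs.refresh();

  auto loglik = [&]() {
    if (prior_only) return 0.0;
    return pruning_loglik(td, g, rs.Rinv, rs.logdetR, root, true);
  };
  double ll = loglik();
  if (!std::isfinite(ll)) stop("initial log-likelihood is not finite");

  auto apply_event = [&](const Event& ev, double sign) {
    if (ev.type == 0) {
      g(ev.edge) += sign * ev.logr;
    } else {
      for (int e : cover[ev.edge]) g(e) += sign * ev.logr;
    }
  };
  auto slot_free = [&](int type, int e) {
    if (type == 0) return !occ_branch[e];
    return cladeok[e] && !occ_clade[e];
  };

  // cumulative move probabilities
  arma::vec mp = as<arma::vec>(move_probs);
  mp /= arma::accu(mp);
  arma::vec cmp = arma::cumsum(mp);

  const int n_samples = iterations / thin;
  arma::ivec samp_iter(n_samples), samp_K(n_samples);
  arma::vec samp_ll(n_samples);
  arma::mat samp_g(n_samples, nedge);
  arma::imat cov_any(n_samples, nedge, arma::fill::zeros);
  arma::imat cov_branch(n_samples, nedge, arma::fill::zeros);
  arma::imat clade_focal(n_samples, nedge, arma::fill::zeros);
  arma::mat samp_R(n_samples, p * p);
  arma::mat samp_root(n_samples, p);
  std::vector<int> ev_sample, ev_type, ev_edge;
  std::vector<double> ev_logr;

  arma::ivec prop_n(6, arma::fill::zeros), acc_n(6, arma::fill::zeros);
  RNGScope scope;

  for (int it = 0; it < iterations; ++it) {
    const double u = unif_rand();
    int mv = 0;
    while (mv < 5 && u > cmp(mv)) ++mv;
    prop_n(mv)++;
    const int K = static_cast<int>(events.size());

    if (mv == 0) {  // birth
      const int nfree = S - K;
      if (nfree > 0) {
        int pick = static_cast<int>(unif_rand() * nfree);
        if (pick >= nfree) pick = nfree - 1;
        Event ev{0, -1, 0.0};
        int cnt = 0;
        for (int e = 0; e < nedge && ev.edge < 0; ++e)
          if (!occ_branch[e] && cnt++ == pick) { ev.type = 0; ev.edge = e; }
        for (int e = 0; e < nedge && ev.edge < 0; ++e)
          if (cladeok[e] && !occ_clade[e] && cnt++ == pick) {
            ev.type = 1; ev.edge = e;
          }
        ev.logr = norm_rand() * scalar_sd;
        apply_event(ev, +1.0);
        const double ll_new = loglik();
        const double logacc =
            (ll_new - ll) + std::log(poisson_mean) - std::log(K + 1.0);
        if (std::log(unif_rand()) < logacc) {
          events.push_back(ev);
          (ev.type == 0 ? occ_branch : occ_clade)[ev.edge] = 1;
          ll = ll_new;
          acc_n(mv)++;
        } else {
          apply_event(ev, -1.0);
        }
      }
    } else if (mv == 1) {  // death
      if (K > 0) {
        int pick = static_cast<int>(unif_rand() * K);
        if (pick >= K) pick = K - 1;
        Event ev = events[pick];
        apply_event(ev, -1.0);
        const double ll_new = loglik();
        const double logacc =
            (ll_new - ll) + std::log(static_cast<double>(K)) -
            std::log(poisson_mean);
        if (std::log(unif_rand()) < logacc) {
          (ev.type == 0 ? occ_branch : occ_clade)[ev.edge] = 0;
          events.erase(events.begin() + pick);
          ll = ll_new;
          acc_n(mv)++;
        } else {
          apply_event(ev, +1.0);
        }
      }
    } else if (mv == 2) {  // resize scalar
      if (K > 0) {
        int pick = static_cast<int>(unif_rand() * K);
        if (pick >= K) pick = K - 1;
        Event& ev = events[pick];
        const double old_logr = ev.logr;
        const double new_logr = old_logr + norm_rand() * step_scalar;
        Event delta{ev.type, ev.edge, new_logr - old_logr};
        apply_event(delta, +1.0);
        const double ll_new = loglik();
        const double logprior =
            -(new_logr * new_logr - old_logr * old_logr) /
            (2.0 * scalar_sd * scalar_sd);
        if (std::log(unif_rand()) < (ll_new - ll) + logprior) {
          ev.logr = new_logr;
          ll = ll_new;
          acc_n(mv)++;
        } else {
          apply_event(delta, -1.0);
        }
      }
    } else if (mv == 3) {  // move shift to a free slot of the same type
      if (K > 0) {
        int pick = static_cast<int>(unif_rand() * K);
        if (pick >= K) pick = K - 1;
        Event& ev = events[pick];
        int nfree = 0;
        for (int e = 0; e < nedge; ++e)
          if (slot_free(ev.type, e)) ++nfree;
        if (nfree > 0) {
          int tgt = static_cast<int>(unif_rand() * nfree);
          if (tgt >= nfree) tgt = nfree - 1;
          int dest = -1, cnt = 0;
          for (int e = 0; e < nedge && dest < 0; ++e)
            if (slot_free(ev.type, e) && cnt++ == tgt) dest = e;
          Event ev_old = ev;
          Event ev_new{ev.type, dest, ev.logr};
          apply_event(ev_old, -1.0);
          apply_event(ev_new, +1.0);
          const double ll_new = loglik();
          if (std::log(unif_rand()) < (ll_new - ll)) {
            (ev.type == 0 ? occ_branch : occ_clade)[ev_old.edge] = 0;
            (ev.type == 0 ? occ_branch : occ_clade)[dest] = 1;
            ev.edge = dest;
            ll = ll_new;
            acc_n(mv)++;
          } else {
            apply_event(ev_new, -1.0);
            apply_event(ev_old, +1.0);
          }
        }
      }
    } else if (mv == 4) {  // trait covariance via Cholesky element
      int idx = static_cast<int>(unif_rand() * ntheta);
      if (idx >= ntheta) idx = ntheta - 1;
      const double old_th = theta(idx);
      theta(idx) = old_th + norm_rand() * step_R;
      RState rs_old = rs;
      rs.L = build_L(theta);
      rs.refresh();
      const double ll_new = loglik();
      const double logprior =
          -(theta(idx) * theta(idx) - old_th * old_th) /
          (2.0 * theta_prior_sd * theta_prior_sd);
      if (std::log(unif_rand()) < (ll_new - ll) + logprior) {
        ll = ll_new;
        acc_n(mv)++;
      } else {
        theta(idx) = old_th;
        rs = rs_old;
      }
    } else {  // root state
      int idx = static_cast<int>(unif_rand() * p);
      if (idx >= p) idx = p - 1;
      const double old_a = root(idx);
      root(idx) = old_a + norm_rand() * step_root;
      const double ll_new = loglik();
      const double logprior =
          -(root(idx) * root(idx) - old_a * old_a) /
          (2.0 * root_prior_sd * root_prior_sd);
      if (std::log(unif_rand()) < (ll_new - ll) + logprior) {
        ll = ll_new;
        acc_n(mv)++;
      } else {
        root(idx) = old_a;
      }
    }

    if ((it + 1) % thin == 0) {
      const int s = (it + 1) / thin - 1;
      samp_iter(s) = it + 1;
      samp_K(s) = static_cast<int>(events.size());
      samp_ll(s) = ll;
      samp_g.row(s) = (g - arma::mean(g)).t();
      for (const Event& ev : events) {
        ev_sample.push_back(s + 1);
        ev_type.push_back(ev.type);
        ev_edge.push_back(ev.edge + 1);
        ev_logr.push_back(ev.logr);
        if (ev.type == 0) {
          cov_any(s, ev.edge) = 1;
          cov_branch(s, ev.edge) = 1;
        } else {
          clade_focal(s, ev.edge) = 1;
          for (int e : cover[ev.edge]) cov_any(s, e) = 1;
        }
      }
      arma::mat R = rs.L * rs.L.t();
      samp_R.row(s) = arma::vectorise(R).t();
      samp_root.row(s) = root.t();
    }
  }

  return List::create(
      _["iter"] = samp_iter, _["K"] = samp_K, _["loglik"] = samp_ll,
      _["log_scalars"] = samp_g, _["cover_any"] = cov_any,
      _["cover_branch"] = cov_branch, _["clade_focal"] = clade_focal,
      _["R"] = samp_R, _["root"] = samp_root,
      _["event_sample"] = wrap(ev_sample), _["event_type"] = wrap(ev_type),
      _["event_edge"] = wrap(ev_edge), _["event_logr"] = wrap(ev_logr),
      _["proposed"] = prop_n, _["accepted"] = acc_n);
}
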