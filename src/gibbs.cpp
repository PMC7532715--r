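// Gibbs sampler for the phylogenetic animal model with two relatedness
// matrices (common ancestry A, gene flow H), group fixed effects, known
// per-observation measurement-error variances and an iid residual:
//
//   y_i = x_i' beta + a_i + h_i + m_i + e_i,
//   a ~ N(0, s2a * A), h ~ N(0, s2b * H), m_i ~ N(0, mev_i) fixed,
//   e_i ~ N(0, s2e).
//
// The location effects (beta, a, h) are updated jointly in one block --
// a and h are individually weakly identified (only their sum enters the
// likelihood) and single-site updates mix very slowly.  Variances are
// conjugate scaled-inverse-chi-square after augmenting e_i | (m_i + e_i).
// Uses R's RNG so set.seed() in R makes runs reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

// draw x ~ N(Prec^{-1} b, Prec^{-1}) given precision matrix
static arma::vec draw_gauss_prec(const arma::mat& Prec, const arma::vec& b) {
  arma::mat U;
  if (!arma::chol(U, Prec))
    stop("precision matrix not positive definite in Gibbs update");
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(b.n_elem));
}

// scaled-inverse-chi-square draw: (nu*V + ss) / chisq(nu + n)
static double draw_variance(double nu, double V, double ss, double n) {
  return (nu * V + ss) / R::rchisq(nu + n);
}

// [[Rcpp::export(name = ".gibbs_mm")]]
List gibbs_mm(const arma::vec& y, const arma::mat& X,
              const arma::mat& Ainv, const arma::mat& Hinv,
              const arma::vec& mev, const arma::uvec& gidx,
              double nu, double V, double beta_var,
              int niter, int burnin, int thin) {
  const int n = y.n_elem, p = X.n_cols, d = p + 2 * n;
  const int S = (niter - burnin) / thin;
  if (S < 1) stop("chain settings retain no samples");

  const arma::mat Xt = X.t();
  double vary = arma::var(y);
  double v0 = std::max(vary, 1e-6) / 3.0;
  arma::vec beta = arma::solve(Xt * X + 1e-8 * arma::eye(p, p), Xt * y);
  arma::vec a(n, arma::fill::zeros), h(n, arma::fill::zeros);
  double s2a = v0, s2b = v0, s2e = v0;
  const double guard = 1e6 * std::max(vary, 1e-6);

  arma::mat beta_s(S, p), group_s(S, p);
  arma::vec s2a_s(S), s2b_s(S), s2e_s(S), dev_s(S);
  arma::vec beta_mean(p, arma::fill::zeros), a_mean(n, arma::fill::zeros),
            h_mean(n, arma::fill::zeros);
  arma::vec gsize(p, arma::fill::zeros);
  for (int i = 0; i < n; ++i) gsize[gidx[i] - 1] += 1.0;

  arma::mat Prec(d, d);
  arma::vec b(d);
  const arma::span sb(0, p - 1), sa(p, p + n - 1), sh(p + n, d - 1);

  int kept = 0;
  for (int it = 1; it <= niter; ++it) {
    arma::vec Dinv = 1.0 / (s2e + mev);

    // ---- joint (beta, a, h) block update --------------------------------
    arma::mat DX = X.each_col() % Dinv;          // n x p
    Prec.zeros();
    Prec(sb, sb) = Xt * DX;
    Prec(sb, sb).diag() += 1.0 / beta_var;
    Prec(sa, sb) = DX;         Prec(sb, sa) = DX.t();
    Prec(sh, sb) = DX;         Prec(sb, sh) = DX.t();
    Prec(sa, sa) = Ainv / s2a; Prec(sa, sa).diag() += Dinv;
    Prec(sh, sh) = Hinv / s2b; Prec(sh, sh).diag() += Dinv;
    Prec(sa, sh) = arma::diagmat(Dinv);
    Prec(sh, sa) = arma::diagmat(Dinv);
    arma::vec Dy = Dinv % y;
    b(sb) = Xt * Dy;
    b(sa) = Dy;
    b(sh) = Dy;
    arma::vec theta = draw_gauss_prec(Prec, b);
    beta = theta(sb);
    a = theta(sa);
    h = theta(sh);
    arma::vec xb = X * beta;

    // ---- split the residual into measurement + iid parts, update s2e ----
    arma::vec c = y - xb - a - h;
    double ss_e = 0.0;
    for (int i = 0; i < n; ++i) {
      double e;
      if (mev[i] <= 0.0) {
        e = c[i];
      } else {
        double w = s2e / (s2e + mev[i]);
        e = R::rnorm(w * c[i], std::sqrt(w * mev[i]));
      }
      ss_e += e * e;
    }
    s2e = draw_variance(nu, V, ss_e, n);
    s2a = draw_variance(nu, V, arma::as_scalar(a.t() * Ainv * a), n);
    s2b = draw_variance(nu, V, arma::as_scalar(h.t() * Hinv * h), n);

    if (s2a > guard || s2b > guard || s2e > guard)
      stop("divergent chain: a variance sample exceeded 1e6 x data variance; "
           "consider a stronger variance prior");

    if (it > burnin && (it - burnin) % thin == 0) {
      beta_s.row(kept) = beta.t();
      s2a_s[kept] = s2a; s2b_s[kept] = s2b; s2e_s[kept] = s2e;
      // conditional Gaussian deviance given the location effects
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double vv = s2e + mev[i];
        dev += std::log(2.0 * M_PI * vv) + c[i] * c[i] / vv;
      }
      dev_s[kept] = dev;
      arma::vec gre(p, arma::fill::zeros);
      for (int i = 0; i < n; ++i) gre[gidx[i] - 1] += a[i] + h[i];
      group_s.row(kept) = (beta + gre / arma::clamp(gsize, 1.0, arma::datum::inf)).t();
      beta_mean += beta; a_mean += a; h_mean += h;
      ++kept;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  beta_mean /= kept; a_mean /= kept; h_mean /= kept;
  return List::create(
    _["beta"] = beta_s, _["sigma2_a"] = s2a_s, _["sigma2_b"] = s2b_s,
    _["sigma2_e"] = s2e_s, _["deviance"] = dev_s,
    _["group_level"] = group_s,
    _["beta_mean"] = beta_mean, _["a_mean"] = a_mean, _["h_mean"] = h_mean,
    _["retained"] = kept);
}
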