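// Exact (non-approximate) t-SNE with the stabilization contract used by the
// embedding module: at least `iter_min` gradient-descent iterations, then
// continue until the mean per-point displacement, averaged over a trailing
// window and normalized by the bounding-sphere radius of the current layout,
// drops below `stab_tol` (or a hard iteration cap is reached).
//
// Standard reference algorithm: symmetrized conditional affinities calibrated
// by per-point binary search on the Gaussian bandwidth, early exaggeration,
// momentum switch and adaptive gains. Own mt19937 RNG so results are a pure
// function of the seed.

#include <RcppArmadillo.h>
#include <random>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void clamp_floor0(mat& M) {
  M.transform([](double v) { return v < 0.0 ? 0.0 : v; });
}

static mat input_affinities(const mat& X, double perplexity) {
  const uword n = X.n_rows;
  vec sq = sum(square(X), 1);
  mat D = repmat(sq, 1, n) + repmat(sq.t(), n, 1) - 2.0 * (X * X.t());
  D.diag().zeros();
  clamp_floor0(D);

  const double logU = std::log(perplexity);
  mat P(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0;
    double betamin = -datum::inf, betamax = datum::inf;
    rowvec Di = D.row(i);
    rowvec Pi(n);
    for (int it = 0; it < 64; ++it) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP < 1e-300) sumP = 1e-300;
      double H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::abs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isinf(betamax) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = std::isinf(betamin) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    P.row(i) = Pi;
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  P.diag().fill(1e-12);
  P /= accu(P);
  return P;
}

// [[Rcpp::export(name = ".tsne_cpp")]]
Rcpp::List tsne_cpp(const arma::mat& X, double perplexity, double eta,
                    int seed, int dim = 3, int iter_min = 2500,
                    int iter_max = 50000, int stab_window = 50,
                    double stab_tol = 1e-4, int exaggeration_iter = 250,
                    double exaggeration = 12.0) {
  const uword n = X.n_rows;
  mat P = input_affinities(X, perplexity);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::normal_distribution<double> gauss(0.0, 1e-2);
  mat Y(n, dim);
  for (uword i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) Y(i, d) = gauss(rng);

  mat dY(n, dim, fill::zeros), iY(n, dim, fill::zeros),
      gains(n, dim, fill::ones);
  const double min_gain = 0.01;
  double momentum = 0.5;

  std::deque<double> window;
  double window_sum = 0.0;
  int iter = 0;
  mat PP = P * exaggeration;

  for (iter = 1; iter <= iter_max; ++iter) {
    if (iter == exaggeration_iter + 1) {
      PP = P;
      momentum = 0.8;
    }

    // Student-t affinities and gradient in one symmetric pairwise pass
    mat num(n, n);
    double sumQ = 0.0;
    for (uword i = 0; i < n; ++i) {
      num(i, i) = 0.0;
      for (uword j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int d = 0; d < dim; ++d) {
          double diff = Y(i, d) - Y(j, d);
          s += diff * diff;
        }
        double q = 1.0 / (1.0 + s);
        num(i, j) = q;
        num(j, i) = q;
        sumQ += 2.0 * q;
      }
    }
    if (sumQ < 1e-300) sumQ = 1e-300;

    dY.zeros();
    const double inv_sumQ = 1.0 / sumQ;
    for (uword i = 0; i < n; ++i) {
      for (uword j = i + 1; j < n; ++j) {
        double q = num(i, j);
        double coef = 4.0 * (PP(i, j) - q * inv_sumQ) * q;
        for (int d = 0; d < dim; ++d) {
          double diff = Y(i, d) - Y(j, d);
          dY(i, d) += coef * diff;
          dY(j, d) -= coef * diff;
        }
      }
    }

    mat flip = conv_to<mat>::from(sign(dY) != sign(iY));
    gains = (gains + 0.2) % flip + (gains * 0.8) % (1.0 - flip);
    gains.transform([min_gain](double v) { return v < min_gain ? min_gain : v; });
    iY = momentum * iY - eta * (gains % dY);
    Y += iY;
    Y.each_row() -= mean(Y, 0);

    // windowed mean displacement, normalized by bounding radius
    double disp = mean(sqrt(sum(square(iY), 1)));
    double radius = std::sqrt(max(sum(square(Y), 1)));
    double rel = (radius > 0) ? disp / radius : 0.0;
    window.push_back(rel);
    window_sum += rel;
    if ((int)window.size() > stab_window) {
      window_sum -= window.front();
      window.pop_front();
    }
    if (iter >= iter_min && (int)window.size() == stab_window &&
        window_sum / stab_window < stab_tol)
      break;
  }
  if (iter > iter_max) iter = iter_max;

  // final KL divergence against the unexaggerated P
  vec sq = sum(square(Y), 1);
  mat num = repmat(sq, 1, n) + repmat(sq.t(), n, 1) - 2.0 * (Y * Y.t());
  clamp_floor0(num);
  num = 1.0 / (1.0 + num);
  num.diag().zeros();
  mat Q = num / accu(num);
  Q.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  double kl = accu(P % log(P / Q));

  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("kl_divergence") = kl,
                            Rcpp::Named("iterations") = iter);
}
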