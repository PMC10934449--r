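// Full-batch Adam trainer for the single-hidden-layer "wide" network
// (ReLU hidden units, softmax output, L2 weight decay). Weight
// initialization happens in R so all randomness stays under R's RNG; this
// loop is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List widenn_train_cpp(const arma::mat& X, const arma::mat& Y,
                            arma::mat W1, arma::rowvec b1,
                            arma::mat W2, arma::rowvec b2,
                            const double decay, const int epochs,
                            const double lr) {
  const double n = X.n_rows;
  const double be1 = 0.9, be2 = 0.999, eps = 1e-8;
  mat mW1(size(W1), fill::zeros), vW1(size(W1), fill::zeros);
  mat mW2(size(W2), fill::zeros), vW2(size(W2), fill::zeros);
  rowvec mb1(size(b1), fill::zeros), vb1(size(b1), fill::zeros);
  rowvec mb2(size(b2), fill::zeros), vb2(size(b2), fill::zeros);

  for (int t = 1; t <= epochs; ++t) {
    mat H = X * W1;
    H.each_row() += b1;
    mat A = clamp(H, 0.0, datum::inf);
    mat O = A * W2;
    O.each_row() += b2;
    O.each_col() -= max(O, 1);
    mat P = exp(O);
    P.each_col() /= sum(P, 1);

    mat dO = (P - Y) / n;
    mat gW2 = A.t() * dO + decay * W2;
    rowvec gb2 = sum(dO, 0);
    mat dH = (dO * W2.t()) % conv_to<mat>::from(H > 0.0);
    mat gW1 = X.t() * dH + decay * W1;
    rowvec gb1 = sum(dH, 0);

    const double ct = lr * std::sqrt(1.0 - std::pow(be2, t)) /
                      (1.0 - std::pow(be1, t));
    mW1 = be1 * mW1 + (1 - be1) * gW1;  vW1 = be2 * vW1 + (1 - be2) * square(gW1);
    mW2 = be1 * mW2 + (1 - be1) * gW2;  vW2 = be2 * vW2 + (1 - be2) * square(gW2);
    mb1 = be1 * mb1 + (1 - be1) * gb1;  vb1 = be2 * vb1 + (1 - be2) * square(gb1);
    mb2 = be1 * mb2 + (1 - be1) * gb2;  vb2 = be2 * vb2 + (1 - be2) * square(gb2);
    W1 -= ct * mW1 / (sqrt(vW1) + eps);
    W2 -= ct * mW2 / (sqrt(vW2) + eps);
    b1 -= ct * mb1 / (sqrt(vb1) + eps);
    b2 -= ct * mb2 / (sqrt(vb2) + eps);
  }
  return Rcpp::List::create(Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
                            Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2);
}
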