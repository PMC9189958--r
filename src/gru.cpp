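// Hot loops of the recurrent layers: one direction of one GRU layer over a
// right-padded batch, forward and backward-through-time. Matrices are laid
// out with the (person, time) pair as rows in person-fastest order, i.e. row
// index b + B * t, matching R's flattening of a B x T x D array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List gru_fwd_cpp(const arma::mat& Xp, const arma::vec& maskv,
                       const arma::mat& Wh, const arma::vec& bh,
                       bool reverse, int B, int T, bool keep_cache) {
  const int H = Wh.n_rows;
  mat h(B, H, fill::zeros);
  mat Hout(B * T, H);
  mat cr, cz, cn, cahn, chprev;
  if (keep_cache) {
    cr.set_size(B * T, H); cz.set_size(B * T, H); cn.set_size(B * T, H);
    cahn.set_size(B * T, H); chprev.set_size(B * T, H);
  }
  for (int step = 0; step < T; ++step) {
    int t = reverse ? (T - 1 - step) : step;
    int r0 = t * B, r1 = t * B + B - 1;
    mat ah = h * Wh;
    ah.each_row() += bh.t();
    mat xi = Xp.rows(r0, r1);
    mat r = sigm(xi.cols(0, H - 1) + ah.cols(0, H - 1));
    mat z = sigm(xi.cols(H, 2 * H - 1) + ah.cols(H, 2 * H - 1));
    mat ahn = ah.cols(2 * H, 3 * H - 1);
    mat n = tanh(xi.cols(2 * H, 3 * H - 1) + r % ahn);
    vec m = maskv.subvec(r0, r1);
    mat hnew = (1.0 - z) % n + z % h;
    if (keep_cache) {
      cr.rows(r0, r1) = r; cz.rows(r0, r1) = z; cn.rows(r0, r1) = n;
      cahn.rows(r0, r1) = ahn; chprev.rows(r0, r1) = h;
    }
    hnew.each_col() %= m;
    h.each_col() %= (1.0 - m);
    h += hnew;
    Hout.rows(r0, r1) = h;
  }
  if (keep_cache)
    return Rcpp::List::create(Rcpp::Named("out") = Hout,
                              Rcpp::Named("r") = cr, Rcpp::Named("z") = cz,
                              Rcpp::Named("n") = cn, Rcpp::Named("ahn") = cahn,
                              Rcpp::Named("hprev") = chprev);
  return Rcpp::List::create(Rcpp::Named("out") = Hout);
}

// [[Rcpp::export]]
Rcpp::List gru_bwd_cpp(const arma::mat& dH, const arma::mat& cr,
                       const arma::mat& cz, const arma::mat& cn,
                       const arma::mat& cahn, const arma::mat& chprev,
                       const arma::vec& maskv, const arma::mat& Wh,
                       bool reverse, int B, int T) {
  const int H = Wh.n_rows;
  mat dXp(B * T, 3 * H);
  mat gWh(H, 3 * H, fill::zeros);
  rowvec gbh(3 * H, fill::zeros);
  mat dh(B, H, fill::zeros);
  mat WhT = Wh.t();
  for (int step = 0; step < T; ++step) {
    int t = reverse ? step : (T - 1 - step);
    int r0 = t * B, r1 = t * B + B - 1;
    dh += dH.rows(r0, r1);
    vec m = maskv.subvec(r0, r1);
    mat dhnew = dh; dhnew.each_col() %= m;
    mat dcarry = dh; dcarry.each_col() %= (1.0 - m);
    mat r = cr.rows(r0, r1), z = cz.rows(r0, r1), n = cn.rows(r0, r1);
    mat ahn = cahn.rows(r0, r1), hp = chprev.rows(r0, r1);
    mat dz = dhnew % (hp - n);
    mat dn = dhnew % (1.0 - z);
    mat dhp = dhnew % z + dcarry;
    mat dnpre = dn % (1.0 - n % n);
    mat dahn = dnpre % r;
    mat dr = dnpre % ahn;
    mat drpre = dr % r % (1.0 - r);
    mat dzpre = dz % z % (1.0 - z);
    mat dah = join_rows(drpre, dzpre, dahn);
    gWh += hp.t() * dah;
    gbh += sum(dah, 0);
    dXp.submat(r0, 0, r1, H - 1) = drpre;
    dXp.submat(r0, H, r1, 2 * H - 1) = dzpre;
    dXp.submat(r0, 2 * H, r1, 3 * H - 1) = dnpre;
    dh = dhp + dah * WhT;
  }
  return Rcpp::List::create(Rcpp::Named("dXp") = dXp,
                            Rcpp::Named("gWh") = gWh,
                            Rcpp::Named("gbh") = gbh);
}
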