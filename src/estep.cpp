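// E-step of the GPCCA EM algorithm with per-subject partial-observation
// algebra. For each subject only the observed rows participate in the
// likelihood; the d x d Woodbury matrix M = (I + W~' Psi~^-1 W~)^-1 keeps all
// per-subject solves at cost governed by d and by the observed sub-blocks of
// the block-diagonal Psi. Fully observed blocks reuse factorizations cached
// once per iteration; partially observed blocks use the Schur-complement
// identity Psi_oo^-1 = P_oo - P_om P_mm^-1 P_mo on the cached full-block
// inverse P = Psi_r^-1, so per-subject cost scales with the number of
// missing rows rather than with the block size. Rank-one second-moment
// accumulations are deferred and performed as single BLAS-3 products over
// the completed data at the end of the pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
Rcpp::List cpp_estep(const arma::mat& X,
                     const arma::umat& O,
                     const arma::uvec& bsizes,
                     const arma::mat& W,
                     const arma::vec& mu,
                     const Rcpp::List& Psi,
                     bool use_cache,
                     bool want_subject) {
  const uword m = X.n_rows, n = X.n_cols, d = W.n_cols, R = bsizes.n_elem;

  uvec off(R + 1);
  off(0) = 0;
  for (uword r = 0; r < R; ++r) off(r + 1) = off(r) + bsizes(r);
  if (off(R) != m) Rcpp::stop("block sizes do not sum to the number of rows");

  // per-iteration caches: P = Psi_r^-1, A = P W_r, W_r' A, log|Psi_r|
  field<mat> Psib(R), Pinv(R), A(R), WtA(R);
  vec logdet(R);
  for (uword r = 0; r < R; ++r) {
    Psib(r) = symmatu(Rcpp::as<mat>(Psi[r]));
    mat Pi;
    if (!inv_sympd(Pi, Psib(r)))
      Rcpp::stop("error covariance block %d is not positive definite", r + 1);
    Pinv(r) = Pi;
    double val;
    if (!log_det_sympd(val, Psib(r)))
      Rcpp::stop("error covariance block %d is not positive definite", r + 1);
    logdet(r) = val;
    const mat Wr = W.rows(off(r), off(r + 1) - 1);
    A(r) = Pi * Wr;
    WtA(r) = Wr.t() * A(r);
  }

  vec Sz(d, fill::zeros);
  mat Szz(d, d, fill::zeros), Sxz(m, d, fill::zeros);
  field<mat> Sxx(R);
  for (uword r = 0; r < R; ++r) Sxx(r).zeros(bsizes(r), bsizes(r));

  mat EzAll(d, n), ExAll(m, n);
  cube Mts, Ezzs, Exzs;
  if (want_subject) {
    Mts.set_size(d, d, n);
    Ezzs.set_size(d, d, n);
    Exzs.set_size(m, d, n);
  }

  double ll = 0.0;
  std::vector<uword> buf;

  for (uword k = 0; k < n; ++k) {
    mat Sk = eye(d, d);
    vec h(d, fill::zeros);
    double q = 0.0, ld = 0.0;
    uword mk = 0;
    field<uvec> mis(R);

    for (uword r = 0; r < R; ++r) {
      const uword b0 = off(r), mr = bsizes(r);
      buf.clear();
      for (uword i = 0; i < mr; ++i)
        if (!O(b0 + i, k)) buf.push_back(i);
      mis(r) = conv_to<uvec>::from(buf);
      const uword mm = mis(r).n_elem;
      if (mm == mr) continue; // modality entirely missing
      mk += mr - mm;

      // residual, zero at missing rows
      vec x0(mr, fill::zeros);
      for (uword i = 0; i < mr; ++i)
        if (O(b0 + i, k)) x0(i) = X(b0 + i, k) - mu(b0 + i);

      if (mm == 0 && use_cache) {
        Sk += WtA(r);
        h += A(r).t() * x0;
        q += dot(x0, Pinv(r) * x0);
        ld += logdet(r);
      } else if (use_cache) {
        const mat& P = Pinv(r);
        const uvec& mi = mis(r);
        const mat Wr = W.rows(b0, b0 + mr - 1);
        const mat Wm = Wr.rows(mi);
        // PY = P * Y with Y = [W_r (missing rows zeroed) | x0]
        mat PY = join_rows(A(r) - P.cols(mi) * Wm, P * x0);
        // T1 = Y' P Y = J' PY - J_mi' PY_mi
        mat J = join_rows(Wr, x0);
        mat Bm = PY.rows(mi); // = P_mo U_o
        mat T1 = J.t() * PY - J.rows(mi).t() * Bm;
        mat L = chol(symmatu(P.submat(mi, mi)), "lower");
        mat K = solve(trimatl(L), Bm);
        mat SV = T1 - K.t() * K;
        Sk += SV.submat(0, 0, d - 1, d - 1);
        h += SV.submat(0, d, d - 1, d);
        q += SV(d, d);
        // det(Psi_oo) = det(Psi_r) * det((Psi_r^-1)_mm)
        ld += logdet(r) + 2.0 * accu(log(L.diag()));
      } else {
        // reference path: factorize the observed sub-block directly
        uvec o(mr - mm);
        uword s = 0;
        for (uword i = 0; i < mr; ++i)
          if (O(b0 + i, k)) o(s++) = i;
        mat Wo(o.n_elem, d);
        vec res(o.n_elem);
        for (uword t = 0; t < o.n_elem; ++t) {
          Wo.row(t) = W.row(b0 + o(t));
          res(t) = x0(o(t));
        }
        mat V = join_rows(Wo, res);
        mat L = chol(symmatu(Psib(r).submat(o, o)), "lower");
        mat KV = solve(trimatl(L), V);
        mat SV = KV.t() * KV;
        Sk += SV.submat(0, 0, d - 1, d - 1);
        h += SV.submat(0, d, d - 1, d);
        q += SV(d, d);
        ld += 2.0 * accu(log(L.diag()));
      }
    }

    double lsk;
    mat Mt;
    if (!log_det_sympd(lsk, symmatu(Sk)) || !inv_sympd(Mt, symmatu(Sk)))
      Rcpp::stop("posterior precision not positive definite for subject %d", k + 1);
    vec Ez = Mt * h;
    if (mk > 0)
      ll += -0.5 * (mk * LOG2PI + ld + lsk + q - dot(h, Ez));
    if (!std::isfinite(ll))
      Rcpp::stop("non-finite log-likelihood contribution for subject %d", k + 1);

    Sz += Ez;
    Szz += Mt; // + Ez Ez' added in one product at the end
    EzAll.col(k) = Ez;

    vec Exk(m);
    for (uword i = 0; i < m; ++i)
      Exk(i) = O(i, k) ? X(i, k) : dot(W.row(i), Ez) + mu(i);
    ExAll.col(k) = Exk;

    mat Exzk;
    if (want_subject) Exzk = Exk * Ez.t();
    for (uword r = 0; r < R; ++r) {
      const uvec& mi = mis(r);
      if (mi.n_elem == 0) continue;
      const uword b0 = off(r);
      mat Wm(mi.n_elem, d);
      for (uword s = 0; s < mi.n_elem; ++s) Wm.row(s) = W.row(b0 + mi(s));
      mat WmM = Wm * Mt;
      for (uword s = 0; s < mi.n_elem; ++s) {
        Sxz.row(b0 + mi(s)) += WmM.row(s);
        if (want_subject) Exzk.row(b0 + mi(s)) += WmM.row(s);
      }
      // within-block second-moment correction for jointly missing pairs
      Sxx(r).submat(mi, mi) += WmM * Wm.t() + Psib(r).submat(mi, mi);
    }
    if (want_subject) {
      Mts.slice(k) = Mt;
      Ezzs.slice(k) = Mt + Ez * Ez.t();
      Exzs.slice(k) = Exzk;
    }
  }

  // deferred rank-one accumulations as BLAS-3 products
  vec Sx = sum(ExAll, 1);
  Szz += EzAll * EzAll.t();
  Sxz += ExAll * EzAll.t();
  for (uword r = 0; r < R; ++r) {
    const mat Exr = ExAll.rows(off(r), off(r + 1) - 1);
    Sxx(r) += Exr * Exr.t();
  }

  Rcpp::List Sxx_out(R);
  for (uword r = 0; r < R; ++r) Sxx_out[r] = Sxx(r);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("Ez") = EzAll,
      Rcpp::Named("Ex") = ExAll,
      Rcpp::Named("Sx") = Sx,
      Rcpp::Named("Sz") = Sz,
      Rcpp::Named("Szz") = Szz,
      Rcpp::Named("Sxz") = Sxz,
      Rcpp::Named("Sxx") = Sxx_out);
  if (want_subject) {
    out["M"] = Mts;
    out["Ezz"] = Ezzs;
    out["Exz"] = Exzs;
  }
  return out;
}
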