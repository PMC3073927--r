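#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Minimum RMSD over proper rotations + translations (Kabsch via SVD with a
// determinant correction so reflections are never used: mirror images are
// distinct conformers).
static double kabsch_rmsd(const arma::mat &A, const arma::mat &B) {
    const arma::uword n = A.n_rows;
    arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
    arma::mat Ac = A.each_row() - ca;
    arma::mat Bc = B.each_row() - cb;
    double E0 = arma::accu(Ac % Ac) + arma::accu(Bc % Bc);
    arma::mat C = Ac.t() * Bc;  // 3x3 covariance
    arma::mat U, V;
    arma::vec s;
    if (!arma::svd(U, s, V, C)) Rcpp::stop("SVD failed in RMSD computation");
    double d = arma::det(U) * arma::det(V) < 0 ? -1.0 : 1.0;
    double tr = s(0) + s(1) + d * s(2);
    double msd = (E0 - 2.0 * tr) / (double)n;
    if (msd < 0) msd = 0;
    return std::sqrt(msd);
}

//' @noRd
// [[Rcpp::export]]
double kabsch_rmsd_cpp(const arma::mat &A, const arma::mat &B) {
    if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
        Rcpp::stop("coordinate sets must be n x 3 with matching n");
    return kabsch_rmsd(A, B);
}

//' @noRd
// [[Rcpp::export]]
Rcpp::NumericVector rmsd_to_set_cpp(const arma::mat &A, Rcpp::List Bs) {
    Rcpp::NumericVector out(Bs.size());
    for (R_xlen_t i = 0; i < Bs.size(); ++i) {
        arma::mat B = Rcpp::as<arma::mat>(Bs[i]);
        if (B.n_rows != A.n_rows) Rcpp::stop("mismatched atom counts");
        out[i] = kabsch_rmsd(A, B);
    }
    return out;
}
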