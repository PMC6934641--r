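// Inner loops of the rotation-based parallel-beam projector.
//
// A volume rotated into the detector frame is handled as a cube of
// detector-parallel planes V(:,:,i), i indexing depth towards the detector.
// Each plane is blurred with a separable Gaussian whose width depends on the
// plane's distance to the detector (collimator-detector response), then the
// planes are summed along the ray axis.  The adjoint spreads a projection
// back into planes with the transposed kernels.  Kernel matrices are
// precomputed per depth on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".cdrBlurSum")]]
arma::mat cdr_blur_sum(const arma::cube& vol,
                       const arma::cube& ku,
                       const arma::cube& kv) {
    const arma::uword nd = vol.n_slices;
    arma::mat proj(vol.n_rows, vol.n_cols, arma::fill::zeros);
    for (arma::uword i = 0; i < nd; ++i) {
        proj += ku.slice(i) * vol.slice(i) * kv.slice(i).t();
    }
    return proj;
}

// [[Rcpp::export(name = ".cdrBlurSpread")]]
arma::cube cdr_blur_spread(const arma::mat& proj,
                           const arma::cube& ku,
                           const arma::cube& kv) {
    const arma::uword nd = ku.n_slices;
    arma::cube vol(proj.n_rows, proj.n_cols, nd);
    for (arma::uword i = 0; i < nd; ++i) {
        vol.slice(i) = ku.slice(i).t() * proj * kv.slice(i);
    }
    return vol;
}
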