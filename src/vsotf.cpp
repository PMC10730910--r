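// Through-focus VSOTF sweep.
//
// The optical transfer function is obtained as the inverse FFT of the
// point-spread function, itself |FFT(generalized pupil)|^2.  Two structural
// facts keep the sweep cheap: the pupil occupies a centred sub-block of the
// grid (pupil_fill <= 0.5), so the first column pass only touches the
// non-zero columns; and the CSF weight vanishes beyond the frequency cutoff,
// so the second row pass only has to produce the low-frequency OTF rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// fft2 of a complex matrix whose non-zero entries live in columns c0..c1.
static cx_mat fft2_colpruned(const cx_mat& X, uword c0, uword c1) {
  cx_mat Y(X.n_rows, X.n_cols, fill::zeros);
  Y.cols(c0, c1) = fft(X.cols(c0, c1));
  return strans(fft(strans(Y)));
}

// Rows of ifft2(PSF) listed in `rows` (0-based, must include row 0 first).
static cx_mat ifft2_rows(const mat& psf, const uvec& rows) {
  cx_mat C = ifft(cx_mat(psf, mat(size(psf), fill::zeros)));
  return strans(ifft(strans(C.rows(rows))));
}

// [[Rcpp::export]]
arma::vec cpp_vsotf_sweep(const arma::mat& opd_um,
                          const arma::mat& defocus_unit,
                          const arma::mat& mask,
                          const arma::vec& c20_um,
                          const double wavelength_um,
                          const arma::mat& weight_rows,
                          const arma::uvec& keep_rows) {
  const uword n = mask.n_rows;
  if (mask.n_cols != n || opd_um.n_rows != n || opd_um.n_cols != n ||
      defocus_unit.n_rows != n || defocus_unit.n_cols != n)
    Rcpp::stop("opd, defocus and mask matrices must be square and congruent");
  if (weight_rows.n_rows != keep_rows.n_elem || weight_rows.n_cols != n)
    Rcpp::stop("weight matrix must have one row per kept OTF row");
  if (keep_rows(0) != 0)
    Rcpp::stop("kept rows must start with the zero-frequency row");

  // column extent of the pupil support
  uvec nz = find(any(mask > 0, 0));
  if (nz.n_elem == 0) Rcpp::stop("empty pupil mask");
  const uword c0 = nz.min(), c1 = nz.max();

  // diffraction-limited reference through the identical numerical path
  cx_mat P0(mask, mat(size(mask), fill::zeros));
  mat psf0 = square(abs(fft2_colpruned(P0, c0, c1)));
  cx_mat otf0 = ifft2_rows(psf0, keep_rows);
  const double a0 = real(otf0(0, 0));
  const double denom = accu(weight_rows % (real(otf0) / a0));
  if (!(denom > 0)) Rcpp::stop("diffraction-limited weight integral is not positive");

  const double k = 2.0 * datum::pi / wavelength_um;
  const mat opdB = k * opd_um.cols(c0, c1);
  const mat defB = k * defocus_unit.cols(c0, c1);
  const mat maskB = mask.cols(c0, c1);
  vec out(c20_um.n_elem);
  cx_mat P(n, n, fill::zeros);
  for (uword i = 0; i < c20_um.n_elem; ++i) {
    mat phi = opdB + c20_um[i] * defB;
    P.cols(c0, c1) = cx_mat(maskB % cos(phi), maskB % sin(phi));
    mat psf = square(abs(fft2_colpruned(P, c0, c1)));
    cx_mat otf = ifft2_rows(psf, keep_rows);
    const double n0 = real(otf(0, 0));
    out[i] = accu(weight_rows % abs(real(otf) / n0)) / denom;
  }
  return out;
}
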