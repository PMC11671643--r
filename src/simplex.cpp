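// 2D simplex gradient noise (Perlin's simplex construction) with octave
// summation. The permutation table and per-octave lattice offsets come from
// the caller so that all randomness flows through R's RNG.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GRAD2[8][2] = {
  {1, 1}, {-1, 1}, {1, -1}, {-1, -1},
  {1, 0}, {-1, 0}, {0, 1}, {0, -1}
};

// perm: integer vector of length 512 (a 0..255 permutation repeated twice)
static double simplex2(double xin, double yin, const Rcpp::IntegerVector& perm) {
  static const double F2 = 0.5 * (std::sqrt(3.0) - 1.0);
  static const double G2 = (3.0 - std::sqrt(3.0)) / 6.0;

  const double s = (xin + yin) * F2;
  const int i = static_cast<int>(std::floor(xin + s));
  const int j = static_cast<int>(std::floor(yin + s));
  const double t = (i + j) * G2;
  const double x0 = xin - (i - t);
  const double y0 = yin - (j - t);

  const int i1 = x0 > y0 ? 1 : 0;
  const int j1 = 1 - i1;

  const double x1 = x0 - i1 + G2;
  const double y1 = y0 - j1 + G2;
  const double x2 = x0 - 1.0 + 2.0 * G2;
  const double y2 = y0 - 1.0 + 2.0 * G2;

  const int ii = i & 255;
  const int jj = j & 255;
  const int gi0 = perm[ii + perm[jj]] & 7;
  const int gi1 = perm[ii + i1 + perm[jj + j1]] & 7;
  const int gi2 = perm[ii + 1 + perm[jj + 1]] & 7;

  double n = 0.0;
  double t0 = 0.5 - x0 * x0 - y0 * y0;
  if (t0 > 0) {
    t0 *= t0;
    n += t0 * t0 * (GRAD2[gi0][0] * x0 + GRAD2[gi0][1] * y0);
  }
  double t1 = 0.5 - x1 * x1 - y1 * y1;
  if (t1 > 0) {
    t1 *= t1;
    n += t1 * t1 * (GRAD2[gi1][0] * x1 + GRAD2[gi1][1] * y1);
  }
  double t2 = 0.5 - x2 * x2 - y2 * y2;
  if (t2 > 0) {
    t2 *= t2;
    n += t2 * t2 * (GRAD2[gi2][0] * x2 + GRAD2[gi2][1] * y2);
  }
  return 70.0 * n;  // scales the raw kernel roughly into [-1, 1]
}

// offsets: octaves x 2 matrix of lattice translations (one per octave).
// [[Rcpp::export]]
arma::mat simplex_octaves_cpp(int height, int width, double freq, int octaves,
                              double decay, const Rcpp::IntegerVector& perm,
                              const arma::mat& offsets) {
  mat out(height, width, fill::zeros);
  double amp = 1.0;
  double f = freq;
  for (int k = 0; k < octaves; ++k) {
    const double ox = offsets(k, 0), oy = offsets(k, 1);
    for (int j = 0; j < width; ++j) {
      const double xj = (j + ox) * f;
      for (int i = 0; i < height; ++i) {
        out(i, j) += amp * simplex2(xj, (i + oy) * f, perm);
      }
    }
    amp *= decay;
    f *= 2.0;
  }
  return out;
}
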