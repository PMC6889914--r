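#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

// Direct-summation structure factors for both Friedel mates.
//
// F(h)  = sum_sites occ * (f0(s) + f' + i f'') * exp(-B s^2) *
//         sum_ops exp(2 pi i h.(R x + t))
// F(-h) uses the complex conjugate of the geometric sum but the same
// (complex) scattering factor, which is what breaks Friedel symmetry.
//
// hkl:    n x 3 integer Miller indices
// frac:   m x 3 fractional coordinates
// occ,b:  per-site occupancy and isotropic B (A^2)
// elidx:  per-site 0-based index into the element tables
// f0mat:  n x nel, f0 evaluated at each reflection's s for each element
// fp,fdp: per-element f' and f'' (electrons)
// s2:     per-reflection (sin theta / lambda)^2
// rot:    list of 3x3 rotation matrices, tra: list of translations
// [[Rcpp::export]]
ComplexMatrix cpp_structure_factors(IntegerMatrix hkl, NumericMatrix frac,
                                    NumericVector occ, NumericVector b,
                                    IntegerVector elidx, NumericMatrix f0mat,
                                    NumericVector fp, NumericVector fdp,
                                    NumericVector s2, List rot, List tra) {
  const int n = hkl.nrow(), m = frac.nrow(), nops = rot.size();
  const double twopi = 2.0 * M_PI;

  // per-op: hR (n x 3) and h.t (n)
  std::vector<std::vector<double>> hr(nops), ht(nops);
  for (int o = 0; o < nops; ++o) {
    NumericMatrix R = rot[o];
    NumericVector t = tra[o];
    hr[o].resize(3 * n);
    ht[o].resize(n);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k)
        hr[o][3 * i + k] = hkl(i, 0) * R(0, k) + hkl(i, 1) * R(1, k) + hkl(i, 2) * R(2, k);
      ht[o][i] = hkl(i, 0) * t[0] + hkl(i, 1) * t[1] + hkl(i, 2) * t[2];
    }
  }

  ComplexMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::complex<double> fplus(0, 0), fminus(0, 0);
    for (int j = 0; j < m; ++j) {
      double gr = 0, gi = 0;
      const double xj = frac(j, 0), yj = frac(j, 1), zj = frac(j, 2);
      for (int o = 0; o < nops; ++o) {
        double ph = twopi * (hr[o][3 * i] * xj + hr[o][3 * i + 1] * yj +
                             hr[o][3 * i + 2] * zj + ht[o][i]);
        gr += std::cos(ph);
        gi += std::sin(ph);
      }
      const int e = elidx[j];
      const std::complex<double> fel(f0mat(i, e) + fp[e], fdp[e]);
      const double w = occ[j] * std::exp(-b[j] * s2[i]);
      fplus  += w * fel * std::complex<double>(gr,  gi);
      fminus += w * fel * std::complex<double>(gr, -gi);
    }
    out(i, 0) = Rcomplex{fplus.real(), fplus.imag()};
    out(i, 1) = Rcomplex{fminus.real(), fminus.imag()};
  }
  return out;
}

// Bounded two-parameter (occupancy, B) Gauss-Newton refinement against
// |F_obs|, run independently from many random starts for a fixed number of
// cycles (no early stopping: the attractor structure is the readout).
//
// Fc_i = Frest_i + occ * exp(-B s2_i) * g_i, residual r_i = fobs_i - |Fc_i|,
// target sum w_i r_i^2.  Both Friedel mates are rows of the input vectors.
// [[Rcpp::export]]
NumericMatrix cpp_multistart_gn(NumericVector fobs, NumericVector w,
                                ComplexVector frest, ComplexVector g,
                                NumericVector s2, NumericVector occ0,
                                NumericVector b0, int n_cycles,
                                double occ_lo, double occ_hi,
                                double b_lo, double b_hi,
                                double damping) {
  const int n = fobs.size(), K = occ0.size();
  std::vector<double> frr(n), fri(n), gr(n), gi(n);
  for (int i = 0; i < n; ++i) {
    frr[i] = frest[i].r; fri[i] = frest[i].i;
    gr[i] = g[i].r; gi[i] = g[i].i;
  }
  NumericMatrix out(K, 2);
  for (int k = 0; k < K; ++k) {
    double occ = occ0[k], B = b0[k];
    for (int c = 0; c < n_cycles; ++c) {
      double a11 = 0, a12 = 0, a22 = 0, r1 = 0, r2 = 0;
      for (int i = 0; i < n; ++i) {
        const double dw = std::exp(-B * s2[i]);
        const double fcr = frr[i] + occ * dw * gr[i];
        const double fci = fri[i] + occ * dw * gi[i];
        const double amp2 = fcr * fcr + fci * fci;
        if (amp2 < 1e-24) continue;
        const double amp = std::sqrt(amp2);
        const double q = (fcr * gr[i] + fci * gi[i]) * dw / amp;
        const double jo = q;                // d|Fc|/d occ
        const double jb = -s2[i] * occ * q; // d|Fc|/d B
        const double r = fobs[i] - amp;
        const double wjo = w[i] * jo;
        a11 += wjo * jo;
        a12 += wjo * jb;
        a22 += w[i] * jb * jb;
        r1 += wjo * r;
        r2 += w[i] * jb * r;
      }
      // Levenberg damping: the occ-B normal matrix is near-singular along
      // the occupancy-B trade-off, and the damped step converges slowly
      // along that valley, preserving the attractor structure the
      // multi-start histogram reads out
      const double damp = damping * (a11 + a22) + 1e-30;
      a11 += damp; a22 += damp;
      const double det = a11 * a22 - a12 * a12;
      if (det <= 0 || !std::isfinite(det)) break;
      double d_occ = (a22 * r1 - a12 * r2) / det;
      double d_b = (a11 * r2 - a12 * r1) / det;
      // step limiting keeps wild starts inside the basin structure
      if (d_occ > 0.5) d_occ = 0.5; else if (d_occ < -0.5) d_occ = -0.5;
      if (d_b > 75) d_b = 75; else if (d_b < -75) d_b = -75;
      occ += d_occ; B += d_b;
      if (occ < occ_lo) occ = occ_lo; else if (occ > occ_hi) occ = occ_hi;
      if (B < b_lo) B = b_lo; else if (B > b_hi) B = b_hi;
    }
    out(k, 0) = occ;
    out(k, 1) = B;
  }
  return out;
}
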