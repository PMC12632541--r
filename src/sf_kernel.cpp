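#include <Rcpp.h>
using namespace Rcpp;

// Direct-summation scattering kernels. All kernels work on a single symmetry
// operator: HR is the (n_refl x 3) matrix of rotated Miller indices h %*% R,
// X the (n_atom x 3) fractional coordinates, coef the (n_refl x n_atom) real
// scattering coefficient occ * f(stol) * exp(-B stol^2). The caller loops
// over operators and applies the exp(2 pi i h.t) translation phase.

// Per-atom phase-factor tables over the integer Miller index range:
// exp(2 pi i (h x + k y + l z)) = px[h] * py[k] * pz[l], with each axis
// table built by repeated complex multiplication. Index ranges are small
// (|h| <= cell/d_min), so the tables cost nothing next to the reflection
// loop, which then needs only two complex multiplies per term.
struct PhaseTables {
  std::vector<std::complex<double> > px, py, pz;
  int h0, k0, l0;  // offsets (minimum indices)
  void build(double x, double y, double z,
             int hmin, int hmax, int kmin, int kmax, int lmin, int lmax) {
    h0 = hmin; k0 = kmin; l0 = lmin;
    fill(px, x, hmin, hmax);
    fill(py, y, kmin, kmax);
    fill(pz, z, lmin, lmax);
  }
  static void fill(std::vector<std::complex<double> >& p, double x,
                   int mn, int mx) {
    p.resize(mx - mn + 1);
    const std::complex<double> base = std::polar(1.0, 2.0 * M_PI * (x - std::floor(x)));
    // exact anchor at the minimum index, then ascending multiplication
    p[0] = std::polar(1.0, 2.0 * M_PI * mn * (x - std::floor(x)));
    for (int i = 1; i < (int)p.size(); ++i) p[i] = p[i - 1] * base;
  }
};

static void index_range(const NumericMatrix& HR, int* mn, int* mx) {
  for (int d = 0; d < 3; ++d) { mn[d] = 0; mx[d] = 0; }
  for (int h = 0; h < HR.nrow(); ++h)
    for (int d = 0; d < 3; ++d) {
      const int v = (int)std::lround(HR(h, d));
      if (v < mn[d]) mn[d] = v;
      if (v > mx[d]) mx[d] = v;
    }
}

// [[Rcpp::export]]
ComplexVector sf_forward(const NumericMatrix& HR, const NumericMatrix& X,
                         const NumericMatrix& coef) {
  const int nr = HR.nrow(), na = X.nrow();
  if (coef.nrow() != nr || coef.ncol() != na)
    stop("coef dimensions do not match reflections x atoms");
  int mn[3], mx[3];
  index_range(HR, mn, mx);
  std::vector<int> hi(nr), ki(nr), li(nr);
  for (int h = 0; h < nr; ++h) {
    hi[h] = (int)std::lround(HR(h, 0)) - mn[0];
    ki[h] = (int)std::lround(HR(h, 1)) - mn[1];
    li[h] = (int)std::lround(HR(h, 2)) - mn[2];
  }
  std::vector<double> fre(nr, 0.0), fim(nr, 0.0);
  PhaseTables pt;
  for (int a = 0; a < na; ++a) {
    pt.build(X(a, 0), X(a, 1), X(a, 2), mn[0], mx[0], mn[1], mx[1], mn[2], mx[2]);
    for (int h = 0; h < nr; ++h) {
      const std::complex<double> e = pt.px[hi[h]] * pt.py[ki[h]] * pt.pz[li[h]];
      const double c = coef(h, a);
      fre[h] += c * e.real();
      fim[h] += c * e.imag();
    }
  }
  ComplexVector out(nr);
  for (int h = 0; h < nr; ++h) {
    out[h].r = fre[h];
    out[h].i = fim[h];
  }
  return out;
}

// Chain-rule gradient of sum_h Re(pref_h * conj?) -- specifically the
// Cartesian gradient of L = sum_h dL/d|F_M|_h * |F_M|_h through this
// operator's contribution to F. pref_h must be
//   dL/d|F_M|_h * k_total * w_state * exp(-i phi_h) * exp(2 pi i h.t_op)
// and SR the (n_refl x 3) Cartesian scattering vectors of the rotated
// indices. Returns the (n_atom x 3) gradient.
// [[Rcpp::export]]
NumericMatrix sf_gradient(const NumericMatrix& HR, const NumericMatrix& X,
                          const NumericMatrix& coef,
                          const NumericVector& pref_re,
                          const NumericVector& pref_im,
                          const NumericMatrix& SR) {
  const int nr = HR.nrow(), na = X.nrow();
  if (coef.nrow() != nr || coef.ncol() != na)
    stop("coef dimensions do not match reflections x atoms");
  NumericMatrix G(na, 3);
  int mn[3], mx[3];
  index_range(HR, mn, mx);
  std::vector<int> hi(nr), ki(nr), li(nr);
  for (int h = 0; h < nr; ++h) {
    hi[h] = (int)std::lround(HR(h, 0)) - mn[0];
    ki[h] = (int)std::lround(HR(h, 1)) - mn[1];
    li[h] = (int)std::lround(HR(h, 2)) - mn[2];
  }
  PhaseTables pt;
  for (int a = 0; a < na; ++a) {
    pt.build(X(a, 0), X(a, 1), X(a, 2), mn[0], mx[0], mn[1], mx[1], mn[2], mx[2]);
    double g0 = 0.0, g1 = 0.0, g2 = 0.0;
    for (int h = 0; h < nr; ++h) {
      const std::complex<double> e = pt.px[hi[h]] * pt.py[ki[h]] * pt.pz[li[h]];
      // Re(pref * 2 pi i * coef * e^{ip}) = -2 pi coef (pr sin p + pi cos p)
      const double t = -2.0 * M_PI * coef(h, a) *
        (pref_re[h] * e.imag() + pref_im[h] * e.real());
      g0 += t * SR(h, 0);
      g1 += t * SR(h, 1);
      g2 += t * SR(h, 2);
    }
    G(a, 0) = g0;
    G(a, 1) = g1;
    G(a, 2) = g2;
  }
  return G;
}

// Minimum periodic distance from each grid voxel to any atom, for the flat
// bulk-solvent mask. Xf: fractional atom coordinates (n_atom x 3);
// ng: grid divisions per axis (length 3); M: 3x3 orthogonalization matrix
// (column-major as passed from R). Returns voxel-order (fastest axis first)
// vector of minimum distances in Angstrom.
// [[Rcpp::export]]
NumericVector mask_min_distance(const NumericMatrix& Xf,
                                const IntegerVector& ng,
                                const NumericMatrix& M) {
  const int n1 = ng[0], n2 = ng[1], n3 = ng[2];
  const int na = Xf.nrow();
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  R_xlen_t v = 0;
  for (int k = 0; k < n3; ++k) {
    const double fz = (double)k / n3;
    for (int j = 0; j < n2; ++j) {
      const double fy = (double)j / n2;
      for (int i = 0; i < n1; ++i) {
        const double fx = (double)i / n1;
        double best = R_PosInf;
        for (int a = 0; a < na; ++a) {
          double dx = fx - Xf(a, 0), dy = fy - Xf(a, 1), dz = fz - Xf(a, 2);
          dx -= std::round(dx); dy -= std::round(dy); dz -= std::round(dz);
          const double cx = M(0, 0) * dx + M(0, 1) * dy + M(0, 2) * dz;
          const double cy = M(1, 0) * dx + M(1, 1) * dy + M(1, 2) * dz;
          const double cz = M(2, 0) * dx + M(2, 1) * dy + M(2, 2) * dz;
          const double d2 = cx * cx + cy * cy + cz * cz;
          if (d2 < best) best = d2;
        }
        out[v++] = std::sqrt(best);
      }
    }
  }
  return out;
}

// Lennard-Jones energy and gradient over an explicit pair list with a
// switching function between r_on and r_off. eps/rmin are per-pair
// (pre-combined); scale allows 1-4 scaling. Returns list(energy, grad).
// [[Rcpp::export]]
List lj_pairs(const NumericMatrix& X, const IntegerMatrix& pairs,
              const NumericVector& eps, const NumericVector& rmin,
              const NumericVector& scale, double r_on, double r_off) {
  const int np = pairs.nrow(), na = X.nrow();
  NumericMatrix G(na, 3);
  double E = 0.0;
  const double ron2 = r_on * r_on, roff2 = r_off * r_off;
  const double denom = std::pow(roff2 - ron2, 3);
  for (int p = 0; p < np; ++p) {
    const int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    const double dx = X(i, 0) - X(j, 0);
    const double dy = X(i, 1) - X(j, 1);
    const double dz = X(i, 2) - X(j, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= roff2) continue;
    if (r2 < 1e-12) stop("singular contact: overlapping atoms in nonbonded pair");
    const double r = std::sqrt(r2);
    const double q = rmin[p] / r;
    const double q6 = q * q * q * q * q * q;
    const double q12 = q6 * q6;
    const double e = scale[p] * eps[p] * (q12 - 2.0 * q6);
    // dE/dr = scale*eps*(-12 q12 + 12 q6)/r
    double dedr = scale[p] * eps[p] * 12.0 * (q6 - q12) / r;
    double sw = 1.0, dswdr = 0.0;
    if (r2 > ron2) {
      const double a = roff2 - r2, b = roff2 + 2.0 * r2 - 3.0 * ron2;
      sw = a * a * b / denom;
      // d/dr2 [a^2 b] = -2 a b + 2 a^2 ; d/dr = 2r * that / denom
      dswdr = 2.0 * r * (-2.0 * a * b + 2.0 * a * a) / denom;
    }
    E += e * sw;
    const double coef = (dedr * sw + e * dswdr) / r;
    G(i, 0) += coef * dx; G(i, 1) += coef * dy; G(i, 2) += coef * dz;
    G(j, 0) -= coef * dx; G(j, 1) -= coef * dy; G(j, 2) -= coef * dz;
  }
  return List::create(_["energy"] = E, _["grad"] = G);
}
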