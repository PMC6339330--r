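#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Border policy throughout: edge replication. Window intensities are read at
// clamped coordinates while the spatial offset (d_x, d_y) keeps its nominal
// value, so every output pixel sees a full (2N+1)^2 window.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// binary-entropy term of the agreement probability, with 0*log(0) = 0
static inline double hterm(double p) {
  double q = 1.0 - p;
  double a = (p > 0.0) ? p * std::log(p) : 0.0;
  double b = (q > 0.0) ? q * std::log(q) : 0.0;
  return a + b;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  const int m = img.nrow(), n = img.ncol();
  const int w = 2 * radius + 1, ws = w * w;
  NumericMatrix out(m, n);
  std::vector<double> buf(ws);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      int k = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        const int cj = clampi(j + dj, 0, n - 1);
        for (int di = -radius; di <= radius; ++di)
          buf[k++] = img(clampi(i + di, 0, m - 1), cj);
      }
      std::nth_element(buf.begin(), buf.begin() + ws / 2, buf.end());
      out(i, j) = buf[ws / 2];
    }
  }
  return out;
}

// per-pixel agreement probability p and entropy terms h for the whole image
static void fill_p_h(const NumericMatrix& img, const NumericMatrix& med,
                     double maxI, std::vector<double>& h,
                     std::vector<double>& p) {
  const int m = img.nrow(), n = img.ncol();
  h.resize((size_t)m * n);
  p.resize((size_t)m * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      double d = 1.0 - std::fabs(img(i, j) - med(i, j)) / maxI;
      double pp = 0.5 * d * d + 0.5;
      p[(size_t)j * m + i] = pp;
      h[(size_t)j * m + i] = hterm(pp);
    }
}

// windowed entropy H at (i, j) from the global h buffer, replicated edges
static inline double entropy_at(const std::vector<double>& h, int m, int n,
                                int i, int j, int N) {
  double s = 0.0;
  for (int dj = -N; dj <= N; ++dj) {
    const int cj = clampi(j + dj, 0, n - 1);
    for (int di = -N; di <= N; ++di)
      s += h[(size_t)cj * m + clampi(i + di, 0, m - 1)];
  }
  return -s;
}

// Reference backend: per-pixel evaluation of the full collateral filter.
// `beta` is a per-pixel blend map (a scalar beta is expanded by the caller).
// [[Rcpp::export]]
NumericMatrix cpp_collateral_reference(NumericMatrix img, NumericMatrix med,
                                       int N, double sigma_s, double sigma_r,
                                       double sigma_m, NumericMatrix beta,
                                       double maxI) {
  const int m = img.nrow(), n = img.ncol();
  NumericMatrix out(m, n);
  std::vector<double> h, p;
  fill_p_h(img, med, maxI, h, p);
  const double as = -0.5 / (sigma_s * sigma_s);
  const double ar = -0.5 / (sigma_r * sigma_r);
  const double am = -0.5 / (sigma_m * sigma_m);
  // blend image B = (1 - beta) I + beta I^M
  NumericMatrix B(m, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i)
      B(i, j) = (1.0 - beta(i, j)) * img(i, j) + beta(i, j) * med(i, j);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      const double H = entropy_at(h, m, n, i, j, N);
      const double cr = 1.0 / (1.0 + H);
      const double Ic = img(i, j), Mc = med(i, j);
      // accumulate deviations from the center blend value so a constant
      // window returns the constant exactly
      const double Bc = B(i, j);
      double num = 0.0, den = 0.0;
      for (int dj = -N; dj <= N; ++dj) {
        const int cj = clampi(j + dj, 0, n - 1);
        for (int di = -N; di <= N; ++di) {
          const int ci = clampi(i + di, 0, m - 1);
          const double dr = img(ci, cj) - Ic;
          const double dm = med(ci, cj) - Mc;
          // log-space ensemble weight: (W^M)^H underflows for large H
          const double lw = as * (double)(di * di + dj * dj) +
                            cr * ar * dr * dr + H * am * dm * dm;
          const double w = std::exp(lw);
          num += w * (B(ci, cj) - Bc);
          den += w;
        }
      }
      out(i, j) = Bc + num / den;
    }
  }
  return out;
}

// Tiled backend: S x S output tiles with an N-pixel apron. Per tile, the
// entropy terms (HPB), blend values (BETA buffer) and apron intensities are
// staged once, the per-pixel entropy sum (HG) is taken from HPB, and spatial
// weights come from the (N+1)x(N+1) buffer WSB indexed by |d_x|, |d_y|.
// [[Rcpp::export]]
NumericMatrix cpp_collateral_tiled(NumericMatrix img, NumericMatrix med,
                                   int N, double sigma_s, double sigma_r,
                                   double sigma_m, NumericMatrix beta,
                                   double maxI, int tile_side) {
  const int m = img.nrow(), n = img.ncol(), S = tile_side;
  NumericMatrix out(m, n);
  const double as = -0.5 / (sigma_s * sigma_s);
  const double ar = -0.5 / (sigma_r * sigma_r);
  const double am = -0.5 / (sigma_m * sigma_m);
  // spatial weight buffer WSB(d_x, d_y), 0 <= d_x, d_y <= N
  std::vector<double> wsb((size_t)(N + 1) * (N + 1));
  for (int dy = 0; dy <= N; ++dy)
    for (int dx = 0; dx <= N; ++dx)
      wsb[(size_t)dy * (N + 1) + dx] = std::exp(as * (double)(dx * dx + dy * dy));
  const int A = S + 2 * N;  // apron side
  std::vector<double> hpb((size_t)A * A), bb((size_t)A * A),
      ai((size_t)A * A), amv((size_t)A * A);
  const int ktiles_i = (m + S - 1) / S, ktiles_j = (n + S - 1) / S;
  for (int tj = 0; tj < ktiles_j; ++tj) {
    const int c0 = tj * S, c1 = std::min(c0 + S, n);
    for (int ti = 0; ti < ktiles_i; ++ti) {
      const int r0 = ti * S, r1 = std::min(r0 + S, m);
      // stage the apron: intensities, median, blend and entropy terms
      for (int aj = 0; aj < c1 - c0 + 2 * N; ++aj) {
        const int gj = clampi(c0 - N + aj, 0, n - 1);
        for (int aiu = 0; aiu < r1 - r0 + 2 * N; ++aiu) {
          const int gi = clampi(r0 - N + aiu, 0, m - 1);
          const size_t k = (size_t)aj * A + aiu;
          const double iv = img(gi, gj), mv = med(gi, gj);
          ai[k] = iv;
          amv[k] = mv;
          double d = 1.0 - std::fabs(iv - mv) / maxI;
          hpb[k] = hterm(0.5 * d * d + 0.5);
          bb[k] = (1.0 - beta(gi, gj)) * iv + beta(gi, gj) * mv;
        }
      }
      // per output pixel of the tile
      for (int j = c0; j < c1; ++j) {
        const int lj = j - c0 + N;  // apron-local column
        for (int i = r0; i < r1; ++i) {
          const int li = i - r0 + N;
          // HG: windowed entropy from the staged terms. Apron reads step
          // outside the staged area only when the tile touches the image
          // border; those coordinates are clamped into the apron, which by
          // construction holds the replicated edge values there.
          double H = 0.0;
          for (int dj = -N; dj <= N; ++dj) {
            const int cj2 = clampi(lj + dj, 0, c1 - c0 + 2 * N - 1);
            for (int di = -N; di <= N; ++di)
              H += hpb[(size_t)cj2 * A +
                       clampi(li + di, 0, r1 - r0 + 2 * N - 1)];
          }
          H = -H;
          const double cr = 1.0 / (1.0 + H);
          const double Ic = ai[(size_t)lj * A + li];
          const double Mc = amv[(size_t)lj * A + li];
          const double Bc = bb[(size_t)lj * A + li];
          double num = 0.0, den = 0.0;
          for (int dj = -N; dj <= N; ++dj) {
            const int cj2 = clampi(lj + dj, 0, c1 - c0 + 2 * N - 1);
            for (int di = -N; di <= N; ++di) {
              const int ci2 = clampi(li + di, 0, r1 - r0 + 2 * N - 1);
              const size_t k = (size_t)cj2 * A + ci2;
              const double dr = ai[k] - Ic;
              const double dm = amv[k] - Mc;
              const double w =
                  wsb[(size_t)std::abs(dj) * (N + 1) + std::abs(di)] *
                  std::exp(cr * ar * dr * dr + H * am * dm * dm);
              num += w * (bb[k] - Bc);
              den += w;
            }
          }
          out(i, j) = Bc + num / den;
        }
      }
    }
  }
  return out;
}

// Brute-force grid search support: filters `noisy` with every parameter row
// and returns PSNR against `clean`. The entropy map, squared offset
// differences and clamped neighbor indices depend only on the image and N,
// so they are staged once for the whole grid.
// [[Rcpp::export]]
NumericVector cpp_collateral_grid(NumericMatrix noisy, NumericMatrix med,
                                  NumericMatrix clean, int N,
                                  NumericVector sigma_s, NumericVector sigma_r,
                                  NumericVector sigma_m, NumericVector beta,
                                  double maxI) {
  const int m = noisy.nrow(), n = noisy.ncol();
  const size_t np = (size_t)m * n;
  const int w = 2 * N + 1, noff = w * w;
  const int G = sigma_s.size();
  std::vector<double> h, p;
  fill_p_h(noisy, med, maxI, h, p);
  std::vector<double> H(np);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i)
      H[(size_t)j * m + i] = entropy_at(h, m, n, i, j, N);
  // per-offset staging
  std::vector<double> d2(noff), dr2(np * noff), dm2(np * noff);
  std::vector<int> nidx(np * noff);
  {
    int o = 0;
    for (int dj = -N; dj <= N; ++dj)
      for (int di = -N; di <= N; ++di, ++o) {
        d2[o] = (double)(di * di + dj * dj);
        for (int j = 0; j < n; ++j) {
          const int cj = clampi(j + dj, 0, n - 1);
          for (int i = 0; i < m; ++i) {
            const int ci = clampi(i + di, 0, m - 1);
            const size_t k = (size_t)j * m + i;
            const size_t kn = (size_t)cj * m + ci;
            const double a = noisy[kn] - noisy[k];
            const double b = med[kn] - med[k];
            dr2[(size_t)o * np + k] = a * a;
            dm2[(size_t)o * np + k] = b * b;
            nidx[(size_t)o * np + k] = (int)kn;
          }
        }
      }
  }
  NumericVector psnr(G);
  std::vector<double> B(np);
  for (int g = 0; g < G; ++g) {
    const double as = -0.5 / (sigma_s[g] * sigma_s[g]);
    const double ar = -0.5 / (sigma_r[g] * sigma_r[g]);
    const double am = -0.5 / (sigma_m[g] * sigma_m[g]);
    const double bet = beta[g];
    for (size_t k = 0; k < np; ++k)
      B[k] = (1.0 - bet) * noisy[k] + bet * med[k];
    double sse = 0.0;
    for (size_t k = 0; k < np; ++k) {
      const double cr = ar / (1.0 + H[k]);
      const double cm = am * H[k];
      const double Bc = B[k];
      double num = 0.0, den = 0.0;
      for (int o = 0; o < noff; ++o) {
        const size_t ko = (size_t)o * np + k;
        const double wv = std::exp(as * d2[o] + cr * dr2[ko] + cm * dm2[ko]);
        num += wv * (B[nidx[ko]] - Bc);
        den += wv;
      }
      const double e = Bc + num / den - clean[k];
      sse += e * e;
    }
    psnr[g] = (sse == 0.0) ? R_PosInf
                           : 10.0 * std::log10(maxI * maxI /
                                               (sse / (double)np));
  }
  return psnr;
}
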