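#include <Rcpp.h>
using namespace Rcpp;

// Eight neighbour offsets at unit radius, clockwise from top-left.
// Bit i of the positive/negative code corresponds to offset i.
static const int NB_DY[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int NB_DX[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

// SSD between the (2*ph+1)^2 patch at (y,x) in frame `fa` and the patch at
// (y+dy, x+dx) in frame `fb`; frames are h x w, column-major.
static inline double patch_ssd(const int* fa, const int* fb, int h,
                               int y, int x, int dy, int dx, int ph) {
  double s = 0.0;
  for (int ox = -ph; ox <= ph; ++ox) {
    const int* ca = fa + (size_t)(x + ox) * h;
    const int* cb = fb + (size_t)(x + dx + ox) * h;
    for (int oy = -ph; oy <= ph; ++oy) {
      double d = (double)ca[y + oy] - (double)cb[y + dy + oy];
      s += d * d;
    }
  }
  return s;
}

// Trit codes for a single pixel triple of frames; returns packed (bp, bm).
static inline void trit_pixel(const int* ft, const int* fm, const int* fp,
                              int h, int y, int x, int radius, int ph,
                              double tau, int* bp, int* bm) {
  int cp = 0, cm = 0;
  for (int i = 0; i < 8; ++i) {
    int dy = NB_DY[i] * radius, dx = NB_DX[i] * radius;
    double dminus = patch_ssd(ft, fm, h, y, x, dy, dx, ph);
    double dplus = patch_ssd(ft, fp, h, y, x, dy, dx, ph);
    if (dminus - dplus > tau) cp |= (1 << i);
    else if (dplus - dminus > tau) cm |= (1 << i);
  }
  *bp = cp;
  *bm = cm;
}

//' @noRd
// [[Rcpp::export]]
List ltp_trit_codes_cpp(IntegerVector frames, int h, int w, int nframes,
                        int t, int delta, int patch_half, int radius,
                        double tau) {
  if (t < delta || t > nframes - 1 - delta)
    stop("frame index out of temporal range");
  const int* f0 = INTEGER(frames);
  const int* ft = f0 + (size_t)t * h * w;
  const int* fm = f0 + (size_t)(t - delta) * h * w;
  const int* fp = f0 + (size_t)(t + delta) * h * w;
  int m = patch_half + radius;
  IntegerMatrix bpm(h, w), bmm(h, w);
  std::fill(bpm.begin(), bpm.end(), NA_INTEGER);
  std::fill(bmm.begin(), bmm.end(), NA_INTEGER);
  for (int x = m; x < w - m; ++x) {
    for (int y = m; y < h - m; ++y) {
      int bp, bm;
      trit_pixel(ft, fm, fp, h, y, x, radius, patch_half, tau, &bp, &bm);
      bpm(y, x) = bp;
      bmm(y, x) = bm;
    }
  }
  return List::create(_["b_plus"] = bpm, _["b_minus"] = bmm);
}

//' @noRd
// [[Rcpp::export]]
List ltp_features_range_cpp(IntegerVector frames, int h, int w, int nframes,
                            int delta, int patch_half, int radius, double tau,
                            int grid_cols, int grid_rows, bool l1) {
  if (nframes < 2 * delta + 1)
    stop("stack shorter than 2*delta + 1 frames");
  int cw = w / grid_cols, ch = h / grid_rows;
  if (cw < 1 || ch < 1) stop("grid finer than the region of interest");
  int m = patch_half + radius;
  int ncell = grid_cols * grid_rows;
  int dim = ncell * 512;
  int nout = nframes - 2 * delta;
  const int* f0 = INTEGER(frames);

  std::vector<int> ii, jj;
  std::vector<double> xx;
  std::vector<double> counts((size_t)dim, 0.0);
  std::vector<double> cell_tot((size_t)ncell, 0.0);

  for (int t = delta; t < nframes - delta; ++t) {
    std::fill(counts.begin(), counts.end(), 0.0);
    std::fill(cell_tot.begin(), cell_tot.end(), 0.0);
    const int* ft = f0 + (size_t)t * h * w;
    const int* fm = f0 + (size_t)(t - delta) * h * w;
    const int* fp = f0 + (size_t)(t + delta) * h * w;
    for (int x = m; x < w - m; ++x) {
      int cc = x / cw; if (cc >= grid_cols) cc = grid_cols - 1;
      for (int y = m; y < h - m; ++y) {
        int cr = y / ch; if (cr >= grid_rows) cr = grid_rows - 1;
        int cell = cr * grid_cols + cc;
        int bp, bm;
        trit_pixel(ft, fm, fp, h, y, x, radius, patch_half, tau, &bp, &bm);
        counts[(size_t)cell * 512 + bp] += 1.0;
        counts[(size_t)cell * 512 + 256 + bm] += 1.0;
        cell_tot[cell] += 1.0;
      }
    }
    int row = t - delta + 1;  // 1-based for sparseMatrix()
    for (int c = 0; c < ncell; ++c) {
      double denom = l1 && cell_tot[c] > 0 ? cell_tot[c] : 1.0;
      for (int b = 0; b < 512; ++b) {
        double v = counts[(size_t)c * 512 + b];
        if (v != 0.0) {
          ii.push_back(row);
          jj.push_back(c * 512 + b + 1);
          xx.push_back(v / denom);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx),
                      _["nrow"] = nout, _["dim"] = dim);
}
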