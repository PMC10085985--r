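#include <Rcpp.h>
using namespace Rcpp;

// Gaussian deviates by the polar (Marsaglia) method from R's uniform
// stream: reproducible under set.seed() and much cheaper than inversion
// at ~1 Mpx per frame.
struct PolarGauss {
  double spare = 0.0;
  bool have_spare = false;
  double next() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
};

// Additive Gaussian sensor noise + clip to [0,1] in one pass over the frame.
// [[Rcpp::export]]
NumericMatrix cpp_noisy_frame(NumericMatrix base, double noise_sd) {
  R_xlen_t n = base.size();
  NumericMatrix out(base.nrow(), base.ncol());
  if (noise_sd <= 0) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = base[i];
      out[i] = v < 0 ? 0 : (v > 1 ? 1 : v);
    }
    return out;
  }
  PolarGauss g;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = base[i] + noise_sd * g.next();
    out[i] = v < 0 ? 0 : (v > 1 ? 1 : v);
  }
  return out;
}

// Fused render pass: copy the base pattern, add Gaussian sensor noise,
// clip to [0,1], then darken active spots (recomputing only their
// bounding boxes). Minimizes full-frame memory traffic.
// [[Rcpp::export]]
NumericMatrix cpp_render(NumericMatrix base, NumericVector sy,
                         NumericVector sx, NumericVector sr,
                         double depth, double noise_sd) {
  int nr = base.nrow(), nc = base.ncol();
  R_xlen_t n = base.size();
  NumericMatrix out(no_init(nr, nc));
  if (noise_sd > 0) {
    PolarGauss g;
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = base[i] + noise_sd * g.next();
      out[i] = v < 0 ? 0 : (v > 1 ? 1 : v);
    }
  } else {
    std::copy(base.begin(), base.end(), out.begin());
  }
  for (R_xlen_t k = 0; k < sy.size(); ++k) {
    double cy = sy[k], cx = sx[k], r = sr[k];
    double edge = std::min(2.0, r / 2), inner = r - edge;
    int r0 = std::max(0, (int)std::floor(cy - r) - 1);
    int r1 = std::min(nr - 1, (int)std::ceil(cy + r));
    int c0 = std::max(0, (int)std::floor(cx - r) - 1);
    int c1 = std::min(nc - 1, (int)std::ceil(cx + r));
    for (int j = c0; j <= c1; ++j) {
      double dx = (j + 1) - cx;
      for (int i = r0; i <= r1; ++i) {
        double dy = (i + 1) - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d >= r) continue;
        double s = (edge > 0 && d > inner) ? (r - d) / edge : 1.0;
        double v = out(i, j) - base(i, j) * depth * s;
        out(i, j) = v < 0 ? 0 : v;
      }
    }
  }
  return out;
}

// Crop a rectangular window (1-based inclusive row/col bounds) and resize
// it to out_h x out_w by bilinear interpolation, in one pass over the
// output. Pixel centers align at the window borders (half-pixel
// convention), so an identity-size crop reproduces its input exactly.
// [[Rcpp::export]]
NumericMatrix cpp_crop_resize(NumericMatrix img, int r0, int r1, int c0,
                              int c1, int out_h, int out_w) {
  int src_h = r1 - r0 + 1, src_w = c1 - c0 + 1;
  NumericMatrix out(no_init(out_h, out_w));
  double sy = (double)src_h / out_h, sx = (double)src_w / out_w;
  for (int j = 0; j < out_w; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(xs);
    double wx = xs - x0;
    int xa = std::min(std::max(x0, 0), src_w - 1);
    int xb = std::min(x0 + 1, src_w - 1);
    for (int i = 0; i < out_h; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(ys);
      double wy = ys - y0;
      int ya = std::min(std::max(y0, 0), src_h - 1);
      int yb = std::min(y0 + 1, src_h - 1);
      double v00 = img(r0 - 1 + ya, c0 - 1 + xa);
      double v01 = img(r0 - 1 + ya, c0 - 1 + xb);
      double v10 = img(r0 - 1 + yb, c0 - 1 + xa);
      double v11 = img(r0 - 1 + yb, c0 - 1 + xb);
      double v = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                 wy * ((1 - wx) * v10 + wx * v11);
      out(i, j) = v < 0 ? 0 : (v > 1 ? 1 : v);
    }
  }
  return out;
}

// Every k-th pixel of a frame, single pass (cheap proxy image for the
// quality metrics and coarse component labeling).
// [[Rcpp::export]]
NumericMatrix cpp_downsample(NumericMatrix img, int k) {
  int nr = (img.nrow() + k - 1) / k, nc = (img.ncol() + k - 1) / k;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img(i * k, j * k);
  return out;
}

// Multiply pixels inside a disc by (1 - depth * s), where s falls linearly
// from 1 to 0 across the outer `edge` pixels of the disc. Operates in place
// on a matrix the caller owns. cy/cx are 1-based row/col centers.
// [[Rcpp::export]]
void cpp_darken_disc(NumericMatrix img, double cy, double cx, double r,
                     double depth, double edge) {
  if (r <= 0 || depth <= 0) return;
  int nr = img.nrow(), nc = img.ncol();
  int r0 = std::max(0, (int)std::floor(cy - r) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(cy + r));
  int c0 = std::max(0, (int)std::floor(cx - r) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(cx + r));
  double inner = r - edge;
  for (int j = c0; j <= c1; ++j) {
    double dx = (j + 1) - cx;
    for (int i = r0; i <= r1; ++i) {
      double dy = (i + 1) - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= r) continue;
      double s = (edge > 0 && d > inner) ? (r - d) / edge : 1.0;
      img(i, j) *= (1.0 - depth * s);
    }
  }
}

// Paint an opaque stroke (eyelash occluder) along sampled curve points:
// pixels within halfwidth of any sample are set to `value`.
// [[Rcpp::export]]
void cpp_draw_stroke(NumericMatrix img, NumericVector ys, NumericVector xs,
                     double halfwidth, double value) {
  int nr = img.nrow(), nc = img.ncol();
  double hw2 = halfwidth * halfwidth;
  for (R_xlen_t k = 0; k < ys.size(); ++k) {
    double cy = ys[k], cx = xs[k];
    int r0 = std::max(0, (int)std::floor(cy - halfwidth) - 1);
    int r1 = std::min(nr - 1, (int)std::ceil(cy + halfwidth));
    int c0 = std::max(0, (int)std::floor(cx - halfwidth) - 1);
    int c1 = std::min(nc - 1, (int)std::ceil(cx + halfwidth));
    for (int j = c0; j <= c1; ++j) {
      double dx = (j + 1) - cx;
      for (int i = r0; i <= r1; ++i) {
        double dy = (i + 1) - cy;
        if (dx * dx + dy * dy <= hw2) img(i, j) = value;
      }
    }
  }
}

// Per-row and per-column counts of pixels above a threshold, one pass.
// Used for bright-region (corneal disc) extent and area statistics.
// [[Rcpp::export]]
List cpp_bright_counts(NumericMatrix img, double thr) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerVector rows(nr), cols(nc);
  double total = 0;
  for (int j = 0; j < nc; ++j) {
    int cj = 0;
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) > thr) {
        ++cj;
        ++rows[i];
      }
    }
    cols[j] = cj;
    total += cj;
  }
  return List::create(_["rows"] = rows, _["cols"] = cols,
                      _["frac"] = total / (double)(nr * (double)nc));
}

// Fraction of pixels in the annulus rin <= d < rout (around 1-based cy/cx)
// that fall below `thr`. Used as the occluder-coverage score: a dark stroke
// crossing the corneal rim darkens this ring, breakup spots do not reach it.
// [[Rcpp::export]]
double cpp_dark_ring_frac(NumericMatrix img, double cy, double cx,
                          double rin, double rout, double thr) {
  int nr = img.nrow(), nc = img.ncol();
  int r0 = std::max(0, (int)std::floor(cy - rout) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(cy + rout));
  int c0 = std::max(0, (int)std::floor(cx - rout) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(cx + rout));
  double in2 = rin * rin, out2 = rout * rout;
  double n = 0, dark = 0;
  for (int j = c0; j <= c1; ++j) {
    double dx = (j + 1) - cx;
    for (int i = r0; i <= r1; ++i) {
      double dy = (i + 1) - cy;
      double d2 = dx * dx + dy * dy;
      if (d2 >= in2 && d2 < out2) {
        n += 1;
        if (img(i, j) < thr) dark += 1;
      }
    }
  }
  return n > 0 ? dark / n : 0.0;
}
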