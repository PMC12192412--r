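#include <Rcpp.h>
using namespace Rcpp;

// Dense similarity map between a frame and a (possibly masked) template.
// Matrices are column-major [row = y, col = x]; placements are template
// top-left positions, map(py, px) for 0-based (px, py).
//
// method 0: zero-mean normalised cross-correlation under the mask
// method 1: raw cross-correlation (plain sum of pairwise products)
//
// The mask is decomposed into contiguous per-column runs so the inner loops
// stream over memory; a circular mask has exactly one run per column.
// Zero-variance placements under NCC get similarity 0 and are counted in
// n_degenerate so callers can flag them instead of propagating NaN.
// [[Rcpp::export]]
List match_map_cpp(NumericMatrix frame, NumericMatrix patch,
                   LogicalMatrix mask, bool use_mask, int method) {
  const int H = frame.nrow(), W = frame.ncol();
  const int h = patch.nrow(), w = patch.ncol();
  if (h >= H || w >= W)
    stop("template (%d x %d) must be strictly smaller than frame (%d x %d)",
         w, h, W, H);

  // per-column runs of contributing template pixels
  struct Run { int j, i0, i1; };
  std::vector<Run> runs;
  long nm = 0;
  for (int j = 0; j < w; ++j) {
    int i = 0;
    while (i < h) {
      while (i < h && use_mask && !mask(i, j)) ++i;
      if (i >= h) break;
      int i0 = i;
      while (i < h && (!use_mask || mask(i, j))) ++i;
      runs.push_back({j, i0, i - 1});
      nm += i - i0;
    }
  }
  if (nm == 0) stop("empty template mask");

  // masked template stats; tc holds (t - tbar) on the mask, 0 elsewhere
  double tbar = 0.0;
  for (const Run& r : runs)
    for (int i = r.i0; i <= r.i1; ++i) tbar += patch(i, r.j);
  tbar /= nm;
  std::vector<double> tc(h * w, 0.0), tv(h * w, 0.0);
  double st2 = 0.0;
  for (const Run& r : runs)
    for (int i = r.i0; i <= r.i1; ++i) {
      const double v = patch(i, r.j);
      tv[r.j * h + i] = v;
      tc[r.j * h + i] = v - tbar;
      st2 += (v - tbar) * (v - tbar);
    }

  const int oh = H - h + 1, ow = W - w + 1;
  NumericMatrix out(oh, ow);
  int n_degenerate = 0;
  const double eps = 1e-12;
  const double* F = REAL(frame);

  for (int px = 0; px < ow; ++px) {
    for (int py = 0; py < oh; ++py) {
      double s = 0.0;
      if (method == 1) {
        for (const Run& r : runs) {
          const double* f = F + (long)(px + r.j) * H + py + r.i0;
          const double* t = tv.data() + r.j * h + r.i0;
          for (int i = r.i0; i <= r.i1; ++i) s += (*f++) * (*t++);
        }
      } else {
        double sf = 0.0, sff = 0.0, sft = 0.0;
        for (const Run& r : runs) {
          const double* f = F + (long)(px + r.j) * H + py + r.i0;
          const double* t = tc.data() + r.j * h + r.i0;
          for (int i = r.i0; i <= r.i1; ++i) {
            const double v = *f++;
            sf += v; sff += v * v; sft += v * (*t++);
          }
        }
        const double varf = sff - sf * sf / nm;
        const double den2 = varf * st2;
        if (den2 <= eps) { s = 0.0; ++n_degenerate; }
        else s = sft / std::sqrt(den2);
      }
      out(py, px) = s;
    }
  }
  return List::create(_["map"] = out, _["n_degenerate"] = n_degenerate);
}
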