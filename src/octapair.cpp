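#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector float32_snap_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = static_cast<double>(static_cast<float>(x[i]));
  }
  return out;
}

// Sum of volume values over per-column depth intervals [top, bot] (1-based,
// top > bot marks an empty column). Long-double accumulation keeps the
// result independent of traversal order to well below 1e-12 relative.
// [[Rcpp::export]]
List layer_sum_cpp(NumericVector vol, IntegerMatrix top, IntegerMatrix bot) {
  IntegerVector d = vol.attr("dim");
  const int nf = d[0], ns = d[1], nz = d[2];
  if (top.nrow() != nf || top.ncol() != ns) stop("mask/volume shape mismatch");
  long double acc = 0.0L;
  double count = 0.0;
  const double *v = vol.begin();
  for (int j = 0; j < ns; ++j) {
    for (int i = 0; i < nf; ++i) {
      int a = top(i, j), b = bot(i, j);
      if (a < 1) a = 1;
      if (b > nz) b = nz;
      if (b < a) continue;
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nf * (R_xlen_t)j;
      const R_xlen_t stride = (R_xlen_t)nf * (R_xlen_t)ns;
      for (int k = a - 1; k < b; ++k) acc += v[base + stride * (R_xlen_t)k];
      count += b - a + 1;
    }
  }
  return List::create(_["sum"] = (double)acc, _["count"] = count);
}

// Maximum-intensity projection over per-column depth intervals; columns with
// no masked voxel project to 0.
// [[Rcpp::export]]
NumericMatrix mip_cpp(NumericVector vol, IntegerMatrix top, IntegerMatrix bot) {
  IntegerVector d = vol.attr("dim");
  const int nf = d[0], ns = d[1], nz = d[2];
  NumericMatrix out(nf, ns);
  const double *v = vol.begin();
  for (int j = 0; j < ns; ++j) {
    for (int i = 0; i < nf; ++i) {
      int a = top(i, j), b = bot(i, j);
      if (a < 1) a = 1;
      if (b > nz) b = nz;
      double m = 0.0;
      if (b >= a) {
        const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nf * (R_xlen_t)j;
        const R_xlen_t stride = (R_xlen_t)nf * (R_xlen_t)ns;
        m = v[base + stride * (R_xlen_t)(a - 1)];
        for (int k = a; k < b; ++k) {
          double x = v[base + stride * (R_xlen_t)k];
          if (x > m) m = x;
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Phenomenological OCT forward model. Slab boundaries per column (um from
// the volume top): vitreous | [ILM, IPL] | (IPL, OPL] | (OPL, ISOS] |
// (ISOS, RPE] fluid | (RPE, BM] | Sattler | Haller | sclera. Voxel value =
// slab reflectivity x exp(-tissue_att * tissue_path - fluid_excess *
// fluid_path - rolloff * z) + Gaussian noise, clipped at 0 and snapped to
// float32. Depth sample k (1-based) is centred at (k-1)*ax_um. Noise uses
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector render_volume_cpp(int n_fast, int n_slow, int n_depth,
                                double ax_um,
                                NumericMatrix ilm, NumericMatrix ipl,
                                NumericMatrix opl, NumericMatrix isos,
                                NumericMatrix rpe, NumericMatrix bm,
                                double t_sattler_um, double t_haller_um,
                                NumericVector refl, // 9 slabs, order above
                                double tissue_att, double fluid_excess,
                                double rolloff, double noise_abs_sd) {
  NumericVector out((R_xlen_t)n_fast * n_slow * n_depth);
  out.attr("dim") = IntegerVector::create(n_fast, n_slow, n_depth);
  const double r_vit = refl[0], r_sup = refl[1], r_deep = refl[2],
               r_out = refl[3], r_fluid = refl[4], r_rpe = refl[5],
               r_sat = refl[6], r_hal = refl[7], r_scl = refl[8];
  double *o = out.begin();
  const R_xlen_t stride = (R_xlen_t)n_fast * (R_xlen_t)n_slow;
  const bool noisy = noise_abs_sd > 0.0;
  for (int j = 0; j < n_slow; ++j) {
    for (int i = 0; i < n_fast; ++i) {
      const double d_ilm = ilm(i, j), d_ipl = ipl(i, j), d_opl = opl(i, j),
                   d_isos = isos(i, j), d_rpe = rpe(i, j), d_bm = bm(i, j);
      const double d_sat = d_bm + t_sattler_um;
      const double d_hal = d_sat + t_haller_um;
      const double gap = d_rpe - d_isos;
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)n_fast * (R_xlen_t)j;
      for (int k = 0; k < n_depth; ++k) {
        const double z = k * ax_um;
        double r;
        if (z < d_ilm) r = r_vit;
        else if (z <= d_ipl) r = r_sup;
        else if (z <= d_opl) r = r_deep;
        else if (z <= d_isos) r = r_out;
        else if (z <= d_rpe) r = r_fluid;
        else if (z <= d_bm) r = r_rpe;
        else if (z <= d_sat) r = r_sat;
        else if (z <= d_hal) r = r_hal;
        else r = r_scl;
        const double tissue_mm = z > d_ilm ? (z - d_ilm) / 1000.0 : 0.0;
        double fluid_mm = 0.0;
        if (gap > 0.0 && z > d_isos) {
          fluid_mm = (z < d_rpe ? z - d_isos : gap) / 1000.0;
        }
        double val = r * std::exp(-tissue_att * tissue_mm -
                                  fluid_excess * fluid_mm -
                                  rolloff * z / 1000.0);
        if (noisy) val += noise_abs_sd * norm_rand();
        if (val < 0.0) val = 0.0;
        o[base + stride * (R_xlen_t)k] = (double)(float)val;
      }
    }
  }
  return out;
}

// Rasterize thick line segments onto a logical canvas (used for the
// synthetic vascular patterns). Coordinates are 1-based pixel positions.
// [[Rcpp::export]]
LogicalMatrix raster_segments_cpp(LogicalMatrix canvas,
                                  NumericVector x0, NumericVector y0,
                                  NumericVector x1, NumericVector y1,
                                  NumericVector halfw) {
  const int nx = canvas.nrow(), ny = canvas.ncol();
  for (R_xlen_t s = 0; s < x0.size(); ++s) {
    const double ax = x0[s], ay = y0[s], bx = x1[s], by = y1[s], hw = halfw[s];
    const double dx = bx - ax, dy = by - ay;
    const double len2 = dx * dx + dy * dy;
    int ilo = (int)std::floor(std::min(ax, bx) - hw) - 1;
    int ihi = (int)std::ceil(std::max(ax, bx) + hw) + 1;
    int jlo = (int)std::floor(std::min(ay, by) - hw) - 1;
    int jhi = (int)std::ceil(std::max(ay, by) + hw) + 1;
    if (ilo < 1) ilo = 1;
    if (jlo < 1) jlo = 1;
    if (ihi > nx) ihi = nx;
    if (jhi > ny) jhi = ny;
    const double hw2 = hw * hw;
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        double px = i - ax, py = j - ay;
        double t = len2 > 0.0 ? (px * dx + py * dy) / len2 : 0.0;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
        const double qx = px - t * dx, qy = py - t * dy;
        if (qx * qx + qy * qy <= hw2) canvas(i - 1, j - 1) = true;
      }
    }
  }
  return canvas;
}
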