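#include <Rcpp.h>
using namespace Rcpp;

// Blue-noise point sampling and relaxation kernels for the monolayer
// simulator. All randomness is drawn from R's RNG so that set.seed() on the
// R side makes the output reproducible.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bridson's Poisson-disc sampling in the rectangle [0,width] x [0,height]
// with minimum pairwise distance rmin. k = candidate attempts per active
// point. Returns an n x 2 matrix of coordinates.
// [[Rcpp::export(name = ".bridsonSample")]]
NumericMatrix bridson_sample(double width, double height, double rmin, int k) {
  if (width <= 0 || height <= 0 || rmin <= 0)
    stop("width, height and rmin must be positive");
  const double cell = rmin / std::sqrt(2.0);
  const int nx = (int)std::ceil(width / cell);
  const int ny = (int)std::ceil(height / cell);
  std::vector<int> grid((size_t)nx * ny, -1);
  std::vector<double> px, py;
  std::vector<int> active;
  px.reserve(4096); py.reserve(4096);

  double x0 = R::runif(0.0, width), y0 = R::runif(0.0, height);
  px.push_back(x0); py.push_back(y0);
  grid[(size_t)clampi((int)(x0 / cell), 0, nx - 1) * ny +
       clampi((int)(y0 / cell), 0, ny - 1)] = 0;
  active.push_back(0);

  while (!active.empty()) {
    int ai = (int)std::floor(R::runif(0.0, 1.0) * active.size());
    if (ai >= (int)active.size()) ai = (int)active.size() - 1;
    const int pi = active[ai];
    bool found = false;
    for (int attempt = 0; attempt < k; ++attempt) {
      const double ang = R::runif(0.0, 2.0 * M_PI);
      const double rad = rmin * (1.0 + R::runif(0.0, 1.0));
      const double cx = px[pi] + rad * std::cos(ang);
      const double cy = py[pi] + rad * std::sin(ang);
      if (cx < 0 || cx >= width || cy < 0 || cy >= height) continue;
      const int gx = clampi((int)(cx / cell), 0, nx - 1);
      const int gy = clampi((int)(cy / cell), 0, ny - 1);
      bool ok = true;
      for (int ix = std::max(0, gx - 2); ix <= std::min(nx - 1, gx + 2) && ok; ++ix)
        for (int iy = std::max(0, gy - 2); iy <= std::min(ny - 1, gy + 2) && ok; ++iy) {
          const int q = grid[(size_t)ix * ny + iy];
          if (q >= 0) {
            const double dx = px[q] - cx, dy = py[q] - cy;
            if (dx * dx + dy * dy < rmin * rmin) ok = false;
          }
        }
      if (ok) {
        px.push_back(cx); py.push_back(cy);
        grid[(size_t)gx * ny + gy] = (int)px.size() - 1;
        active.push_back((int)px.size() - 1);
        found = true;
        break;
      }
    }
    if (!found) {
      active[ai] = active.back();
      active.pop_back();
    }
  }

  NumericMatrix out((int)px.size(), 2);
  for (size_t i = 0; i < px.size(); ++i) {
    out((int)i, 0) = px[i];
    out((int)i, 1) = py[i];
  }
  return out;
}

// Discrete Lloyd relaxation: each step assigns raster sample points (spacing
// gridStep) to their nearest seed and moves every seed to the centroid of its
// assigned samples. Sampling is restricted to the disc of radius discR
// centred in the rectangle when discR > 0, otherwise to the full rectangle.
// Seeds are kept inside the domain.
// [[Rcpp::export(name = ".lloydRelax")]]
NumericMatrix lloyd_relax(NumericMatrix pts, double xmin, double xmax,
                          double ymin, double ymax, double gridStep,
                          int steps, double discR) {
  const int n = pts.nrow();
  if (n == 0 || steps <= 0) return pts;
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); }
  const double cx0 = 0.5 * (xmin + xmax), cy0 = 0.5 * (ymin + ymax);
  const double w = xmax - xmin, h = ymax - ymin;

  for (int s = 0; s < steps; ++s) {
    const double bucket = std::max(gridStep, 2.0 * std::sqrt(w * h / std::max(n, 1)));
    const int bx = std::max(1, (int)std::ceil(w / bucket));
    const int by = std::max(1, (int)std::ceil(h / bucket));
    std::vector< std::vector<int> > buckets((size_t)bx * by);
    for (int i = 0; i < n; ++i) {
      const int ix = clampi((int)((px[i] - xmin) / bucket), 0, bx - 1);
      const int iy = clampi((int)((py[i] - ymin) / bucket), 0, by - 1);
      buckets[(size_t)ix * by + iy].push_back(i);
    }
    std::vector<double> sx(n, 0.0), sy(n, 0.0);
    std::vector<int> cnt(n, 0);
    for (double gx = xmin + gridStep / 2; gx < xmax; gx += gridStep) {
      for (double gy = ymin + gridStep / 2; gy < ymax; gy += gridStep) {
        if (discR > 0) {
          const double dx = gx - cx0, dy = gy - cy0;
          if (dx * dx + dy * dy > discR * discR) continue;
        }
        const int ix = clampi((int)((gx - xmin) / bucket), 0, bx - 1);
        const int iy = clampi((int)((gy - ymin) / bucket), 0, by - 1);
        int best = -1;
        double bestd = std::numeric_limits<double>::max();
        const int maxring = std::max(bx, by);
        for (int ring = 0; ring <= maxring; ++ring) {
          // once a candidate is found, rings beyond bestdist/bucket + 1 cannot win
          if (best >= 0 && (double)(ring - 1) * bucket > std::sqrt(bestd)) break;
          for (int jx = std::max(0, ix - ring); jx <= std::min(bx - 1, ix + ring); ++jx)
            for (int jy = std::max(0, iy - ring); jy <= std::min(by - 1, iy + ring); ++jy) {
              if (std::max(std::abs(jx - ix), std::abs(jy - iy)) != ring) continue;
              const std::vector<int>& b = buckets[(size_t)jx * by + jy];
              for (size_t t = 0; t < b.size(); ++t) {
                const int q = b[t];
                const double dx = px[q] - gx, dy = py[q] - gy;
                const double d = dx * dx + dy * dy;
                if (d < bestd) { bestd = d; best = q; }
              }
            }
        }
        if (best >= 0) { sx[best] += gx; sy[best] += gy; cnt[best]++; }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (cnt[i] == 0) continue;
      double nxp = sx[i] / cnt[i], nyp = sy[i] / cnt[i];
      if (discR > 0) {
        const double dx = nxp - cx0, dy = nyp - cy0;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d > discR) {
          nxp = cx0 + dx / d * discR * 0.999;
          nyp = cy0 + dy / d * discR * 0.999;
        }
      } else {
        nxp = std::min(std::max(nxp, xmin), xmax);
        nyp = std::min(std::max(nyp, ymin), ymax);
      }
      px[i] = nxp; py[i] = nyp;
    }
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}
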