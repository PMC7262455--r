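#include <Rcpp.h>
using namespace Rcpp;

// Orientationally averaged scattering of point beads (Debye sum).
// I(q) = sum_i sum_j f_i f_j sin(q r_ij)/(q r_ij); i==j and q->0 limits are 1.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix pos, NumericVector f, NumericVector q) {
  const int n = pos.nrow(), nq = q.size();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  std::vector<double> d(np), w(np);
  double self = 0.0;
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    self += f[i] * f[i];
    for (int j = i + 1; j < n; ++j, ++k) {
      double dx = pos(i,0) - pos(j,0);
      double dy = pos(i,1) - pos(j,1);
      double dz = pos(i,2) - pos(j,2);
      d[k] = std::sqrt(dx*dx + dy*dy + dz*dz);
      w[k] = f[i] * f[j];
    }
  }
  NumericVector I(nq);
  for (int m = 0; m < nq; ++m) {
    double qm = q[m], s = 0.0;
    if (qm <= 0.0) {
      for (k = 0; k < np; ++k) s += w[k];
    } else {
      for (k = 0; k < np; ++k) {
        double x = qm * d[k];
        s += (x < 1e-9) ? w[k] : w[k] * std::sin(x) / x;
      }
    }
    I[m] = self + 2.0 * s;
  }
  return I;
}

// Weighted histogram of all pairwise distances (i < j, weight 2 f_i f_j).
// breaks: ascending bin edges; distances outside [first, last) are dropped.
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, NumericVector f, NumericVector breaks) {
  const int n = pos.nrow(), nb = breaks.size() - 1;
  NumericVector counts(nb);
  const double lo = breaks[0], hi = breaks[nb];
  const double bw = (hi - lo) / nb;  // uniform bins assumed
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i,0) - pos(j,0);
      double dy = pos(i,1) - pos(j,1);
      double dz = pos(i,2) - pos(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < lo || d >= hi) continue;
      int b = (int)((d - lo) / bw);
      if (b >= nb) b = nb - 1;
      counts[b] += 2.0 * f[i] * f[j];
    }
  }
  return counts;
}

// Shrake-Rupley solvent accessible surface area.
// Test points on each atom's expanded sphere (radius + probe) by golden-angle
// spiral; a point is occluded if inside any neighbour's expanded sphere.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii, double probe,
                       int npoints) {
  const int n = coords.nrow();
  NumericVector sasa(n);
  // unit sphere points
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
  double maxr = 0.0;
  for (int i = 0; i < n; ++i) maxr = std::max(maxr, radii[i]);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double cut = ri + maxr + probe;
    // neighbour list for atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j,0) - coords(i,0);
      double dy = coords(j,1) - coords(i,1);
      double dz = coords(j,2) - coords(i,2);
      if (dx*dx + dy*dy + dz*dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double x = coords(i,0) + ri * px[k];
      double y = coords(i,1) + ri * py[k];
      double z = coords(i,2) + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = x - coords(j,0), dy = y - coords(j,1), dz = z - coords(j,2);
        if (dx*dx + dy*dy + dz*dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    sasa[i] = 4.0 * M_PI * ri * ri * (double)acc / npoints;
  }
  return sasa;
}

// Maximum pairwise distance within one point set (Dmax).
// [[Rcpp::export]]
double cpp_max_pair_dist(NumericMatrix pos) {
  const int n = pos.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i,0) - pos(j,0);
      double dy = pos(i,1) - pos(j,1);
      double dz = pos(i,2) - pos(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Minimum distance between two point sets (early exit when below `stop_below`).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix a, NumericMatrix b, double stop_below) {
  double best = R_PosInf;
  const double s2 = stop_below * stop_below;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i,0) - b(j,0);
      double dy = a(i,1) - b(j,1);
      double dz = a(i,2) - b(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) {
        best = d2;
        if (best < s2) return std::sqrt(best);
      }
    }
  }
  return std::sqrt(best);
}
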