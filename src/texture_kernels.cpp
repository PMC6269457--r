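#include <Rcpp.h>
using namespace Rcpp;

// Gray-level co-occurrence features over a quantized region.
// lv: integer matrix of levels in 1..G, 0 = outside the region.
// offsets: k x 2 integer matrix of (dr, dc) displacements (distance 1).
// Pairs are accumulated symmetrically into one normalized G x G matrix.
// Returns (contrast, correlation, homogeneity, energy, entropy, inverse
// difference moment, cluster shade); entropy in bits. Degenerate (no valid
// pair) conventions: contrast 0, correlation 0, homogeneity 1, energy 1,
// entropy 0, IDM 1, shade 0.
// [[Rcpp::export]]
NumericVector cpp_glcm_features(IntegerMatrix lv, int G, IntegerMatrix offsets) {
  int nr = lv.nrow(), nc = lv.ncol();
  std::vector<double> P((size_t)G * G, 0.0);
  double total = 0.0;
  for (int k = 0; k < offsets.nrow(); k++) {
    int dr = offsets(k, 0), dc = offsets(k, 1);
    for (int c = 0; c < nc; c++) {
      for (int r = 0; r < nr; r++) {
        int a = lv(r, c);
        if (a == 0) continue;
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int b = lv(r2, c2);
        if (b == 0) continue;
        P[(size_t)(a - 1) * G + (b - 1)] += 1.0;
        P[(size_t)(b - 1) * G + (a - 1)] += 1.0;
        total += 2.0;
      }
    }
  }
  double contrast = 0, corr = 0, homog = 1, energy = 1, entropy = 0,
         idm = 1, shade = 0;
  if (total > 0) {
    homog = 0; energy = 0; idm = 0;
    double mu = 0.0;
    for (int i = 0; i < G; i++)
      for (int j = 0; j < G; j++) {
        double p = P[(size_t)i * G + j] / total;
        if (p <= 0) continue;
        mu += (i + 1) * p;  // marginal means equal by symmetry
      }
    double sig2 = 0.0;
    for (int i = 0; i < G; i++)
      for (int j = 0; j < G; j++) {
        double p = P[(size_t)i * G + j] / total;
        if (p <= 0) continue;
        double di = (i + 1) - mu, dj = (j + 1) - mu, dij = (double)(i - j);
        contrast += dij * dij * p;
        sig2 += di * di * p;
        corr += di * dj * p;
        homog += p / (1.0 + std::abs(dij));
        energy += p * p;
        entropy -= p * std::log2(p);
        idm += p / (1.0 + dij * dij);
        shade += (di + dj) * (di + dj) * (di + dj) * p;
      }
    corr = (sig2 > 1e-12) ? corr / sig2 : 0.0;
  }
  return NumericVector::create(contrast, corr, homog, energy, entropy, idm, shade);
}

// Run-length features over a quantized region along one direction.
// Runs are maximal constant-level strings of in-region pixels along (dr, dc);
// runs break at the region boundary. Returns the 11 classical statistics:
// SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE.
// [[Rcpp::export]]
NumericVector cpp_rlm_features(IntegerMatrix lv, int G, int dr, int dc) {
  int nr = lv.nrow(), nc = lv.ncol();
  int maxlen = nr + nc;
  std::vector<double> cg(G + 1, 0.0), cl(maxlen + 2, 0.0);
  double Nr = 0, Np = 0;
  double sre = 0, lre = 0, lgre = 0, hgre = 0, srlge = 0, srhge = 0,
         lrlge = 0, lrhge = 0;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      int g = lv(r, c);
      if (g == 0) continue;
      Np += 1;
      // run start: predecessor is out of bounds, outside region, or differs
      int rp = r - dr, cp = c - dc;
      bool start = (rp < 0 || rp >= nr || cp < 0 || cp >= nc || lv(rp, cp) != g);
      if (!start) continue;
      int len = 1, r2 = r + dr, c2 = c + dc;
      while (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && lv(r2, c2) == g) {
        len++; r2 += dr; c2 += dc;
      }
      double l2 = (double)len * len, g2 = (double)g * g;
      Nr += 1; cg[g] += 1; cl[len] += 1;
      sre += 1.0 / l2; lre += l2;
      lgre += 1.0 / g2; hgre += g2;
      srlge += 1.0 / (g2 * l2); srhge += g2 / l2;
      lrlge += l2 / g2; lrhge += g2 * l2;
    }
  }
  if (Nr == 0)
    return NumericVector::create(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0);
  double gln = 0, rln = 0;
  for (int g = 1; g <= G; g++) gln += cg[g] * cg[g];
  for (int l = 1; l <= maxlen + 1; l++) rln += cl[l] * cl[l];
  return NumericVector::create(sre / Nr, lre / Nr, gln / Nr, rln / Nr,
                               Nr / Np, lgre / Nr, hgre / Nr, srlge / Nr,
                               srhge / Nr, lrlge / Nr, lrhge / Nr);
}
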