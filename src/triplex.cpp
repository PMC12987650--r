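#include <Rcpp.h>
using namespace Rcpp;

// Ungapped triplex alignment over all diagonals of an (RNA, DNA) pair.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=T; negative codes mark ambiguity
// (never paired, score 0).  `pair_lut` is a 4x4 logical matrix indexed
// [rna, dna]: TRUE where a triplex rule lets the third-strand base pair
// with the duplex purine-strand base.  Per-position score is +1 when
// paired, tt_penalty for a T.T juxtaposition, cc_penalty for C.C, else 0.
//
// A window qualifies when its length >= min_nt, it starts and ends on a
// paired position, and 100 * score / length >= min_identity.  Reported
// windows are, per diagonal, the qualifying windows not contained in a
// longer qualifying window on the same diagonal (per-start maximal end,
// then a staircase filter over starts).
// [[Rcpp::export]]
DataFrame triplex_scan_cpp(IntegerVector rna, IntegerVector dna,
                           LogicalMatrix pair_lut,
                           double tt_penalty, double cc_penalty,
                           int min_nt, double min_identity) {
  const int n = rna.size(), m = dna.size();
  std::vector<int> out_rs, out_re, out_ds, out_de, out_np;
  if (n == 0 || m == 0) stop("empty sequence");
  if (min_nt < 1) stop("min_nt must be >= 1");

  std::vector<int> paired;    // 0/1 per diagonal position
  std::vector<double> score;  // per-position score
  std::vector<int> pidx;      // indices of paired positions

  for (int d = -(n - 1); d <= m - 1; ++d) {
    // rna index i pairs dna index j = i + d
    int i0 = std::max(0, -d);
    int i1 = std::min(n - 1, m - 1 - d);
    int L = i1 - i0 + 1;
    if (L < min_nt) continue;
    paired.assign(L, 0);
    score.assign(L, 0.0);
    pidx.clear();
    for (int k = 0; k < L; ++k) {
      int rb = rna[i0 + k], db = dna[i0 + k + d];
      if (rb < 0 || db < 0) continue;  // ambiguity: unpaired
      if (pair_lut(rb, db)) {
        paired[k] = 1; score[k] = 1.0; pidx.push_back(k);
      } else if (rb == 3 && db == 3) {
        score[k] = tt_penalty;
      } else if (rb == 1 && db == 1) {
        score[k] = cc_penalty;
      }
    }
    if ((int)pidx.size() < 1) continue;
    // quick upper bound: even a fully clean window needs enough paired sites
    if (100.0 * pidx.size() < min_identity * min_nt) continue;

    // prefix sums
    std::vector<int> cp(L + 1, 0);
    std::vector<double> cs(L + 1, 0.0);
    for (int k = 0; k < L; ++k) {
      cp[k + 1] = cp[k] + paired[k];
      cs[k + 1] = cs[k] + score[k];
    }

    // per paired start, maximal qualifying end
    std::vector<int> starts, ends, npair;
    const int np = pidx.size();
    for (int a = 0; a < np; ++a) {
      int s = pidx[a];
      int beste = -1, bestp = 0;
      for (int b = a; b < np; ++b) {
        int e = pidx[b];
        int len = e - s + 1;
        if (len < min_nt) continue;
        double sc = cs[e + 1] - cs[s];
        if (100.0 * sc >= min_identity * len) {
          beste = e; bestp = cp[e + 1] - cp[s];
        }
      }
      if (beste >= 0) { starts.push_back(s); ends.push_back(beste); npair.push_back(bestp); }
    }
    // staircase containment filter: keep windows whose end exceeds all
    // ends at strictly smaller starts
    int maxend = -1;
    for (size_t w = 0; w < starts.size(); ++w) {
      if (ends[w] > maxend) {
        maxend = ends[w];
        out_rs.push_back(i0 + starts[w]);
        out_re.push_back(i0 + ends[w] + 1);          // half-open
        out_ds.push_back(i0 + starts[w] + d);
        out_de.push_back(i0 + ends[w] + 1 + d);
        out_np.push_back(npair[w]);
      }
    }
  }
  return DataFrame::create(
    _["rna_start"] = out_rs, _["rna_end"] = out_re,
    _["dna_start"] = out_ds, _["dna_end"] = out_de,
    _["n_paired"]  = out_np);
}
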