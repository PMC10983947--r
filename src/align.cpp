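#include <Rcpp.h>
#include <vector>
#include <string>
#include <array>
#include <climits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) of `query` against `subject`,
// reporting successive non-overlapping hits by mask-and-rescan. A gap of
// length g scores gap_open + g * gap_extend (both negative).
//
// Returns a matrix with one row per hit:
//   sub_start, sub_end (0-based half-open on subject), score,
//   n_match, q_aligned (query characters consumed by the alignment).
// [[Rcpp::export(name = ".sw_hits_cpp")]]
IntegerMatrix sw_hits_cpp(std::string subject, std::string query,
                          int match, int mismatch, int gap_open,
                          int gap_extend, int min_score, int max_hits) {
  const int n = subject.size(), m = query.size();
  const int NEG = INT_MIN / 4;
  std::vector<char> masked(n, 0);
  std::vector<std::array<int, 5>> hits;

  std::vector<int> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)),
      F((n + 1) * (m + 1));
  // BH: 0 = restart (score 0), 1 = diagonal, 2 = from E, 3 = from F
  // BE/BF: 1 = gap opened from H, 0 = gap extended
  std::vector<unsigned char> BH((n + 1) * (m + 1)), BE((n + 1) * (m + 1)),
      BF((n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  while ((int)hits.size() < max_hits) {
    int best = 0, bi = -1, bj = -1;
    for (int j = 0; j <= m; ++j) {
      H[idx(0, j)] = 0; E[idx(0, j)] = NEG; F[idx(0, j)] = NEG;
      BH[idx(0, j)] = 0;
    }
    for (int i = 1; i <= n; ++i) {
      H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; F[idx(i, 0)] = NEG;
      BH[idx(i, 0)] = 0;
      for (int j = 1; j <= m; ++j) {
        int eo = H[idx(i - 1, j)] + gap_open + gap_extend;
        int ee = E[idx(i - 1, j)] + gap_extend;
        if (eo >= ee) { E[idx(i, j)] = eo; BE[idx(i, j)] = 1; }
        else          { E[idx(i, j)] = ee; BE[idx(i, j)] = 0; }
        int fo = H[idx(i, j - 1)] + gap_open + gap_extend;
        int fe = F[idx(i, j - 1)] + gap_extend;
        if (fo >= fe) { F[idx(i, j)] = fo; BF[idx(i, j)] = 1; }
        else          { F[idx(i, j)] = fe; BF[idx(i, j)] = 0; }
        int s = masked[i - 1]
                    ? NEG
                    : (subject[i - 1] == query[j - 1] ? match : mismatch);
        int diag = H[idx(i - 1, j - 1)] + s;
        int h = 0; unsigned char b = 0;
        if (diag > h) { h = diag; b = 1; }
        if (E[idx(i, j)] > h) { h = E[idx(i, j)]; b = 2; }
        if (F[idx(i, j)] > h) { h = F[idx(i, j)]; b = 3; }
        H[idx(i, j)] = h; BH[idx(i, j)] = b;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score || bi < 0) break;

    int i = bi, j = bj, n_match = 0, q_aln = 0;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      if (state == 0) {
        unsigned char b = BH[idx(i, j)];
        if (b == 0) break;
        if (b == 1) {
          if (subject[i - 1] == query[j - 1]) ++n_match;
          ++q_aln; --i; --j;
        } else if (b == 2) state = 1;
        else state = 2;
      } else if (state == 1) { // E consumes a subject character
        state = BE[idx(i, j)] == 1 ? 0 : 1;
        --i;
      } else { // F consumes a query character
        state = BF[idx(i, j)] == 1 ? 0 : 2;
        ++q_aln; --j;
      }
    }
    int sub_start = i, sub_end = bi;
    if (sub_end <= sub_start) break; // safety: cannot mask an empty span
    hits.push_back({sub_start, sub_end, best, n_match, q_aln});
    for (int k = sub_start; k < sub_end; ++k) masked[k] = 1;
  }

  IntegerMatrix out(hits.size(), 5);
  for (size_t r = 0; r < hits.size(); ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = hits[r][c];
  colnames(out) = CharacterVector::create("sub_start", "sub_end", "score",
                                          "n_match", "q_aligned");
  return out;
}

// Wraparound dynamic programming: global alignment of `segment` against an
// unrolled tandem array of `consensus`, ending at a motif boundary. The
// motif phase at each consumed segment character yields the tiling into
// motif instances.
//
// Returns a list:
//   score        best alignment score
//   motif_index  1-based motif copy index per segment character
//   n_del        per-copy count of consensus characters deleted
//   n_ins        per-copy count of inserted segment characters
// [[Rcpp::export(name = ".wraparound_decompose_cpp")]]
List wraparound_decompose_cpp(std::string segment, std::string consensus,
                              int match, int mismatch, int gap_open,
                              int gap_extend) {
  const int L = segment.size(), m = consensus.size();
  const int K = L / m + 3; // room for whole-motif deletions
  const int W = K * m;
  const long NEG = LONG_MIN / 4;

  std::vector<long> H((long)(L + 1) * (W + 1)), E((long)(L + 1) * (W + 1)),
      F((long)(L + 1) * (W + 1));
  std::vector<unsigned char> B((long)(L + 1) * (W + 1)),
      BE((long)(L + 1) * (W + 1)), BF((long)(L + 1) * (W + 1));
  auto idx = [W](int i, int j) { return (long)i * (W + 1) + j; };

  H[idx(0, 0)] = 0; E[idx(0, 0)] = NEG; F[idx(0, 0)] = NEG; B[idx(0, 0)] = 0;
  for (int j = 1; j <= W; ++j) { // leading deletions of consensus
    F[idx(0, j)] = (j == 1 ? gap_open + gap_extend
                           : F[idx(0, j - 1)] + gap_extend);
    BF[idx(0, j)] = (j == 1 ? 1 : 0);
    H[idx(0, j)] = F[idx(0, j)]; E[idx(0, j)] = NEG; B[idx(0, j)] = 3;
  }
  for (int i = 1; i <= L; ++i) {
    E[idx(i, 0)] = (i == 1 ? gap_open + gap_extend
                           : E[idx(i - 1, 0)] + gap_extend);
    BE[idx(i, 0)] = (i == 1 ? 1 : 0);
    H[idx(i, 0)] = E[idx(i, 0)]; F[idx(i, 0)] = NEG; B[idx(i, 0)] = 2;
    for (int j = 1; j <= W; ++j) {
      long eo = H[idx(i - 1, j)] + gap_open + gap_extend;
      long ee = E[idx(i - 1, j)] + gap_extend;
      if (eo >= ee) { E[idx(i, j)] = eo; BE[idx(i, j)] = 1; }
      else          { E[idx(i, j)] = ee; BE[idx(i, j)] = 0; }
      long fo = H[idx(i, j - 1)] + gap_open + gap_extend;
      long fe = F[idx(i, j - 1)] + gap_extend;
      if (fo >= fe) { F[idx(i, j)] = fo; BF[idx(i, j)] = 1; }
      else          { F[idx(i, j)] = fe; BF[idx(i, j)] = 0; }
      int s = segment[i - 1] == consensus[(j - 1) % m] ? match : mismatch;
      long diag = H[idx(i - 1, j - 1)] + s;
      long h = diag; unsigned char b = 1;
      if (E[idx(i, j)] > h) { h = E[idx(i, j)]; b = 2; }
      if (F[idx(i, j)] > h) { h = F[idx(i, j)]; b = 3; }
      H[idx(i, j)] = h; B[idx(i, j)] = b;
    }
  }
  long best = NEG; int bj = m; // ties -> fewest copies
  for (int j = m; j <= W; j += m)
    if (H[idx(L, j)] > best) { best = H[idx(L, j)]; bj = j; }

  std::vector<int> motif_index(L, 0);
  int ncopy = bj / m;
  std::vector<int> n_del(ncopy, 0), n_ins(ncopy, 0);
  int i = L, j = bj, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      unsigned char b = B[idx(i, j)];
      if (b == 1) { motif_index[i - 1] = (j - 1) / m + 1; --i; --j; }
      else if (b == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // inserted segment character
      int copy = j > 0 ? (j - 1) / m + 1 : 1;
      motif_index[i - 1] = copy;
      n_ins[copy - 1] += 1;
      state = BE[idx(i, j)] == 1 ? 0 : 1;
      --i;
    } else { // deleted consensus character
      n_del[(j - 1) / m] += 1;
      state = BF[idx(i, j)] == 1 ? 0 : 2;
      --j;
    }
  }
  return List::create(_["score"] = (double)best,
                      _["motif_index"] = wrap(motif_index),
                      _["n_del"] = wrap(n_del), _["n_ins"] = wrap(n_ins));
}
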