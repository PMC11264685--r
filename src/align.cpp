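// Core alignment kernels: exact word seeding, ungapped X-drop extension and
// (banded) affine-gap Smith-Waterman with traceback. Coordinates are 1-based
// inclusive on both sequences; a band restricts the diagonal d = j - i.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // ambiguous: never seeds, mismatches everything
  }
}

// [[Rcpp::export]]
IntegerMatrix find_seeds_cpp(std::string query, std::string subject, int w) {
  int nq = (int)query.size(), ns = (int)subject.size();
  std::vector<std::pair<int, int> > out;
  if (w < 1 || w > nq || w > ns)
    return IntegerMatrix(0, 2);
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t key = 0;
  uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;
  for (int i = 0; i < nq; ++i) {
    int e = enc_base(query[i]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run >= w) idx[key].push_back(i - w + 2);  // 1-based start
  }
  key = 0; run = 0;
  for (int j = 0; j < ns; ++j) {
    int e = enc_base(subject[j]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run >= w) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(key);
      if (it != idx.end()) {
        int sstart = j - w + 2;
        for (size_t k = 0; k < it->second.size(); ++k)
          out.push_back(std::make_pair(it->second[k], sstart));
      }
    }
  }
  IntegerMatrix m((int)out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    m((int)i, 0) = out[i].first;
    m((int)i, 1) = out[i].second;
  }
  colnames(m) = CharacterVector::create("qstart", "sstart");
  return m;
}

// Ungapped extension of an exact seed in both directions, stopping when the
// running score drops more than `xdrop` below the running maximum.
// [[Rcpp::export]]
IntegerVector ungapped_extend_cpp(std::string a, std::string b,
                                  int qstart, int sstart, int w,
                                  int match, int mismatch, int xdrop) {
  int na = (int)a.size(), nb = (int)b.size();
  int score = w * match;
  int qlo = qstart, qhi = qstart + w - 1, slo = sstart, shi = sstart + w - 1;
  // right
  {
    int best = score, cur = score, bq = qhi, bs = shi;
    int i = qhi + 1, j = shi + 1;
    while (i <= na && j <= nb) {
      int ea = enc_base(a[i - 1]), eb = enc_base(b[j - 1]);
      cur += (ea >= 0 && ea == eb) ? match : mismatch;
      if (cur > best) { best = cur; bq = i; bs = j; }
      if (best - cur > xdrop) break;
      ++i; ++j;
    }
    qhi = bq; shi = bs; score = best;
  }
  // left
  {
    int best = score, cur = score, bq = qlo, bs = slo;
    int i = qlo - 1, j = slo - 1;
    while (i >= 1 && j >= 1) {
      int ea = enc_base(a[i - 1]), eb = enc_base(b[j - 1]);
      cur += (ea >= 0 && ea == eb) ? match : mismatch;
      if (cur > best) { best = cur; bq = i; bs = j; }
      if (best - cur > xdrop) break;
      --i; --j;
    }
    qlo = bq; slo = bs; score = best;
  }
  return IntegerVector::create(_["qstart"] = qlo, _["qend"] = qhi,
                               _["sstart"] = slo, _["send"] = shi,
                               _["score"] = score);
}

// Affine-gap local alignment with traceback. A gap of length L costs
// gap_open + L * gap_extend. Cells with diagonal j - i outside
// [diag_lo, diag_hi] are excluded (pass -na, nb for the full matrix).
// Ties on the optimal score are broken by the smallest end coordinate in b,
// then in a.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int diag_lo, int diag_hi) {
  const int NEG = INT_MIN / 4;
  int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) stop("empty sequence");
  size_t ncell = (size_t)(na + 1) * (size_t)(nb + 1);
  std::vector<int> H(ncell, 0), E(ncell, NEG), F(ncell, NEG);
  // tb_h: 0 stop, 1 diag, 2 from E (gap in a, consumes b), 3 from F
  std::vector<unsigned char> tb_h(ncell, 0), tb_e(ncell, 0), tb_f(ncell, 0);
  std::vector<int> ea(na), eb(nb);
  for (int i = 0; i < na; ++i) ea[i] = enc_base(a[i]);
  for (int j = 0; j < nb; ++j) eb[j] = enc_base(b[j]);

  int best = 0, bi = 0, bj = 0;
  const int gi = gap_open + gap_extend;
  for (int i = 1; i <= na; ++i) {
    int jlo = i + diag_lo, jhi = i + diag_hi;
    if (jlo < 1) jlo = 1;
    if (jhi > nb) jhi = nb;
    size_t row = (size_t)i * (nb + 1), prow = (size_t)(i - 1) * (nb + 1);
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = row + j;
      // E: gap in a (move along b)
      {
        int open = H[c - 1] - gi;
        int ext = E[c - 1] - gap_extend;
        if (open >= ext) { E[c] = open; tb_e[c] = 1; }
        else { E[c] = ext; tb_e[c] = 0; }
      }
      // F: gap in b (move along a)
      {
        int open = H[prow + j] - gi;
        int ext = F[prow + j] - gap_extend;
        if (open >= ext) { F[c] = open; tb_f[c] = 1; }
        else { F[c] = ext; tb_f[c] = 0; }
      }
      int s = (ea[i - 1] >= 0 && ea[i - 1] == eb[j - 1]) ? match : mismatch;
      int diag = H[prow + j - 1] + s;
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      H[c] = h; tb_h[c] = t;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = "", _["b_aln"] = "");

  std::string alnA, alnB;
  int i = bi, j = bj;
  int state = 0;  // 0 = H
  while (true) {
    size_t c = (size_t)i * (nb + 1) + j;
    if (state == 0) {
      unsigned char t = tb_h[c];
      if (t == 0) break;
      if (t == 1) {
        alnA.push_back(a[i - 1]); alnB.push_back(b[j - 1]);
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      alnA.push_back('-'); alnB.push_back(b[j - 1]);
      unsigned char t = tb_e[c];
      --j;
      if (t == 1) state = 0;
    } else {
      alnA.push_back(a[i - 1]); alnB.push_back('-');
      unsigned char t = tb_f[c];
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(alnA.begin(), alnA.end());
  std::reverse(alnB.begin(), alnB.end());
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["a_aln"] = alnA, _["b_aln"] = alnB);
}
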