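// Smith-Waterman local alignment with affine gaps, multi-HSP by query
// masking.  Gap convention: the first residue of a gap costs
// gap_open + gap_extend, each further residue gap_extend (BLAST-style).
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const int NEG = std::numeric_limits<int>::min() / 4;

struct Aln {
  int score, qs, qe, ss, se, len, ident, mismatch, gapopen;
};

// one SW pass over query x subject; cells in masked query columns are
// forced to zero so no alignment path crosses an already-used residue
bool sw_once(const std::vector<int>& q, const std::vector<int>& s,
             const std::vector<int>& mat, int nres, int go, int ge,
             const std::vector<char>& qused, int floor_score, Aln& out) {
  const int m = q.size(), n = s.size();
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  // traceback codes: 0 stop, 1 diag, 2 from F (gap in subject), 3 from E
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const bool masked = qused[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int c = i * (n + 1) + j;
      if (masked) { H[c] = 0; E[c] = NEG; F[c] = NEG; continue; }
      const int up = (i - 1) * (n + 1) + j, left = c - 1,
                diag = up - 1;
      int e_open = H[left] - go - ge, e_ext = E[left] - ge;
      E[c] = e_open >= e_ext ? e_open : e_ext;
      tbE[c] = e_open >= e_ext ? 0 : 1;
      int f_open = H[up] - go - ge, f_ext = F[up] - ge;
      F[c] = f_open >= f_ext ? f_open : f_ext;
      tbF[c] = f_open >= f_ext ? 0 : 1;
      int d = H[diag] + mat[q[i - 1] * nres + s[j - 1]];
      int h = 0; unsigned char tb = 0;
      if (d > h) { h = d; tb = 1; }
      if (F[c] > h) { h = F[c]; tb = 2; }
      if (E[c] > h) { h = E[c]; tb = 3; }
      H[c] = h; tbH[c] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best < floor_score || best <= 0) return false;
  // traceback
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  int qs = bi, qe = bi, ss = bj, se = bj;
  int len = 0, ident = 0, mism = 0, gopen = 0;
  while (true) {
    const int c = i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[c];
      if (tb == 0) break;
      if (tb == 1) {
        ++len;
        if (q[i - 1] == s[j - 1]) ++ident; else ++mism;
        qs = i; ss = j; --i; --j;
      } else if (tb == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: gap in query, consumes subject residue
      ++len; ss = j;
      if (tbE[c] == 0) { state = 0; ++gopen; }
      --j;
    } else { // F: gap in subject, consumes query residue
      ++len; qs = i;
      if (tbF[c] == 0) { state = 0; ++gopen; }
      --i;
    }
  }
  out.score = best;
  out.qs = qs - 1; out.qe = qe; out.ss = ss - 1; out.se = se;
  out.len = len; out.ident = ident; out.mismatch = mism; out.gapopen = gopen;
  return true;
}

std::vector<Aln> sw_pair(const std::vector<int>& q, const std::vector<int>& s,
                         const std::vector<int>& mat, int nres, int go,
                         int ge, int floor_score, int max_aln) {
  std::vector<Aln> res;
  std::vector<char> qused(q.size(), 0);
  for (int k = 0; k < max_aln; ++k) {
    Aln a;
    if (!sw_once(q, s, mat, nres, go, ge, qused, floor_score, a)) break;
    res.push_back(a);
    for (int i = a.qs; i < a.qe; ++i) qused[i] = 1;
  }
  return res;
}

std::vector<int> as_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// row-major flat copy: cheap residue lookups in the DP inner loop
std::vector<int> flat_matrix(const IntegerMatrix& mat) {
  const int n = mat.nrow();
  std::vector<int> f(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) f[i * n + j] = mat(i, j);
  return f;
}

} // namespace

// [[Rcpp::export]]
DataFrame sw_align_cpp(IntegerVector query, IntegerVector subject,
                       IntegerMatrix mat, int gap_open, int gap_extend,
                       int score_floor, int max_alignments) {
  std::vector<Aln> res = sw_pair(as_vec(query), as_vec(subject),
                                 flat_matrix(mat), mat.nrow(),
                                 gap_open, gap_extend,
                                 std::max(score_floor, 1), max_alignments);
  const int k = res.size();
  IntegerVector score(k), qs(k), qe(k), ss(k), se(k), len(k), id(k), mm(k),
      gp(k);
  for (int i = 0; i < k; ++i) {
    score[i] = res[i].score; qs[i] = res[i].qs; qe[i] = res[i].qe;
    ss[i] = res[i].ss; se[i] = res[i].se; len[i] = res[i].len;
    id[i] = res[i].ident; mm[i] = res[i].mismatch; gp[i] = res[i].gapopen;
  }
  return DataFrame::create(
      _["raw_score"] = score, _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se, _["length"] = len,
      _["n_ident"] = id, _["n_mismatch"] = mm, _["n_gapopen"] = gp);
}

// [[Rcpp::export]]
DataFrame sw_search_cpp(IntegerVector query, List subjects, IntegerMatrix mat,
                        int gap_open, int gap_extend, int score_floor,
                        int max_alignments) {
  std::vector<int> q = as_vec(query);
  std::vector<int> fm = flat_matrix(mat);
  std::vector<int> sub_idx;
  std::vector<Aln> all;
  for (int si = 0; si < subjects.size(); ++si) {
    std::vector<int> s = as_vec(subjects[si]);
    std::vector<Aln> res = sw_pair(q, s, fm, mat.nrow(), gap_open,
                                   gap_extend, std::max(score_floor, 1),
                                   max_alignments);
    for (size_t r = 0; r < res.size(); ++r) {
      all.push_back(res[r]);
      sub_idx.push_back(si + 1);
    }
  }
  const int k = all.size();
  IntegerVector subj(k), score(k), qs(k), qe(k), ss(k), se(k), len(k), id(k),
      mm(k), gp(k);
  for (int i = 0; i < k; ++i) {
    subj[i] = sub_idx[i];
    score[i] = all[i].score; qs[i] = all[i].qs; qe[i] = all[i].qe;
    ss[i] = all[i].ss; se[i] = all[i].se; len[i] = all[i].len;
    id[i] = all[i].ident; mm[i] = all[i].mismatch; gp[i] = all[i].gapopen;
  }
  return DataFrame::create(
      _["subject_index"] = subj, _["raw_score"] = score, _["q_start"] = qs,
      _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["length"] = len, _["n_ident"] = id, _["n_mismatch"] = mm,
      _["n_gapopen"] = gp);
}
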