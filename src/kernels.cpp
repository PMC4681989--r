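#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Gapless shift-limited alignment of b against a: residue b[j] pairs with
// a[j + s]. Trailing overhangs score 0. Ties: smaller |s|, then negative s.
// Sequences are 1-based integer residue codes.
static void shift_align(const int* a, int la, const int* b, int lb,
                        const double* mat, int max_shift,
                        double& best_score, int& best_shift, int& best_ov) {
  best_score = NEG_INF;
  best_shift = 0;
  best_ov = 0;
  for (int abs_s = 0; abs_s <= max_shift; ++abs_s) {
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      if (abs_s == 0 && sgn == 1) continue;
      int s = sgn * abs_s;
      int j0 = std::max(0, -s);
      int j1 = std::min(lb, la - s);  // exclusive
      if (j1 <= j0) continue;
      double sc = 0.0;
      for (int j = j0; j < j1; ++j)
        sc += mat[(a[j + s] - 1) + 20 * (b[j] - 1)];
      if (sc > best_score) {
        best_score = sc;
        best_shift = s;
        best_ov = j1 - j0;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_shift_align(IntegerVector a, IntegerVector b, NumericMatrix mat,
                     int max_shift) {
  double score; int shift, ov;
  shift_align(a.begin(), a.size(), b.begin(), b.size(), mat.begin(),
              max_shift, score, shift, ov);
  return List::create(_["score"] = score, _["shift"] = shift,
                      _["overlap"] = ov);
}

// One full greedy incremental clustering pass. seqs: list of 1-based integer
// residue vectors, already in insertion order. Each sequence joins the
// best-scoring existing representative if that score >= threshold (ties:
// earliest-created cluster), else founds a new cluster. Returns 1-based
// cluster ids, the shift of each member against its representative, and the
// alignment score.
// [[Rcpp::export]]
List cpp_greedy(List seqs, NumericMatrix mat, double threshold,
                int max_shift) {
  int n = seqs.size();
  IntegerVector cl(n), shifts(n);
  NumericVector scores(n);
  std::vector<std::vector<int> > reps;   // representative residue codes
  std::vector<int> rep_cluster;          // cluster id per representative
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    double best = NEG_INF; int best_rep = -1, best_shift = 0;
    for (size_t r = 0; r < reps.size(); ++r) {
      double sc; int sh, ov;
      shift_align(&reps[r][0], (int)reps[r].size(), s.begin(), s.size(),
                  mat.begin(), max_shift, sc, sh, ov);
      if (sc > best) { best = sc; best_rep = (int)r; best_shift = sh; }
    }
    if (best_rep >= 0 && best >= threshold) {
      cl[i] = rep_cluster[best_rep];
      shifts[i] = best_shift;
      scores[i] = best;
    } else {
      reps.push_back(std::vector<int>(s.begin(), s.end()));
      int id = (int)reps.size();
      rep_cluster.push_back(id);
      cl[i] = id;
      shifts[i] = 0;
      double sc; int sh, ov;
      shift_align(s.begin(), s.size(), s.begin(), s.size(), mat.begin(), 0,
                  sc, sh, ov);
      scores[i] = sc;
    }
  }
  return List::create(_["cluster"] = cl, _["shift"] = shifts,
                      _["score"] = scores);
}

// Local Viterbi over a profile HMM in log2-odds space.
//
// m_lo:  K x 20 match-emission log-odds log2(e_k(r) / bg(r)).
// trans: K x 7 log2 transition probabilities, columns
//        (MM, MI, MD, IM, II, DM, DD); row k describes transitions leaving
//        position k+1 (0-based row k). Row K-1 is unused (free exit).
// seq:   1-based residue codes.
//
// Free uniform entry into any match state (log2(1/K)), free exit from any
// match state; unaligned flanking residues and insert emissions score 0.
static void viterbi_core(const NumericMatrix& m_lo, const NumericMatrix& trans,
                         const IntegerVector& seq, double& best,
                         int& best_i, int& best_k,
                         std::vector<std::vector<double> >& VM,
                         std::vector<std::vector<double> >& VI,
                         std::vector<std::vector<double> >& VD) {
  int K = m_lo.nrow(), L = seq.size();
  double entry = -std::log2((double)K);
  VM.assign(L + 1, std::vector<double>(K + 1, NEG_INF));
  VI.assign(L + 1, std::vector<double>(K + 1, NEG_INF));
  VD.assign(L + 1, std::vector<double>(K + 1, NEG_INF));
  best = NEG_INF; best_i = 0; best_k = 0;
  for (int i = 1; i <= L; ++i) {
    int r = seq[i - 1] - 1;
    for (int k = 1; k <= K; ++k) {
      double m = entry;  // fresh local start at (i, k)
      if (i > 1 && k > 1) {
        double v;
        v = VM[i - 1][k - 1] + trans(k - 2, 0); if (v > m) m = v;
        v = VI[i - 1][k - 1] + trans(k - 2, 3); if (v > m) m = v;
        v = VD[i - 1][k - 1] + trans(k - 2, 5); if (v > m) m = v;
      }
      VM[i][k] = m_lo(k - 1, r) + m;
      if (VM[i][k] > best) { best = VM[i][k]; best_i = i; best_k = k; }
      if (i > 1 && k < K) {
        double v1 = VM[i - 1][k] + trans(k - 1, 1);
        double v2 = VI[i - 1][k] + trans(k - 1, 4);
        VI[i][k] = std::max(v1, v2);
      }
      if (k > 1) {
        double v1 = VM[i][k - 1] + trans(k - 2, 2);
        double v2 = VD[i][k - 1] + trans(k - 2, 6);
        VD[i][k] = std::max(v1, v2);
      }
    }
  }
}

// [[Rcpp::export]]
double cpp_viterbi_score(NumericMatrix m_lo, NumericMatrix trans,
                         IntegerVector seq) {
  double best; int bi, bk;
  std::vector<std::vector<double> > VM, VI, VD;
  viterbi_core(m_lo, trans, seq, best, bi, bk, VM, VI, VD);
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_score_many(NumericMatrix m_lo, NumericMatrix trans,
                                     List seqs) {
  int n = seqs.size();
  NumericVector out(n);
  std::vector<std::vector<double> > VM, VI, VD;
  for (int i = 0; i < n; ++i) {
    double best; int bi, bk;
    viterbi_core(m_lo, trans, seqs[i], best, bi, bk, VM, VI, VD);
    out[i] = best;
  }
  return out;
}

// Full Viterbi with traceback. Returns the best score, the state path as
// parallel vectors (state: 1=M, 2=I, 3=D; k: match/insert position; i:
// consumed sequence position, 0 for deletions), ordered along the alignment.
// [[Rcpp::export]]
List cpp_viterbi_path(NumericMatrix m_lo, NumericMatrix trans,
                      IntegerVector seq) {
  int K = m_lo.nrow();
  double best; int bi, bk;
  std::vector<std::vector<double> > VM, VI, VD;
  viterbi_core(m_lo, trans, seq, best, bi, bk, VM, VI, VD);
  double entry = -std::log2((double)K);
  const double eps = 1e-9;
  std::vector<int> st, pk, pi;
  int state = 1, i = bi, k = bk;
  while (true) {
    st.push_back(state); pk.push_back(k); pi.push_back(state == 3 ? 0 : i);
    if (state == 1) {
      int r = seq[i - 1] - 1;
      double need = VM[i][k] - m_lo(k - 1, r);
      if (std::abs(need - entry) < eps && !(i > 1 && k > 1 &&
          (std::abs(VM[i - 1][k - 1] + trans(k - 2, 0) - need) < eps ||
           std::abs(VI[i - 1][k - 1] + trans(k - 2, 3) - need) < eps ||
           std::abs(VD[i - 1][k - 1] + trans(k - 2, 5) - need) < eps))) {
        break;  // local entry
      }
      if (i > 1 && k > 1 &&
          std::abs(VM[i - 1][k - 1] + trans(k - 2, 0) - need) < eps) {
        state = 1; --i; --k;
      } else if (i > 1 && k > 1 &&
                 std::abs(VI[i - 1][k - 1] + trans(k - 2, 3) - need) < eps) {
        state = 2; --i; --k;
      } else if (i > 1 && k > 1 &&
                 std::abs(VD[i - 1][k - 1] + trans(k - 2, 5) - need) < eps) {
        state = 3; --i; --k;
      } else {
        break;  // local entry
      }
    } else if (state == 2) {
      if (std::abs(VI[i][k] - (VM[i - 1][k] + trans(k - 1, 1))) < eps) {
        state = 1; --i;
      } else {
        state = 2; --i;
      }
    } else {
      if (std::abs(VD[i][k] - (VM[i][k - 1] + trans(k - 2, 2))) < eps) {
        state = 1; --k;
      } else {
        state = 3; --k;
      }
    }
  }
  std::reverse(st.begin(), st.end());
  std::reverse(pk.begin(), pk.end());
  std::reverse(pi.begin(), pi.end());
  return List::create(_["score"] = best,
                      _["state"] = IntegerVector(st.begin(), st.end()),
                      _["k"] = IntegerVector(pk.begin(), pk.end()),
                      _["i"] = IntegerVector(pi.begin(), pi.end()));
}
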