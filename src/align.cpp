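#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh three-state) global alignment.
// Gap of length L costs gap_open + L * gap_extend; end gaps are
// penalized. Traceback tie-break is fixed: diagonal > up (gap in s2)
// > left (gap in s1), applied to the state choice and within each
// state's predecessors, so results are deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string s1, std::string s2,
                  NumericMatrix submat, CharacterVector alphabet,
                  double gap_open, double gap_extend) {
  int n = s1.size(), m = s2.size();
  std::vector<int> idx(256, -1);
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string a = as<std::string>(alphabet[i]);
    idx[(unsigned char)a[0]] = i;
  }
  std::vector<int> a1(n), a2(m);
  for (int i = 0; i < n; ++i) {
    a1[i] = idx[(unsigned char)s1[i]];
    if (a1[i] < 0) stop("non-amino-acid character '%s' in sequence 1",
                        std::string(1, s1[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    a2[j] = idx[(unsigned char)s2[j]];
    if (a2[j] < 0) stop("non-amino-acid character '%s' in sequence 2",
                        std::string(1, s2[j]).c_str());
  }

  // M: s1[i] aligned to s2[j]; X: gap in s2 (consume s1, "up");
  // Y: gap in s1 (consume s2, "left").
  int R = n + 1, C = m + 1;
  std::vector<double> M(R * C, NEG_INF), X(R * C, NEG_INF),
      Y(R * C, NEG_INF);
  // trace codes: predecessor state 0=M,1=X,2=Y, -1 none
  std::vector<signed char> tM(R * C, -1), tX(R * C, -1), tY(R * C, -1);
  auto at = [C](int i, int j) { return i * C + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + i * gap_extend);
    tX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + j * gap_extend);
    tY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = submat(a1[i - 1], a2[j - 1]);
      // M from best of M/X/Y at (i-1, j-1), tie-break M > X > Y
      double pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
             py = Y[at(i - 1, j - 1)];
      double best = pm; signed char tb = 0;
      if (px > best) { best = px; tb = 1; }
      if (py > best) { best = py; tb = 2; }
      if (best > NEG_INF / 2) {
        M[at(i, j)] = best + sub;
        tM[at(i, j)] = tb;
      }
      // X: gap in s2, from (i-1, j)
      double open = M[at(i - 1, j)] - (gap_open + gap_extend);
      double ext = X[at(i - 1, j)] - gap_extend;
      if (open >= ext) { X[at(i, j)] = open; tX[at(i, j)] = 0; }
      else { X[at(i, j)] = ext; tX[at(i, j)] = 1; }
      // Y: gap in s1, from (i, j-1)
      open = M[at(i, j - 1)] - (gap_open + gap_extend);
      ext = Y[at(i, j - 1)] - gap_extend;
      if (open >= ext) { Y[at(i, j)] = open; tY[at(i, j)] = 0; }
      else { Y[at(i, j)] = ext; tY[at(i, j)] = 2; }
    }
  }

  double sM = M[at(n, m)], sX = X[at(n, m)], sY = Y[at(n, m)];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  // traceback
  std::string o1, o2;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM[at(i, j)];
      o1.push_back(s1[i - 1]); o2.push_back(s2[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX[at(i, j)];
      o1.push_back(s1[i - 1]); o2.push_back('-');
      --i; state = prev;
    } else {
      int prev = tY[at(i, j)];
      o1.push_back('-'); o2.push_back(s2[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(o1.begin(), o1.end());
  std::reverse(o2.begin(), o2.end());

  int len = o1.size(), matches = 0, positives = 0;
  for (int k = 0; k < len; ++k) {
    if (o1[k] == '-' || o2[k] == '-') continue;
    if (o1[k] == o2[k]) { ++matches; ++positives; }
    else if (submat(idx[(unsigned char)o1[k]],
                    idx[(unsigned char)o2[k]]) > 0) ++positives;
  }
  return List::create(
      _["score"] = score,
      _["identity"] = 100.0 * matches / len,
      _["similarity"] = 100.0 * positives / len,
      _["matches"] = matches,
      _["alignment_length"] = len,
      _["aligned1"] = o1, _["aligned2"] = o2);
}

// All-pairs percent identity for a set of sequences; returns a symmetric
// matrix with 100 on the diagonal. Optional 4-mer prefilter: pairs
// sharing no length-4 substring are skipped (identity set to 0).
// [[Rcpp::export(name = ".pairwise_identity_cpp")]]
NumericMatrix pairwise_identity_cpp(CharacterVector seqs,
                                    NumericMatrix submat,
                                    CharacterVector alphabet,
                                    double gap_open, double gap_extend,
                                    bool kmer_prefilter) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<std::vector<std::string>> kmers(n);
  if (kmer_prefilter) {
    for (int i = 0; i < n; ++i) {
      std::vector<std::string> ks;
      for (int p = 0; p + 4 <= (int)ss[i].size(); ++p)
        ks.push_back(ss[i].substr(p, 4));
      std::sort(ks.begin(), ks.end());
      ks.erase(std::unique(ks.begin(), ks.end()), ks.end());
      kmers[i] = ks;
    }
  }
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      if (kmer_prefilter) {
        std::vector<std::string> shared;
        std::set_intersection(kmers[i].begin(), kmers[i].end(),
                              kmers[j].begin(), kmers[j].end(),
                              std::back_inserter(shared));
        if (shared.empty()) { out(i, j) = out(j, i) = 0.0; continue; }
      }
      List a = nw_align_cpp(ss[i], ss[j], submat, alphabet,
                            gap_open, gap_extend);
      double id = as<double>(a["identity"]);
      out(i, j) = out(j, i) = id;
    }
  }
  return out;
}
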