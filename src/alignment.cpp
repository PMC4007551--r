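#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap convention throughout: a gap of length L costs
// gap_open + gap_extend * L (BLAST "existence 11, extension 1" style).

namespace {

const double NEG_INF = -1e30;

struct AlnStats {
  double score;
  int qstart, qend, sstart, send;   // 1-based, inclusive; 0 if empty aln
  int length, matches, mismatches, gapopens, gaps;
  int cols_nogap, matches_nogap;    // gap-free columns (for distances)
};

// map residues through the matrix alphabet; unknown residue -> error
std::vector<int> encode(const std::string &s, const std::string &alpha) {
  int lut[256];
  std::memset(lut, -1, sizeof(lut));
  for (size_t i = 0; i < alpha.size(); ++i)
    lut[(unsigned char)alpha[i]] = (int)i;
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    if (c < 0)
      stop("residue '%s' not in substitution-matrix alphabet",
           std::string(1, s[i]).c_str());
    v[i] = c;
  }
  return v;
}

// Smith-Waterman local alignment with affine gaps, full traceback.
AlnStats sw_local(const std::vector<int> &a, const std::vector<int> &b,
                  const double *S, int K, double go, double ge) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  // traceback codes: H: 0 stop, 1 diag, 2 from F (gap in b / vertical),
  //                  3 from E (gap in a / horizontal)
  std::vector<unsigned char> tH((n + 1) * W, 0), tE((n + 1) * W, 0),
      tF((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double eo = H[ij - 1] - (go + ge), ee = E[ij - 1] - ge;
      E[ij] = (eo >= ee) ? (tE[ij] = 1, eo) : (tE[ij] = 0, ee);
      double fo = H[ij - W] - (go + ge), fe = F[ij - W] - ge;
      F[ij] = (fo >= fe) ? (tF[ij] = 1, fo) : (tF[ij] = 0, fe);
      double d = H[ij - W - 1] + S[a[i - 1] * K + b[j - 1]];
      double h = 0.0;
      unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (F[ij] > h) { h = F[ij]; t = 2; }
      if (E[ij] > h) { h = E[ij]; t = 3; }
      H[ij] = h;
      tH[ij] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnStats st{};
  st.score = best;
  if (best <= 0.0) return st;  // empty local alignment
  // traceback
  int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
  st.qend = bi; st.send = bj;
  while (true) {
    int ij = i * W + j;
    if (state == 0) {
      unsigned char t = tH[ij];
      if (t == 0) break;
      if (t == 1) {
        ++st.length; ++st.cols_nogap;
        if (a[i - 1] == b[j - 1]) { ++st.matches; ++st.matches_nogap; }
        else ++st.mismatches;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 1;
    } else if (state == 1) {  // E: gap in a, consume b
      ++st.length; ++st.gaps;
      if (tE[ij] == 1) { ++st.gapopens; state = 0; }
      --j;
    } else {  // F: gap in b, consume a
      ++st.length; ++st.gaps;
      if (tF[ij] == 1) { ++st.gapopens; state = 0; }
      --i;
    }
    if (i == 0 && j == 0) break;
  }
  st.qstart = i + 1;
  st.sstart = j + 1;
  return st;
}

// Needleman-Wunsch global alignment with affine gaps (end gaps penalized).
AlnStats nw_global(const std::vector<int> &a, const std::vector<int> &b,
                   const double *S, int K, double go, double ge) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, NEG_INF), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tH((n + 1) * W, 0), tE((n + 1) * W, 0),
      tF((n + 1) * W, 0);
  H[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[j] = -(go + ge * j);
    tE[j] = (j == 1);
    H[j] = E[j];
    tH[j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    F[i * W] = -(go + ge * i);
    tF[i * W] = (i == 1);
    H[i * W] = F[i * W];
    tH[i * W] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double eo = H[ij - 1] - (go + ge), ee = E[ij - 1] - ge;
      E[ij] = (eo >= ee) ? (tE[ij] = 1, eo) : (tE[ij] = 0, ee);
      double fo = H[ij - W] - (go + ge), fe = F[ij - W] - ge;
      F[ij] = (fo >= fe) ? (tF[ij] = 1, fo) : (tF[ij] = 0, fe);
      double d = H[ij - W - 1] + S[a[i - 1] * K + b[j - 1]];
      double h = d;
      unsigned char t = 1;
      if (F[ij] > h) { h = F[ij]; t = 2; }
      if (E[ij] > h) { h = E[ij]; t = 3; }
      H[ij] = h;
      tH[ij] = t;
    }
  }
  AlnStats st{};
  st.score = H[n * W + m];
  st.qstart = n > 0 ? 1 : 0;
  st.qend = n;
  st.sstart = m > 0 ? 1 : 0;
  st.send = m;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    int ij = i * W + j;
    if (state == 0) {
      unsigned char t = tH[ij];
      if (t == 1) {
        ++st.length; ++st.cols_nogap;
        if (a[i - 1] == b[j - 1]) { ++st.matches; ++st.matches_nogap; }
        else ++st.mismatches;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 1;
    } else if (state == 1) {
      ++st.length; ++st.gaps;
      if (tE[ij] == 1) { ++st.gapopens; state = 0; }
      --j;
    } else {
      ++st.length; ++st.gaps;
      if (tF[ij] == 1) { ++st.gapopens; state = 0; }
      --i;
    }
  }
  return st;
}

List stats_to_list(const AlnStats &st) {
  return List::create(
      _["score"] = st.score, _["qstart"] = st.qstart, _["qend"] = st.qend,
      _["sstart"] = st.sstart, _["send"] = st.send, _["length"] = st.length,
      _["matches"] = st.matches, _["mismatches"] = st.mismatches,
      _["gapopens"] = st.gapopens, _["gaps"] = st.gaps,
      _["cols_nogap"] = st.cols_nogap, _["matches_nogap"] = st.matches_nogap);
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  std::string alphabet, double gap_open, double gap_extend) {
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  return stats_to_list(
      sw_local(ea, eb, REAL(submat), submat.nrow(), gap_open, gap_extend));
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  std::string alphabet, double gap_open, double gap_extend) {
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  return stats_to_list(
      nw_global(ea, eb, REAL(submat), submat.nrow(), gap_open, gap_extend));
}

// Batch Smith-Waterman over candidate (query, subject) index pairs; one C++
// call per hit table keeps the all-vs-all search fast.
// [[Rcpp::export(name = ".sw_batch_cpp")]]
DataFrame sw_batch_cpp(CharacterVector seqs_q, CharacterVector seqs_s,
                       IntegerVector qi, IntegerVector si,
                       NumericMatrix submat, std::string alphabet,
                       double gap_open, double gap_extend) {
  if (qi.size() != si.size()) stop("index vectors differ in length");
  const int K = submat.nrow();
  const double *S = REAL(submat);
  std::vector<std::vector<int> > eq(seqs_q.size()), es(seqs_s.size());
  for (int i = 0; i < seqs_q.size(); ++i)
    eq[i] = encode(as<std::string>(seqs_q[i]), alphabet);
  for (int i = 0; i < seqs_s.size(); ++i)
    es[i] = encode(as<std::string>(seqs_s[i]), alphabet);
  const int np = qi.size();
  NumericVector score(np);
  IntegerVector qstart(np), qend(np), sstart(np), send(np), length(np),
      matches(np), mismatches(np), gapopens(np);
  for (int p = 0; p < np; ++p) {
    AlnStats st =
        sw_local(eq[qi[p] - 1], es[si[p] - 1], S, K, gap_open, gap_extend);
    score[p] = st.score;
    qstart[p] = st.qstart; qend[p] = st.qend;
    sstart[p] = st.sstart; send[p] = st.send;
    length[p] = st.length; matches[p] = st.matches;
    mismatches[p] = st.mismatches; gapopens[p] = st.gapopens;
  }
  return DataFrame::create(
      _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send, _["length"] = length,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gapopens"] = gapopens);
}
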