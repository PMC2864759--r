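#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length k costs open + k*ext,
// i.e. the first gapped residue costs open+ext (Biostrings convention).
// Traceback ties: diagonal > up (gap in subject) > left (gap in query).

namespace {

struct AlnResult {
  double score;
  int n_ident, n_cols;      // identity counted over residue-residue columns only
  int q0, q1, s0, s1;       // 0-based half-open spans on query/subject
  bool found;
};

struct ScoreScheme {
  std::vector<double> sub;  // nres x nres
  int idx[256];
  int nres;
  double lookup(unsigned char a, unsigned char b) const {
    int ia = idx[a], ib = idx[b];
    if (ia < 0 || ib < 0)
      stop("residue '%s' not present in the substitution matrix",
           std::string(1, (char)(ia < 0 ? a : b)).c_str());
    return sub[ia * nres + ib];
  }
};

ScoreScheme make_scheme(const NumericMatrix& submat) {
  ScoreScheme sc;
  sc.nres = submat.nrow();
  if (submat.ncol() != sc.nres) stop("substitution matrix must be square");
  List dn = submat.attr("dimnames");
  if (dn.size() != 2) stop("substitution matrix must have dimnames");
  CharacterVector rn = dn[0];
  for (int i = 0; i < 256; ++i) sc.idx[i] = -1;
  for (int i = 0; i < sc.nres; ++i) {
    std::string r = as<std::string>(rn[i]);
    if (r.size() != 1) stop("substitution matrix row names must be single residues");
    sc.idx[(unsigned char)r[0]] = i;
  }
  sc.sub.resize((size_t)sc.nres * sc.nres);
  for (int i = 0; i < sc.nres; ++i)
    for (int j = 0; j < sc.nres; ++j)
      sc.sub[(size_t)i * sc.nres + j] = submat(i, j);
  return sc;
}

const signed char FROM_M = 0, FROM_IX = 1, FROM_IY = 2, FROM_START = 3;

AlnResult sw_core(const std::string& a, const std::string& b,
                  const ScoreScheme& sc, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30, gap_first = gap_open + gap_extend;
  std::vector<double> M((size_t)(n + 1) * (m + 1), 0.0),
      Ix((size_t)(n + 1) * (m + 1), NEG), Iy((size_t)(n + 1) * (m + 1), NEG);
  // traceback: for M, which predecessor state at (i-1,j-1); for Ix/Iy whether opened
  std::vector<signed char> tbM((size_t)(n + 1) * (m + 1), FROM_START);
  std::vector<signed char> opIx((size_t)(n + 1) * (m + 1), 0),
      opIy((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = at(i, j);
      // gaps: Ix consumes a (up), Iy consumes b (left); open only from M
      double ox = M[at(i - 1, j)] - gap_first, ex = Ix[at(i - 1, j)] - gap_extend;
      if (ox >= ex) { Ix[c] = ox; opIx[c] = 1; } else { Ix[c] = ex; opIx[c] = 0; }
      double oy = M[at(i, j - 1)] - gap_first, ey = Iy[at(i, j - 1)] - gap_extend;
      if (oy >= ey) { Iy[c] = oy; opIy[c] = 1; } else { Iy[c] = ey; opIy[c] = 0; }
      double s = sc.lookup(a[i - 1], b[j - 1]);
      size_t d = at(i - 1, j - 1);
      // tie preference: diagonal (M) > up (Ix) > left (Iy) > fresh start
      double pm = M[d], px = Ix[d], py = Iy[d];
      double pv = pm; signed char pf = FROM_M;
      if (px > pv) { pv = px; pf = FROM_IX; }
      if (py > pv) { pv = py; pf = FROM_IY; }
      double v; // continuing from a non-positive predecessor never beats a fresh start
      if (pv <= 0.0) { v = s; pf = FROM_START; } else { v = pv + s; }
      if (v <= 0.0) { M[c] = 0.0; tbM[c] = FROM_START; }
      else { M[c] = v; tbM[c] = pf; }
      if (M[c] > best + 1e-12) { best = M[c]; bi = i; bj = j; }
    }
  }

  AlnResult r; r.score = best; r.n_ident = 0; r.n_cols = 0;
  r.q0 = r.q1 = r.s0 = r.s1 = 0; r.found = best > 0.0;
  if (!r.found) return r;
  int i = bi, j = bj; signed char state = FROM_M;
  r.q1 = i; r.s1 = j;
  bool done = false;
  while (!done) {
    if (state == FROM_M) {
      r.n_cols += 1;
      if (a[i - 1] == b[j - 1]) r.n_ident += 1;
      signed char pf = tbM[at(i, j)];
      --i; --j;
      if (pf == FROM_START) done = true; else state = pf;
    } else if (state == FROM_IX) {
      signed char opened = opIx[at(i, j)];
      --i;
      state = opened ? FROM_M : FROM_IX;
    } else { // FROM_IY
      signed char opened = opIy[at(i, j)];
      --j;
      state = opened ? FROM_M : FROM_IY;
    }
  }
  r.q0 = i; r.s0 = j;
  return r;
}

List result_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["n_ident"] = r.n_ident, _["aligned_cols"] = r.n_cols,
      _["q_start"] = r.q0, _["q_end"] = r.q1, _["s_start"] = r.s0,
      _["s_end"] = r.s1, _["found"] = r.found);
}

} // namespace

// [[Rcpp::export(name = ".sw_align_pair")]]
List sw_align_pair(std::string a, std::string b, NumericMatrix submat,
                   double gap_open, double gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  ScoreScheme sc = make_scheme(submat);
  return result_to_list(sw_core(a, b, sc, gap_open, gap_extend));
}

// All-vs-all search with an optional shared-k-mer prefilter. Returns every
// candidate pair with a positive-score local alignment; reduction (best hit,
// thresholds) happens on the R side.
// [[Rcpp::export(name = ".sw_search")]]
DataFrame sw_search(CharacterVector queries, CharacterVector subjects,
                    NumericMatrix submat, double gap_open, double gap_extend,
                    int k, int min_shared, bool exclude_same_id) {
  ScoreScheme sc = make_scheme(submat);
  const int nq = queries.size(), ns = subjects.size();
  CharacterVector qn = queries.names(), sn = subjects.names();
  if (qn.size() != nq || sn.size() != ns) stop("sequences must be named");
  std::vector<std::string> qs(nq), ss(ns), qid(nq), sid(ns);
  for (int i = 0; i < nq; ++i) { qs[i] = as<std::string>(queries[i]); qid[i] = as<std::string>(qn[i]); }
  for (int i = 0; i < ns; ++i) { ss[i] = as<std::string>(subjects[i]); sid[i] = as<std::string>(sn[i]); }

  bool use_filter = (k > 0 && min_shared > 0);
  std::unordered_map<std::string, std::vector<int>> index;
  if (use_filter) {
    for (int i = 0; i < ns; ++i) {
      if ((int)ss[i].size() < k) continue;
      std::unordered_set<std::string> seen;
      for (size_t p = 0; p + k <= ss[i].size(); ++p) {
        std::string km = ss[i].substr(p, k);
        if (seen.insert(km).second) index[km].push_back(i);
      }
    }
  }

  std::vector<std::string> out_q, out_s;
  std::vector<double> out_score;
  std::vector<int> out_ident, out_cols, out_q0, out_q1, out_s0, out_s1;

  std::vector<int> shared(ns);
  for (int i = 0; i < nq; ++i) {
    std::vector<int> cand;
    if (use_filter) {
      std::fill(shared.begin(), shared.end(), 0);
      std::unordered_set<std::string> seen;
      if ((int)qs[i].size() >= k) {
        for (size_t p = 0; p + k <= qs[i].size(); ++p) {
          std::string km = qs[i].substr(p, k);
          if (!seen.insert(km).second) continue;
          auto it = index.find(km);
          if (it == index.end()) continue;
          for (int j : it->second) shared[j] += 1;
        }
      }
      for (int j = 0; j < ns; ++j)
        if (shared[j] >= min_shared) cand.push_back(j);
    } else {
      cand.resize(ns);
      for (int j = 0; j < ns; ++j) cand[j] = j;
    }
    for (int j : cand) {
      if (exclude_same_id && qid[i] == sid[j]) continue;
      AlnResult r = sw_core(qs[i], ss[j], sc, gap_open, gap_extend);
      if (!r.found) continue;
      out_q.push_back(qid[i]); out_s.push_back(sid[j]);
      out_score.push_back(r.score); out_ident.push_back(r.n_ident);
      out_cols.push_back(r.n_cols);
      out_q0.push_back(r.q0); out_q1.push_back(r.q1);
      out_s0.push_back(r.s0); out_s1.push_back(r.s1);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["query"] = out_q, _["subject"] = out_s, _["score"] = out_score,
      _["n_ident"] = out_ident, _["aligned_cols"] = out_cols,
      _["q_start"] = out_q0, _["q_end"] = out_q1,
      _["s_start"] = out_s0, _["s_end"] = out_s1,
      _["stringsAsFactors"] = false);
}
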