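#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
// Gap of length L costs gap_open + L * gap_extend, the BLAST convention.
// local = Smith-Waterman (cells floored at 0, best cell anywhere);
// global = Needleman-Wunsch with penalized end gaps.
//
// `charmap` maps raw char codes (0..255) to row/column indices of `mat`;
// -1 marks characters absent from the scoring alphabet.

static const int NEG = -1000000000;

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, IntegerMatrix mat,
               IntegerVector charmap, int gap_open, int gap_extend,
               bool local) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 6e7)
    stop("alignment problem too large; chunk the sequences");

  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = charmap[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%s' not in scoring alphabet",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = charmap[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%s' not in scoring alphabet",
                        std::string(1, b[j]));
  }

  int W = m + 1;
  int nmat = mat.nrow();
  std::vector<int> smat(nmat * nmat);
  for (int r = 0; r < nmat; ++r)
    for (int c = 0; c < nmat; ++c) smat[r * nmat + c] = mat(r, c);
  // rolling score rows; full byte matrices kept only for traceback
  // traceback codes: 0 none/stop, 1 diag-from-M, 2 diag-from-X,
  // 3 diag-from-Y; for X/Y: 1 open (from M), 2 extend
  std::vector<int> Mp(W), Mr(W), Xp(W), Xr(W), Yp(W), Yr(W);
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0),
      tX((size_t)(n + 1) * W, 0), tY((size_t)(n + 1) * W, 0);

  int go = gap_open + gap_extend;  // cost of first gapped position
  int ge = gap_extend;
  Mp[0] = 0;
  Xp[0] = Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Yp[j] = local ? NEG : -(gap_open + gap_extend * j);
    tY[j] = (j == 1) ? 1 : 2;
    Mp[j] = local ? 0 : NEG;
    Xp[j] = NEG;
  }

  int best = local ? 0 : NEG, bi_best = 0, bj_best = 0, bstate = 1;
  // NEG is far from INT_MIN, so unconditional arithmetic cannot overflow
  for (int i = 1; i <= n; ++i) {
    Mr[0] = local ? 0 : NEG;
    Xr[0] = local ? NEG : -(gap_open + gap_extend * i);
    tX[(size_t)i * W] = (i == 1) ? 1 : 2;
    Yr[0] = NEG;
    unsigned char *tMr = &tM[(size_t)i * W], *tXr = &tX[(size_t)i * W],
                  *tYr = &tY[(size_t)i * W];
    const int *srow = &smat[(size_t)ai[i - 1] * nmat];
    const int *mp = Mp.data(), *xp = Xp.data(), *yp = Yp.data();
    int *mr = Mr.data(), *xr = Xr.data(), *yr = Yr.data();
    for (int j = 1; j <= m; ++j) {
      // X: gap in b (a[i] vs gap)
      int xo = mp[j] - go, xe = xp[j] - ge;
      if (xo >= xe) { xr[j] = xo; tXr[j] = 1; }
      else          { xr[j] = xe; tXr[j] = 2; }
      // Y: gap in a
      int yo = mr[j - 1] - go, ye = yr[j - 1] - ge;
      if (yo >= ye) { yr[j] = yo; tYr[j] = 1; }
      else          { yr[j] = ye; tYr[j] = 2; }
      // M: a[i] aligned to b[j]
      int s = srow[bi[j - 1]];
      int dm = mp[j - 1] + s, dx = xp[j - 1] + s, dy = yp[j - 1] + s;
      int v = dm; unsigned char t = 1;
      if (dx > v) { v = dx; t = 2; }
      if (dy > v) { v = dy; t = 3; }
      if (local && v < 0) { v = 0; t = 0; }
      mr[j] = v; tMr[j] = t;
      if (local && v > best) { best = v; bi_best = i; bj_best = j; bstate = 1; }
    }
    std::swap(Mp, Mr); std::swap(Xp, Xr); std::swap(Yp, Yr);
  }
  int final_M = Mp[m], final_X = Xp[m], final_Y = Yp[m];
  if (!local) {
    best = final_M; bstate = 1;
    if (final_X > best) { best = final_X; bstate = 2; }
    if (final_Y > best) { best = final_Y; bstate = 3; }
    bi_best = n; bj_best = m;
  }

  // traceback
  std::string aa, ba;
  int i = bi_best, j = bj_best, state = bstate;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (state == 1) {
      if (local && tM[idx] == 0) break;
      if (!local && (i == 0 || j == 0)) {
        // hit a border in global mode: remaining is a pure gap run
        if (i == 0 && j == 0) break;
        state = (i == 0) ? 3 : 2;
        continue;
      }
      unsigned char t = tM[idx];
      aa.push_back(a[i - 1]); ba.push_back(b[j - 1]);
      --i; --j;
      state = (t == 1) ? 1 : (t == 2 ? 2 : 3);
    } else if (state == 2) {  // X: a[i] vs gap
      aa.push_back(a[i - 1]); ba.push_back('-');
      unsigned char t = tX[idx];
      --i;
      state = (t == 1) ? 1 : 2;
    } else {  // Y: gap vs b[j]
      aa.push_back('-'); ba.push_back(b[j - 1]);
      unsigned char t = tY[idx];
      --j;
      state = (t == 1) ? 1 : 3;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ba.begin(), ba.end());

  int a_start = i + 1, b_start = j + 1;
  int n_ident = 0, n_cols = 0;
  for (size_t k = 0; k < aa.size(); ++k) {
    if (aa[k] != '-' && ba[k] != '-') {
      ++n_cols;
      if (aa[k] == ba[k]) ++n_ident;
    }
  }
  return List::create(
      _["score"] = best, _["a_start"] = a_start, _["a_end"] = bi_best,
      _["b_start"] = b_start, _["b_end"] = bj_best, _["a_aln"] = aa,
      _["b_aln"] = ba, _["n_ident"] = n_ident, _["n_cols"] = n_cols,
      _["aln_len"] = (int)aa.size());
}

// Seed positions of many queries against one subject: the subject k-mer
// index is built once and every query is streamed against it.  Returns,
// per query, the 0-based (query_pos, subject_pos) seed pairs.

// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector queries, std::string subject, int k) {
  std::unordered_map<std::string, std::vector<int>> idx;
  for (int j = 0; j + k <= (int)subject.size(); ++j) {
    std::string w = subject.substr(j, k);
    if (w.find('.') == std::string::npos) idx[w].push_back(j);
  }
  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::vector<int> qp, sp;
    for (int i = 0; i + k <= (int)q.size(); ++i) {
      auto it = idx.find(q.substr(i, k));
      if (it != idx.end()) {
        for (int j : it->second) { qp.push_back(i); sp.push_back(j); }
      }
    }
    out[qi] = List::create(_["q"] = wrap(qp), _["s"] = wrap(sp));
  }
  return out;
}

// Batched seed search: one k-mer index over all database subjects, every
// query streamed against it.  Returns, per query, parallel vectors of
// (subject index (1-based), query pos, subject pos), 0-based positions.

// [[Rcpp::export]]
List cpp_seed_hits_db(CharacterVector queries, CharacterVector subjects,
                      int k) {
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  for (int si = 0; si < subjects.size(); ++si) {
    std::string s = as<std::string>(subjects[si]);
    for (int j = 0; j + k <= (int)s.size(); ++j)
      idx[s.substr(j, k)].emplace_back(si + 1, j);
  }
  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::vector<int> sv, qp, sp;
    for (int i = 0; i + k <= (int)q.size(); ++i) {
      auto it = idx.find(q.substr(i, k));
      if (it != idx.end()) {
        for (auto &pr : it->second) {
          sv.push_back(pr.first); qp.push_back(i); sp.push_back(pr.second);
        }
      }
    }
    out[qi] = List::create(_["si"] = wrap(sv), _["q"] = wrap(qp),
                           _["s"] = wrap(sp));
  }
  return out;
}

// Positions (0-based) of all shared k-mers between a query and a subject,
// reported as (query_pos, subject_pos) pairs: the seeding step of the
// search engine.  Exact words only.

// [[Rcpp::export]]
List cpp_shared_kmers(std::string q, std::string s, int k) {
  std::vector<int> qp, sp;
  if ((int)q.size() >= k && (int)s.size() >= k) {
    std::unordered_multimap<std::string, int> idx;
    for (int j = 0; j + k <= (int)s.size(); ++j)
      idx.emplace(s.substr(j, k), j);
    for (int i = 0; i + k <= (int)q.size(); ++i) {
      auto r = idx.equal_range(q.substr(i, k));
      for (auto it = r.first; it != r.second; ++it) {
        qp.push_back(i); sp.push_back(it->second);
      }
    }
  }
  return List::create(_["q"] = wrap(qp), _["s"] = wrap(sp));
}
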