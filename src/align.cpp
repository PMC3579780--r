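#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap dynamic-programming aligners.
//
// Gap convention: a gap run of length L scores gap_open + L * gap_extend
// (both <= 0), i.e. the first gap column pays gap_open + gap_extend.
// Tie-breaking during traceback is fixed: diagonal (match state) first,
// then gap-in-b (consume a), then gap-in-a (consume b).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State : unsigned char { SM = 0, SX = 1, SY = 2, SZERO = 3 };

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch; // N never matches
  return (x == y) ? match : mismatch;
}

// Pick max with fixed preference order M > X > Y (strict improvement to switch).
static inline State argmax3(double m, double x, double y, double &best) {
  State s = SM; best = m;
  if (x > best) { best = x; s = SX; }
  if (y > best) { best = y; s = SY; }
  return s;
}

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double go = gap_open, ge = gap_ext;

  // rolling score rows; full byte traceback
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1),
                      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1)),
                             tbX((size_t)(n + 1) * (m + 1)),
                             tbY((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t)m + 1;

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = go + ge * j;
    tbY[(size_t)0 * W + j] = SY;
  }
  tbY[0] = SM;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = go + ge * i;
    tbX[(size_t)i * W + 0] = (i == 1) ? SM : SX;
    for (int j = 1; j <= m; ++j) {
      const double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double best;
      State st = argmax3(Mp[j - 1], Xp[j - 1], Yp[j - 1], best);
      Mc[j] = best + s;
      tbM[(size_t)i * W + j] = st;

      st = argmax3(Mp[j] + go + ge, Xp[j] + ge, Yp[j] + go + ge, best);
      Xc[j] = best;
      tbX[(size_t)i * W + j] = st;

      st = argmax3(Mc[j - 1] + go + ge, Xc[j - 1] + go + ge, Yc[j - 1] + ge, best);
      Yc[j] = best;
      tbY[(size_t)i * W + j] = st;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score;
  State st = argmax3(Mp[m], Xp[m], Yp[m], score);

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == SM) {
      State prev = (State)tbM[(size_t)i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == SX) {
      State prev = (State)tbX[(size_t)i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = prev;
    } else {
      State prev = (State)tbY[(size_t)i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = score);
}

// [[Rcpp::export(name = ".align_local_cpp")]]
List align_local_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double go = gap_open, ge = gap_ext;

  // boundary match-state cells are -inf: a local alignment can only start
  // at the zero floor inside the match recursion, never with a gap
  std::vector<double> Mp(m + 1, NEG_INF), Xp(m + 1, NEG_INF), Yp(m + 1, NEG_INF),
                      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), SZERO),
                             tbX((size_t)(n + 1) * (m + 1), SM),
                             tbY((size_t)(n + 1) * (m + 1), SM);
  const size_t W = (size_t)m + 1;

  double best_score = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      const double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double best;
      State st = argmax3(Mp[j - 1], Xp[j - 1], Yp[j - 1], best);
      if (best < 0.0) { best = 0.0; st = SZERO; }
      Mc[j] = best + s;
      tbM[(size_t)i * W + j] = st;

      st = argmax3(Mp[j] + go + ge, Xp[j] + ge, Yp[j] + go + ge, best);
      Xc[j] = best;
      tbX[(size_t)i * W + j] = st;

      st = argmax3(Mc[j - 1] + go + ge, Xc[j - 1] + go + ge, Yc[j - 1] + ge, best);
      Yc[j] = best;
      tbY[(size_t)i * W + j] = st;

      if (Mc[j] > best_score) { best_score = Mc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  if (best_score <= 0.0) {
    return List::create(_["row_a"] = "", _["row_b"] = "", _["score"] = 0.0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  }

  std::string ra, rb;
  int i = bi, j = bj;
  State st = SM;
  while (true) {
    if (st == SM) {
      State prev = (State)tbM[(size_t)i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (prev == SZERO) break;
      st = prev;
    } else if (st == SX) {
      State prev = (State)tbX[(size_t)i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = prev;
    } else {
      State prev = (State)tbY[(size_t)i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = best_score,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}

// Profile-profile global alignment for progressive MSA.
// Profiles are 6 x L frequency matrices, rows A,C,G,T,N,'-' summing to 1 per
// column. Column-column score = expected substitution score over residue
// pairs; pairs involving an existing gap contribute 0. Returns the merge path
// as moves: 0 = column from both, 1 = column from a only (gap inserted in b),
// 2 = column from b only.

// [[Rcpp::export(name = ".align_profile_cpp")]]
List align_profile_cpp(NumericMatrix pa, NumericMatrix pb,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int n = pa.ncol(), m = pb.ncol();
  const double go = gap_open, ge = gap_ext;

  // precompute column-column scores
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int x = 0; x < 5; ++x) {
        if (pa(x, i) == 0.0) continue;
        for (int y = 0; y < 5; ++y) {
          if (pb(y, j) == 0.0) continue;
          const double sc = (x == y && x < 4) ? match : mismatch;
          s += pa(x, i) * pb(y, j) * sc;
        }
      }
      S(i, j) = s;
    }

  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1),
                      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1)),
                             tbX((size_t)(n + 1) * (m + 1)),
                             tbY((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t)m + 1;

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF; Yp[j] = go + ge * j;
    tbY[(size_t)0 * W + j] = SY;
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Yc[0] = NEG_INF; Xc[0] = go + ge * i;
    tbX[(size_t)i * W + 0] = (i == 1) ? SM : SX;
    for (int j = 1; j <= m; ++j) {
      double best;
      State st = argmax3(Mp[j - 1], Xp[j - 1], Yp[j - 1], best);
      Mc[j] = best + S(i - 1, j - 1);
      tbM[(size_t)i * W + j] = st;
      st = argmax3(Mp[j] + go + ge, Xp[j] + ge, Yp[j] + go + ge, best);
      Xc[j] = best;
      tbX[(size_t)i * W + j] = st;
      st = argmax3(Mc[j - 1] + go + ge, Xc[j - 1] + go + ge, Yc[j - 1] + ge, best);
      Yc[j] = best;
      tbY[(size_t)i * W + j] = st;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score;
  State st = argmax3(Mp[m], Xp[m], Yp[m], score);

  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == SM) {
      State prev = (State)tbM[(size_t)i * W + j];
      moves.push_back(0); --i; --j; st = prev;
    } else if (st == SX) {
      State prev = (State)tbX[(size_t)i * W + j];
      moves.push_back(1); --i; st = prev;
    } else {
      State prev = (State)tbY[(size_t)i * W + j];
      moves.push_back(2); --j; st = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["moves"] = IntegerVector(moves.begin(), moves.end()),
                      _["score"] = score);
}
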