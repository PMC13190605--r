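#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Gotoh affine-gap global alignment with optionally free terminal gaps
// (EMBOSS-needle-like). Gap of length L costs open + L * ext.
//
// States: M (residue pair), X (gap in `a`, consumes b), Y (gap in `b`,
// consumes a). Tie-break contract, in every max: M beats X beats Y; the
// traceback endpoint prefers (n, m), then the last column bottom-up, then
// the last row right-to-left, replacing only on strictly better score.
//
// Traceback is packed 2 bits per state into one byte per cell:
// bits 0-1 = predecessor of M, 2-3 = of X, 4-5 = of Y (0=M, 1=X, 2=Y,
// 3 = boundary).

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b,
                     NumericMatrix submat, CharacterVector mat_letters,
                     double gap_open, double gap_ext, bool free_ends) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < mat_letters.size(); ++i) {
    std::string s = as<std::string>(mat_letters[i]);
    lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> ia(n), ib(m);
  for (int i = 0; i < n; ++i) {
    ia[i] = lut[(unsigned char)a[i]];
    if (ia[i] < 0)
      stop("residue '%s' absent from substitution matrix",
           std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    ib[j] = lut[(unsigned char)b[j]];
    if (ib[j] < 0)
      stop("residue '%s' absent from substitution matrix",
           std::string(1, b[j]).c_str());
  }

  const double open_cost = gap_open + gap_ext;  // first gap position
  const int nL = mat_letters.size();
  // dense row-major copy of the matrix for cache-friendly lookups
  std::vector<double> sub((size_t)nL * nL);
  for (int r = 0; r < nL; ++r)
    for (int c = 0; c < nL; ++c)
      sub[(size_t)r * nL + c] = submat(r, c);

  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0x3F);
  std::vector<double> lastColM(n + 1), lastColX(n + 1), lastColY(n + 1);

  // row 0
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF;
    Yprev[j] = NEG_INF;
    Xprev[j] = free_ends ? 0.0 : -(gap_open + gap_ext * j);
    tb[j] = (unsigned char)(((j == 1 ? 3 : 1) << 2) | 0x33);
  }
  lastColM[0] = Mprev[m]; lastColX[0] = Xprev[m]; lastColY[0] = Yprev[m];

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF; Xcur[0] = NEG_INF;
    Ycur[0] = free_ends ? 0.0 : -(gap_open + gap_ext * i);
    unsigned char* tbrow = &tb[(size_t)i * (m + 1)];
    tbrow[0] = (unsigned char)(((i == 1 ? 3 : 2) << 4) | 0x0F);
    const double* srow = &sub[(size_t)ia[i - 1] * nL];
    double x_left = Xcur[0], m_left = Mcur[0], y_left = Ycur[0];
    for (int j = 1; j <= m; ++j) {
      const double md = Mprev[j - 1], xd = Xprev[j - 1], yd = Yprev[j - 1];
      const double mu = Mprev[j], xu = Xprev[j], yu = Yprev[j];
      // M from diagonal
      double bm = md; unsigned char wm = 0;
      if (xd > bm) { bm = xd; wm = 1; }
      if (yd > bm) { bm = yd; wm = 2; }
      bm += srow[ib[j - 1]];
      // X from left
      double bx = m_left - open_cost; unsigned char wx = 0;
      if (x_left - gap_ext > bx) { bx = x_left - gap_ext; wx = 1; }
      if (y_left - open_cost > bx) { bx = y_left - open_cost; wx = 2; }
      // Y from above
      double by = mu - open_cost; unsigned char wy = 0;
      if (xu - open_cost > by) { by = xu - open_cost; wy = 1; }
      if (yu - gap_ext > by) { by = yu - gap_ext; wy = 2; }
      Mcur[j] = bm; Xcur[j] = bx; Ycur[j] = by;
      m_left = bm; x_left = bx; y_left = by;
      tbrow[j] = (unsigned char)(wm | (wx << 2) | (wy << 4));
    }
    lastColM[i] = Mcur[m]; lastColX[i] = Xcur[m]; lastColY[i] = Ycur[m];
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  std::vector<double>&lastRowM = Mprev, &lastRowX = Xprev, &lastRowY = Yprev;

  // endpoint selection
  int ei = n, ej = m; unsigned char estate = 0; double escore;
  {
    escore = lastRowM[m]; estate = 0;
    if (lastRowX[m] > escore) { escore = lastRowX[m]; estate = 1; }
    if (lastRowY[m] > escore) { escore = lastRowY[m]; estate = 2; }
  }
  if (free_ends) {
    for (int i = n - 1; i >= 0; --i) {  // last column, bottom-up
      double cand[3] = { lastColM[i], lastColX[i], lastColY[i] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > escore) { escore = cand[s]; ei = i; ej = m; estate = (unsigned char)s; }
    }
    for (int j = m - 1; j >= 0; --j) {  // last row, right-to-left
      double cand[3] = { lastRowM[j], lastRowX[j], lastRowY[j] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > escore) { escore = cand[s]; ei = n; ej = j; estate = (unsigned char)s; }
    }
  }

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej; unsigned char st = estate;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; ra.push_back('-'); rb.push_back(b[j]); continue; }
    if (j == 0) { --i; ra.push_back(a[i]); rb.push_back('-'); continue; }
    unsigned char cell = tb[(size_t)i * (m + 1) + j];
    if (st == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      st = cell & 3; --i; --j;
    } else if (st == 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      st = (cell >> 2) & 3; --j;
      if (st == 3) st = 1;  // boundary run continues as X
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      st = (cell >> 4) & 3; --i;
      if (st == 3) st = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // column stats
  int align_len = ra.size(), n_id = 0, n_sim = 0;
  for (int k = 0; k < align_len; ++k) {
    char ca = ra[k], cb = rb[k];
    if (ca == '-' || cb == '-') continue;
    if (ca == cb) ++n_id;
    if (sub[(size_t)lut[(unsigned char)ca] * nL + lut[(unsigned char)cb]] > 0)
      ++n_sim;
  }

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = escore, _["align_len"] = align_len,
                      _["n_identical"] = n_id, _["n_similar"] = n_sim);
}
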