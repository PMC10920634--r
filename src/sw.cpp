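#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment, affine gaps, with origin tracking.
// Gap of length L costs gap_open + (L-1) * gap_extend. 'N' never matches.
// Returns the optimal local score and the reference start/end coordinates
// (1-based, inclusive) of every cell attaining it.
// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string query, std::string ref,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = -2.0, double gap_extend = -1.0) {
  const int n = (int)query.size();
  const int m = (int)ref.size();
  if (n == 0) stop("empty query");
  if (m == 0) stop("empty reference");

  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fcol(m + 1, NEG);           // vertical gap state per column
  std::vector<int> bHprev(m + 1, 0), bHcur(m + 1, 0), bFcol(m + 1, 0);

  double best = 0.0;
  std::vector<int> starts, ends;

  for (int i = 1; i <= n; ++i) {
    double E = NEG;          // horizontal gap state, current row
    int bE = 0;
    Hcur[0] = 0.0; bHcur[0] = 0;
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char rc = ref[j - 1];
      const double s = (qc == rc && qc != 'N' && rc != 'N') ? match : mismatch;

      // E: gap in query consuming ref (from the left)
      double e_open = Hcur[j - 1] + gap_open;
      double e_ext  = E + gap_extend;
      if (e_open >= e_ext) { E = e_open; bE = (Hcur[j - 1] > 0.0) ? bHcur[j - 1] : j - 1; }
      else                 { E = e_ext; }

      // F: gap in ref consuming query (from above)
      double f_open = Hprev[j] + gap_open;
      double f_ext  = Fcol[j] + gap_extend;
      if (f_open >= f_ext) { Fcol[j] = f_open; bFcol[j] = (Hprev[j] > 0.0) ? bHprev[j] : j; }
      else                 { Fcol[j] = f_ext; }

      double diag = Hprev[j - 1] + s;
      int bdiag = (Hprev[j - 1] > 0.0) ? bHprev[j - 1] : j - 1;

      double h = 0.0; int bh = j;
      if (diag > h)    { h = diag;    bh = bdiag; }
      if (E > h)       { h = E;       bh = bE; }
      if (Fcol[j] > h) { h = Fcol[j]; bh = bFcol[j]; }
      Hcur[j] = h; bHcur[j] = bh;

      if (h > 0.0) {
        if (h > best + 1e-9) {
          best = h; starts.clear(); ends.clear();
          starts.push_back(bh + 1); ends.push_back(j);
        } else if (h > best - 1e-9) {
          starts.push_back(bh + 1); ends.push_back(j);
        }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(bHprev, bHcur);
  }

  return List::create(_["score"] = best,
                      _["starts"] = wrap(starts),
                      _["ends"] = wrap(ends));
}
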