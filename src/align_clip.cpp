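#include <Rcpp.h>
using namespace Rcpp;

// Ungapped alignment of a clipped segment against a construct sequence.
//
// Search space: every placement of the query on both strands of the
// construct.  An end-to-end placement aligns the whole query (terminal
// mismatches allowed, total mismatches <= m).  A local placement is a
// contiguous query sub-segment whose alignment starts and ends on a match
// and contains <= m mismatches.  Best hit: end-to-end preferred, then
// maximal matched length, then fewer mismatches, then smaller construct
// start, then + strand.

namespace {

struct Hit {
  bool found = false;
  bool end2end = false;
  int t_start = 0;      // 1-based on construct
  int t_end = 0;
  int matched_len = 0;
  int mismatches = 0;
  int strand = 0;       // 0 = '+', 1 = '-'
  int q_start = 0;      // 1-based on query as supplied (forward clip)
  int q_end = 0;
};

bool better(const Hit& a, const Hit& b) {
  // true when a beats b
  if (!b.found) return a.found;
  if (!a.found) return false;
  if (a.end2end != b.end2end) return a.end2end;
  if (a.matched_len != b.matched_len) return a.matched_len > b.matched_len;
  if (a.mismatches != b.mismatches) return a.mismatches < b.mismatches;
  if (a.t_start != b.t_start) return a.t_start < b.t_start;
  return a.strand < b.strand;
}

char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Scan one query orientation against the construct.  qs is the query as
// placed on the construct forward strand; strand tags the hit; on the '-'
// strand qs is the reverse complement of the clip, so query coordinates
// must be flipped back when reporting q_start/q_end.
void scan(const std::string& qs, const std::string& T, int m, int min_len,
          int strand, Hit& best) {
  const int n = (int)qs.size(), L = (int)T.size();
  // end-to-end placements
  if (n <= L && n >= min_len) {
    for (int off = 0; off + n <= L; ++off) {
      int mm = 0;
      for (int k = 0; k < n && mm <= m; ++k)
        if (qs[k] != T[off + k]) ++mm;
      if (mm <= m) {
        Hit h;
        h.found = true; h.end2end = true;
        h.t_start = off + 1; h.t_end = off + n;
        h.matched_len = n; h.mismatches = mm; h.strand = strand;
        h.q_start = 1; h.q_end = n;
        if (better(h, best)) best = h;
      }
    }
  }
  // local placements: one pass per diagonal
  std::vector<int> mmpos;
  for (int diag = -(n - 1); diag < L; ++diag) {
    // columns where query position q (0-based) meets construct position
    // q + diag; overlap is q in [q_lo, q_hi]
    int q_lo = std::max(0, -diag);
    int q_hi = std::min(n - 1, L - 1 - diag);
    int W = q_hi - q_lo + 1;
    if (W < min_len) continue;
    mmpos.clear();
    mmpos.push_back(q_lo - 1);                 // left sentinel
    for (int q = q_lo; q <= q_hi; ++q)
      if (qs[q] != T[q + diag]) mmpos.push_back(q);
    mmpos.push_back(q_hi + 1);                 // right sentinel
    const int M = (int)mmpos.size() - 2;       // mismatch count on diagonal
    for (int a = 0; a <= M; ++a)
    for (int b = a + 1; b <= std::min(a + m + 1, M + 1); ++b) {
      int ws = mmpos[a] + 1, we = mmpos[b] - 1;
      int len = we - ws + 1;
      if (len < min_len) continue;
      // endpoints must be matches: with adjacent mismatches the window edge
      // can land on an included mismatch; those windows are represented by a
      // narrower (a, b) pair instead
      if (b > a + 1 && (mmpos[a + 1] == ws || mmpos[b - 1] == we)) continue;
      Hit h;
      h.found = true; h.end2end = false;
      h.matched_len = len; h.mismatches = b - a - 1; h.strand = strand;
      h.t_start = ws + diag + 1; h.t_end = we + diag + 1;
      h.q_start = ws + 1; h.q_end = we + 1;
      if (strand == 1) {                       // flip back to clip coords
        int qs1 = n - h.q_end + 1, qe1 = n - h.q_start + 1;
        h.q_start = qs1; h.q_end = qe1;
      }
      if (better(h, best)) best = h;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".align_clip_cpp")]]
List align_clip_cpp(std::string clip, std::string construct, int m, int min_len) {
  Hit best;
  scan(clip, construct, m, min_len, 0, best);
  std::string rc(clip.rbegin(), clip.rend());
  for (auto& c : rc) c = comp(c);
  scan(rc, construct, m, min_len, 1, best);
  if (!best.found) return List::create(Named("found") = false);
  return List::create(
    Named("found") = true,
    Named("t_start") = best.t_start,
    Named("t_end") = best.t_end,
    Named("t_strand") = best.strand == 0 ? "+" : "-",
    Named("mode") = best.end2end ? "end2end" : "local",
    Named("matched_len") = best.matched_len,
    Named("mismatches") = best.mismatches,
    Named("q_start") = best.q_start,
    Named("q_end") = best.q_end);
}
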