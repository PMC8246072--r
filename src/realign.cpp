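#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Glocal (read-global, context-local) affine-gap alignment in log10
// probability units. A gap of length k costs gap_open + k * gap_extend
// (both supplied as positive costs). The whole read must align; the
// context is free at both ends. Returns score and the 0-based [start, end)
// context interval of the best alignment.
//
// Rolling two-row DP with start-column propagation so the aligned context
// interval is recovered without a traceback.

static const double NEG = -std::numeric_limits<double>::infinity();

struct AlnResult {
  double score;
  int start;
  int end;
};

static AlnResult glocal_align(const std::string& read,
                              const std::string& ctx,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  const int m = read.size(), n = ctx.size();
  AlnResult res = {NEG, -1, -1};
  if (m == 0 || n == 0) return res;

  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);
  std::vector<double> Mp(n + 1), Xp(n + 1), Yp(n + 1);
  std::vector<int> sMc(n + 1), sXc(n + 1), sYc(n + 1);
  std::vector<int> sMp(n + 1), sXp(n + 1), sYp(n + 1);

  // i = 0: no read consumed; alignment may start at any context column.
  for (int j = 0; j <= n; ++j) {
    Mp[j] = 0.0;      sMp[j] = j;   // free start at column j
    Xp[j] = NEG;      sXp[j] = j;
    Yp[j] = NEG;      sYp[j] = j;   // leading read-gap is never optimal here
  }

  for (int i = 1; i <= m; ++i) {
    // j = 0: read consumed without context -> gap in context (X state).
    Mc[0] = NEG; sMc[0] = 0;
    Yc[0] = NEG; sYc[0] = 0;
    double fromM = Mp[0] - (gap_open + gap_extend);
    double fromX = Xp[0] - gap_extend;
    if (fromM >= fromX) { Xc[0] = fromM; sXc[0] = sMp[0]; }
    else                { Xc[0] = fromX; sXc[0] = sXp[0]; }

    for (int j = 1; j <= n; ++j) {
      char rb = read[i - 1], cb = ctx[j - 1];
      double sub = (rb == cb && rb != 'N') ? match : mismatch;
      // M: diagonal from any state
      double bm = Mp[j - 1], bx = Xp[j - 1], by = Yp[j - 1];
      double best = bm; int s = sMp[j - 1];
      if (bx > best) { best = bx; s = sXp[j - 1]; }
      if (by > best) { best = by; s = sYp[j - 1]; }
      Mc[j] = best + sub; sMc[j] = s;
      // X: read base against gap (vertical)
      double xm = Mp[j] - (gap_open + gap_extend);
      double xx = Xp[j] - gap_extend;
      if (xm >= xx) { Xc[j] = xm; sXc[j] = sMp[j]; }
      else          { Xc[j] = xx; sXc[j] = sXp[j]; }
      // Y: context base against gap (horizontal)
      double ym = Mc[j - 1] - (gap_open + gap_extend);
      double yy = Yc[j - 1] - gap_extend;
      if (ym >= yy) { Yc[j] = ym; sYc[j] = sMc[j - 1]; }
      else          { Yc[j] = yy; sYc[j] = sYc[j - 1]; }
    }
    std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
    std::swap(sMc, sMp); std::swap(sXc, sXp); std::swap(sYc, sYp);
  }

  // Best end: read fully consumed (row m), any context column; the
  // alignment should end in M or X (a trailing context gap is free anyway
  // because the context is local at both ends).
  for (int j = 0; j <= n; ++j) {
    if (Mp[j] > res.score) { res.score = Mp[j]; res.start = sMp[j]; res.end = j; }
    if (Xp[j] > res.score) { res.score = Xp[j]; res.start = sXp[j]; res.end = j; }
  }
  return res;
}

// Ungapped score of the read placed at context offset `at`.
static double hamming_score(const std::string& read, const std::string& ctx,
                            long at, double match, double mismatch) {
  double s = 0.0;
  for (size_t k = 0; k < read.size(); ++k) {
    char rb = read[k], cb = ctx[at + k];
    s += (rb == cb && rb != 'N') ? match : mismatch;
  }
  return s;
}

// [[Rcpp::export]]
NumericMatrix score_reads_cpp(CharacterVector reads, std::string context,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  int n = reads.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("score", "start", "end");
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const long m = rd.size(), L = context.size();
    size_t hit = context.find(rd);
    if (hit != std::string::npos) {
      // exact substring: best possible alignment, all matches
      out(i, 0) = match * m;
      out(i, 1) = (double)hit;
      out(i, 2) = (double)(hit + m);
      continue;
    }
    // Anchored fast path: if a half of the read matches the context
    // exactly, the ungapped placement it implies is the DP optimum
    // whenever its score beats the cheapest gapped alignment
    // (-gap_open - gap_extend), because any alignment with a gap costs at
    // least that much. Only substitution differences can then occur.
    double best_anch = NEG; long best_at = -1;
    if (m >= 2) {
      long half = m / 2;
      std::string lh = rd.substr(0, half);
      std::string rh = rd.substr(m - half, half);
      size_t lq = context.find(lh);
      if (lq != std::string::npos && (long)lq + m <= L) {
        double s = hamming_score(rd, context, (long)lq, match, mismatch);
        if (s > best_anch) { best_anch = s; best_at = (long)lq; }
      }
      size_t rq = context.find(rh);
      if (rq != std::string::npos) {
        long at = (long)rq - (m - half);
        if (at >= 0 && at + m <= L) {
          double s = hamming_score(rd, context, at, match, mismatch);
          if (s > best_anch) { best_anch = s; best_at = at; }
        }
      }
    }
    if (best_at >= 0 && best_anch > -(gap_open + gap_extend)) {
      out(i, 0) = best_anch;
      out(i, 1) = (double)best_at;
      out(i, 2) = (double)(best_at + m);
      continue;
    }
    // No half anchor: try disjoint 16-mer blocks. If one occurs exactly it
    // anchors a windowed DP; if none does, every alignment of the read has
    // at least one error per block (q-gram argument), so the score is
    // bounded above by n_blocks * mismatch — far below any competitive
    // alignment, and returned directly instead of running the DP.
    const long B = 16;
    long n_blocks = m / B;
    if (best_at < 0 && n_blocks >= 2) {
      bool any_hit = false;
      for (long b = 0; b < n_blocks && !any_hit; ++b) {
        size_t q = context.find(rd.substr(b * B, B));
        if (q != std::string::npos) {
          long at = (long)q - b * B;
          if (at >= -m && at <= L) { best_at = std::max(0L, at); any_hit = true; }
        }
      }
      if (!any_hit) {
        out(i, 0) = n_blocks * mismatch;
        out(i, 1) = 0.0;
        out(i, 2) = (double)std::min(m, L);
        continue;
      }
    }
    // With an exact anchor, a gap longer than (|mismatch| * m) /
    // gap_extend can never pay for itself, so the optimal alignment lies
    // within a bounded window around the anchored placement; run the DP
    // there. Without any anchor, fall back to the full context.
    long lo = 0, hi = L;
    if (best_at >= 0) {
      long w = (long)(-mismatch * m / gap_extend) + gap_open + 50;
      lo = std::max(0L, best_at - w);
      hi = std::min(L, best_at + m + w);
    }
    AlnResult r = glocal_align(rd, context.substr(lo, hi - lo), match,
                               mismatch, gap_open, gap_extend);
    if (best_at >= 0 && best_anch > r.score) {
      out(i, 0) = best_anch;
      out(i, 1) = (double)best_at;
      out(i, 2) = (double)(best_at + m);
    } else {
      out(i, 0) = r.score;
      out(i, 1) = (double)(r.start + lo);
      out(i, 2) = (double)(r.end + lo);
    }
  }
  return out;
}
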