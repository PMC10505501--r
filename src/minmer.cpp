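#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <map>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: cheap, well-mixed 64-bit finalizer; deterministic across platforms
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// top 53 bits -> double in [0, 1)
inline double hash_to_unit(uint64_t h) {
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

struct Interval {
  double hash;
  int pos, start, end;
  bool orient;
};

inline bool intervalLess(const Interval &a, const Interval &b) {
  if (a.start != b.start) return a.start < b.start;
  if (a.hash != b.hash) return a.hash < b.hash;
  return a.pos < b.pos;
}

// emit with defensive split into chunks of <= w window starts
inline void emitInterval(std::vector<Interval> &out, double h, int pos, int start,
                         int end, int w, const std::vector<int> *orient) {
  bool ob = orient ? (*orient)[pos] != 0 : true;
  for (int a = start; a < end; a += w) {
    Interval iv;
    iv.hash = h;
    iv.pos = pos;
    iv.start = a;
    iv.end = std::min(a + w, end);
    iv.orient = ob;
    out.push_back(iv);
  }
}

List intervalsToList(std::vector<Interval> &ivs, int prunes) {
  std::sort(ivs.begin(), ivs.end(), intervalLess);
  int m = ivs.size();
  NumericVector h(m);
  IntegerVector pos(m), start(m), end(m);
  LogicalVector orient(m);
  for (int i = 0; i < m; ++i) {
    h[i] = ivs[i].hash;
    pos[i] = ivs[i].pos;
    start[i] = ivs[i].start;
    end[i] = ivs[i].end;
    orient[i] = ivs[i].orient;
  }
  return List::create(_["hash"] = h, _["pos"] = pos, _["start"] = start,
                      _["end"] = end, _["orient"] = orient,
                      _["heapPrunes"] = prunes);
}

}  // namespace

// [[Rcpp::export]]
List cpp_kmer_hashes(std::string seq, int k, int seed, bool canonical) {
  int len = seq.size();
  int n = len - k + 1;
  if (n < 1) {
    return List::create(_["hash"] = NumericVector(0),
                        _["orient"] = LogicalVector(0));
  }
  NumericVector out(n);
  LogicalVector orient(n);
  uint64_t seedmix = splitmix64((uint64_t)(int64_t)seed);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  uint64_t fwd = 0, rc = 0;
  int lastN = -1;  // last position (0-based, in bases) holding an N
  for (int i = 0; i < len; ++i) {
    char c = seq[i];
    int b;
    switch (c) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      case 'N': case 'n': b = -1; lastN = i; break;
      default:
        stop("invalid character '%c' at position %d: sequence must be over A,C,G,T,N",
             c, i + 1);
    }
    if (b >= 0) {
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    } else {
      fwd = 0;
      rc = 0;
    }
    int p = i - k + 1;  // k-mer starting position completed at base i
    if (p < 0) continue;
    if (lastN >= p) {
      out[p] = NA_REAL;
      orient[p] = NA_LOGICAL;
      continue;
    }
    bool isFwd = !canonical || fwd <= rc;
    uint64_t code = canonical ? std::min(fwd, rc) : fwd;
    out[p] = hash_to_unit(splitmix64(code ^ seedmix));
    orient[p] = isFwd;
  }
  return List::create(_["hash"] = out, _["orient"] = orient);
}

// Rolling bottom-s sketch over windows of w k-mers, collecting minmer
// intervals per (hash, position).  M holds the current bottom-s distinct
// hashes (with one open interval per active position), H the remaining
// candidates with lazy deletion and a 2w prune rule.
// [[Rcpp::export]]
List cpp_build_minmer_index(NumericVector hashes, int w, int s,
                            Nullable<LogicalVector> orientIn = R_NilValue) {
  int n = hashes.size();
  std::vector<int> orientVec;
  const std::vector<int> *orientPtr = NULL;
  if (orientIn.isNotNull()) {
    LogicalVector ov(orientIn);
    orientVec.resize(n);
    for (int i = 0; i < n; ++i) orientVec[i] = (ov[i] == TRUE) ? 1 : 0;
    orientPtr = &orientVec;
  }
  std::vector<Interval> out;
  if (n == 0) return intervalsToList(out, 0);
  int weff = std::min(w, n);
  int nwin = (n >= w) ? (n - w + 1) : 1;

  typedef std::pair<double, int> HP;  // (hash, pos)
  std::map<double, std::deque<int> > activePos;    // all in-window positions per hash
  std::map<double, std::deque<int> > M;            // sketch hashes -> open starts
  std::priority_queue<HP, std::vector<HP>, std::greater<HP> > H;
  int prunes = 0;

  // initialize first window
  for (int p = 0; p < weff; ++p) {
    double h = hashes[p];
    if (std::isnan(h)) continue;
    activePos[h].push_back(p);
  }
  {
    int taken = 0;
    for (std::map<double, std::deque<int> >::iterator it = activePos.begin();
         it != activePos.end(); ++it) {
      if (taken < s) {
        M[it->first] = std::deque<int>(it->second.size(), 0);
        ++taken;
      } else {
        for (size_t q = 0; q < it->second.size(); ++q)
          H.push(HP(it->first, it->second[q]));
      }
    }
  }

  for (int i = 1; i < nwin; ++i) {
    // exiting k-mer
    int pe = i - 1;
    double he = hashes[pe];
    if (!std::isnan(he)) {
      std::map<double, std::deque<int> >::iterator ap = activePos.find(he);
      ap->second.pop_front();
      std::map<double, std::deque<int> >::iterator sk = M.find(he);
      if (sk != M.end()) {
        emitInterval(out, he, pe, sk->second.front(), i, w, orientPtr);
        sk->second.pop_front();
        if (ap->second.empty()) {
          activePos.erase(ap);
          M.erase(sk);
        }
      } else if (ap->second.empty()) {
        activePos.erase(ap);
      }
    }
    // entering k-mer
    int pn = i + w - 1;
    double hn = hashes[pn];
    if (!std::isnan(hn)) {
      std::deque<int> &dq = activePos[hn];
      dq.push_back(pn);
      std::map<double, std::deque<int> >::iterator sk = M.find(hn);
      if (sk != M.end()) {
        sk->second.push_back(i);  // duplicate of a sketch member: new open interval
      } else {
        H.push(HP(hn, pn));
        // eviction: the entering hash displaces the current sketch maximum
        if ((int)M.size() == s && hn < M.rbegin()->first) {
          double hmax = M.rbegin()->first;
          std::deque<int> &starts = M.rbegin()->second;
          std::deque<int> &poss = activePos[hmax];
          for (size_t q = 0; q < poss.size(); ++q) {
            emitInterval(out, hmax, poss[q], starts[q], i, w, orientPtr);
            H.push(HP(hmax, poss[q]));
          }
          M.erase(hmax);
        }
      }
    }
    // refill open sketch slots from the heap (lazy deletion)
    while ((int)M.size() < s && !H.empty()) {
      HP top = H.top();
      H.pop();
      if (top.second < i) continue;          // expired
      if (M.count(top.first)) continue;      // stale: already in sketch
      std::deque<int> &poss = activePos[top.first];
      M[top.first] = std::deque<int>(poss.size(), i);
    }
    // prune expired heap entries
    if ((int)H.size() > 2 * w) {
      std::priority_queue<HP, std::vector<HP>, std::greater<HP> > H2;
      for (std::map<double, std::deque<int> >::iterator it = activePos.begin();
           it != activePos.end(); ++it) {
        if (M.count(it->first)) continue;
        for (size_t q = 0; q < it->second.size(); ++q)
          H2.push(HP(it->first, it->second[q]));
      }
      H.swap(H2);
      ++prunes;
    }
  }
  // close all open intervals at the last window index + 1
  for (std::map<double, std::deque<int> >::iterator sk = M.begin(); sk != M.end();
       ++sk) {
    std::deque<int> &poss = activePos[sk->first];
    for (size_t q = 0; q < poss.size(); ++q)
      emitInterval(out, sk->first, poss[q], sk->second[q], nwin, w, orientPtr);
  }
  return intervalsToList(out, prunes);
}

// Quadratic oracle: bottom-s distinct of every window by full sort, intervals
// as maximal membership runs per (hash, pos).
// [[Rcpp::export]]
List cpp_brute_force_index(NumericVector hashes, int w, int s,
                           Nullable<LogicalVector> orientIn = R_NilValue) {
  int n = hashes.size();
  std::vector<int> orientVec;
  const std::vector<int> *orientPtr = NULL;
  if (orientIn.isNotNull()) {
    LogicalVector ov(orientIn);
    orientVec.resize(n);
    for (int i = 0; i < n; ++i) orientVec[i] = (ov[i] == TRUE) ? 1 : 0;
    orientPtr = &orientVec;
  }
  std::vector<Interval> out;
  if (n == 0) return intervalsToList(out, 0);
  int weff = std::min(w, n);
  int nwin = (n >= w) ? (n - w + 1) : 1;
  std::vector<int> lastWin(n, -5), runStart(n, -1);
  std::vector<int> idx;
  idx.reserve(weff);
  for (int j = 0; j < nwin; ++j) {
    idx.clear();
    for (int t = 0; t < weff; ++t)
      if (!std::isnan(hashes[j + t])) idx.push_back(j + t);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (hashes[a] != hashes[b]) return hashes[a] < hashes[b];
      return a < b;
    });
    int cnt = 0;
    double last = -1.0;
    for (size_t t = 0; t < idx.size(); ++t) {
      int p = idx[t];
      if (t == 0 || hashes[p] != last) {
        ++cnt;
        last = hashes[p];
      }
      if (cnt > s) break;
      if (lastWin[p] == j - 1) {
        lastWin[p] = j;
      } else {
        if (lastWin[p] >= 0)
          emitInterval(out, hashes[p], p, runStart[p], lastWin[p] + 1, w, orientPtr);
        runStart[p] = j;
        lastWin[p] = j;
      }
    }
  }
  for (int p = 0; p < n; ++p)
    if (lastWin[p] >= 0)
      emitInterval(out, hashes[p], p, runStart[p], lastWin[p] + 1, w, orientPtr);
  return intervalsToList(out, 0);
}

// bottom-s distinct hashes of every window, concatenated (oracle helper)
// [[Rcpp::export]]
List cpp_all_bottom_sketches(NumericVector hashes, int w, int s) {
  int n = hashes.size();
  int weff = std::min(w, n);
  int nwin = (n >= w) ? (n - w + 1) : 1;
  std::vector<double> values;
  IntegerVector lens(nwin);
  std::vector<double> buf;
  buf.reserve(weff);
  for (int j = 0; j < nwin; ++j) {
    buf.clear();
    for (int t = 0; t < weff; ++t)
      if (!std::isnan(hashes[j + t])) buf.push_back(hashes[j + t]);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    int take = std::min((int)buf.size(), s);
    lens[j] = take;
    for (int t = 0; t < take; ++t) values.push_back(buf[t]);
  }
  return List::create(_["values"] = wrap(values), _["lengths"] = lens);
}

// classic w-minimizer positions (leftmost tie-break) via monotonic deque
// [[Rcpp::export]]
IntegerVector cpp_minimizer_positions(NumericVector hashes, int w) {
  int n = hashes.size();
  if (n == 0) return IntegerVector(0);
  int weff = std::min(w, n);
  int nwin = (n >= w) ? (n - w + 1) : 1;
  std::deque<int> dq;  // positions, hashes increasing; front = leftmost minimum
  std::vector<bool> sampled(n, false);
  for (int p = 0; p < n; ++p) {
    double h = std::isnan(hashes[p]) ? 2.0 : hashes[p];
    while (!dq.empty()) {
      double hb = std::isnan(hashes[dq.back()]) ? 2.0 : hashes[dq.back()];
      if (hb > h) dq.pop_back(); else break;  // keep equal: leftmost priority
    }
    dq.push_back(p);
    int j = p - weff + 1;  // window ending at p
    if (dq.front() < j) dq.pop_front();
    if (p >= weff - 1 && j < nwin) {
      if (!std::isnan(hashes[dq.front()])) sampled[dq.front()] = true;
    }
  }
  std::vector<int> out;
  for (int p = 0; p < n; ++p)
    if (sampled[p]) out.push_back(p);
  return wrap(out);
}

// Stage 2: rolling minhash over a candidate region using a static array of
// query-sketch slots.  Interval starts/ends drive O(log s) updates; at each
// window start the numerator over the union bottom-s is read off the slots.
// [[Rcpp::export]]
List cpp_stage2_rolling(NumericVector qs, NumericVector ih, IntegerVector istart,
                        IntegerVector iend, int a, int z, int s) {
  int sq = qs.size();
  int m = ih.size();
  int npos = z - a;
  if (npos < 1) stop("empty candidate region");
  IntegerVector outNum(npos), outDen(npos);
  IntegerVector outPos(npos);
  // sort interval ids by start and by end
  std::vector<int> byStart(m), byEnd(m);
  for (int i = 0; i < m; ++i) byStart[i] = byEnd[i] = i;
  std::sort(byStart.begin(), byStart.end(),
            [&](int x, int y) { return istart[x] < istart[y]; });
  std::sort(byEnd.begin(), byEnd.end(),
            [&](int x, int y) { return iend[x] < iend[y]; });
  std::vector<int> matched(sq, 0);       // active-count of B-hashes equal to slot
  std::vector<int> cnt(sq + 1, 0);       // unmatched B-hashes between slots
  std::map<double, int> act;             // active interval count per hash
  int totalUnmatched = 0, nmatched = 0;
  // B-hash h becomes active / inactive
  auto addHash = [&](double h) {
    int &c = act[h];
    if (c++ > 0) return;
    int lo = std::lower_bound(qs.begin(), qs.end(), h) - qs.begin();
    if (lo < sq && qs[lo] == h) {
      if (matched[lo]++ == 0) ++nmatched;
    } else {
      ++cnt[lo];
      ++totalUnmatched;
    }
  };
  auto rmHash = [&](double h) {
    std::map<double, int>::iterator it = act.find(h);
    if (--(it->second) > 0) return;
    act.erase(it);
    int lo = std::lower_bound(qs.begin(), qs.end(), h) - qs.begin();
    if (lo < sq && qs[lo] == h) {
      if (--matched[lo] == 0) --nmatched;
    } else {
      --cnt[lo];
      --totalUnmatched;
    }
  };
  size_t ps = 0, pe = 0;
  // activate intervals covering the first window start a
  // (ends <= a are dropped by advancing pe without activation bookkeeping)
  std::vector<bool> active(m, false);
  while (ps < byStart.size() && istart[byStart[ps]] <= a) {
    int id = byStart[ps++];
    if (iend[id] > a) {
      addHash(ih[id]);
      active[id] = true;
    }
  }
  for (int j = a; j < z; ++j) {
    if (j > a) {
      while (pe < byEnd.size() && iend[byEnd[pe]] <= j) {
        int id = byEnd[pe++];
        if (active[id]) {
          rmHash(ih[id]);
          active[id] = false;
        }
      }
      while (ps < byStart.size() && istart[byStart[ps]] <= j) {
        int id = byStart[ps++];
        if (iend[id] > j) {
          addHash(ih[id]);
          active[id] = true;
        }
      }
    }
    // walk slots in hash order to find shared members of the union bottom-s
    int u = 0, num = 0;
    for (int t = 0; t < sq; ++t) {
      u += cnt[t];
      if (u >= s) break;
      ++u;  // query hash at slot t enters the union
      if (matched[t] > 0) ++num;
      if (u == s) break;
    }
    int totalUnion = sq + totalUnmatched;
    outPos[j - a] = j;
    outNum[j - a] = num;
    outDen[j - a] = std::min(s, totalUnion);
  }
  return List::create(_["pos"] = outPos, _["numerator"] = outNum,
                      _["denominator"] = outDen);
}

// (w,s)-window guarantee check: every window of w k-mers must contain at
// least min(#distinct, s) sampled positions
// [[Rcpp::export]]
List cpp_check_window_guarantee(NumericVector hashes, LogicalVector sampled,
                                int w, int s) {
  int n = hashes.size();
  int weff = std::min(w, n);
  int nwin = (n >= w) ? (n - w + 1) : 1;
  std::vector<double> buf;
  for (int j = 0; j < nwin; ++j) {
    buf.clear();
    int nsamp = 0;
    for (int t = 0; t < weff; ++t) {
      if (!std::isnan(hashes[j + t])) buf.push_back(hashes[j + t]);
      if (sampled[j + t]) ++nsamp;
    }
    std::sort(buf.begin(), buf.end());
    int ndist = std::unique(buf.begin(), buf.end()) - buf.begin();
    if (nsamp < std::min(ndist, s))
      return List::create(_["ok"] = false, _["window"] = j);
  }
  return List::create(_["ok"] = true, _["window"] = -1);
}

// Exact minmer density by dynamic programming over the rank walk of a k-mer
// across its w subsuming windows (independent Monte-Carlo-free cross-check of
// the closed form).  State: (#smaller exits, #smaller entries) so far; entries
// marginalized sequentially with beta-binomial posterior weights.
// [[Rcpp::export]]
double cpp_minmer_density_dp(int w, int s) {
  if (s >= w) return 1.0;
  double total = (double)s;  // r1 <= s contributes probability 1
  for (int r1 = s + 1; r1 <= w; ++r1) {
    int p = r1 - 1;
    // f[x][y]: survive mass (never rank <= s) after t slides
    std::vector<std::vector<double> > f(p + 1, std::vector<double>(w, 0.0));
    f[0][0] = 1.0;
    for (int t = 1; t <= w - 1; ++t) {
      std::vector<std::vector<double> > g(p + 1, std::vector<double>(w, 0.0));
      int rem = (w - 1) - (t - 1);
      int xmax = std::min(p, t - 1);
      for (int x = 0; x <= xmax; ++x) {
        double peS = (double)(p - x) / rem;
        for (int y = 0; y <= t - 1; ++y) {
          double mass = f[x][y];
          if (mass == 0.0) continue;
          double pnS = (double)(r1 + y) / (w + 1 + (t - 1));
          for (int dx = 0; dx <= 1; ++dx) {
            if (dx && x == p) continue;
            double wx = dx ? peS : 1.0 - peS;
            if (wx == 0.0) continue;
            for (int dy = 0; dy <= 1; ++dy) {
              double wgt = wx * (dy ? pnS : 1.0 - pnS);
              if (wgt == 0.0) continue;
              int rank = r1 - (x + dx) + (y + dy);
              if (rank <= s) continue;  // absorbed: the k-mer is a minmer
              g[x + dx][y + dy] += mass * wgt;
            }
          }
        }
      }
      f.swap(g);
    }
    double survive = 0.0;
    for (int x = 0; x <= p; ++x)
      for (int y = 0; y < w; ++y) survive += f[x][y];
    total += 1.0 - survive;
  }
  return total / w;
}
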