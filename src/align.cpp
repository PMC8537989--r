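// Seed-and-extend local alignment with blastn-style affine-gap scoring,
// plus the tandem telomeric-hexamer scanner. Coordinates are 0-based
// half-open throughout; 'N' never matches any base (including 'N').

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <climits>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int subst(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return x == y ? match : mismatch;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct ExtResult {
  int ai = 0, bj = 0, score = 0;
  std::string ga, gb;
};

// Gapped extension of a vs b forward from their common origin (0,0).
// The running score may fall at most `xdrop` below the best seen before a
// cell is abandoned; the reported extent is the maximal-scoring cell.
// tie_mode: 0 = shortest extension (smaller ai, then bj);
//           1 = longest (larger ai, then larger bj);
//           2 = larger ai, then smaller bj.
static ExtResult xdrop_extend(const std::string& a, const std::string& b,
                              int match, int mismatch,
                              int gap_open, int gap_extend,
                              int xdrop, int tie_mode) {
  const int m = (int)a.size(), n = (int)b.size();
  ExtResult res;
  if (m == 0 && n == 0) return res;

  // per-row traceback: code = hsrc(2 bits) | eopen<<2 | fopen<<3
  std::vector<int> row_lo(m + 1, 0);
  std::vector<std::vector<unsigned char>> tb(m + 1);

  int best = 0, bi = 0, bj = 0;

  std::vector<int> Hprev, Fprev;
  int lo_prev = 0, hi_prev = 0; // inclusive j range of previous row

  // row 0
  {
    std::vector<int> H, F;
    std::vector<unsigned char> codes;
    int j = 0;
    H.push_back(0); F.push_back(NEG); codes.push_back(0);
    int E = NEG;
    for (j = 1; j <= n; ++j) {
      int e_open = H[j - 1] - gap_open - gap_extend;
      int e_ext  = E - gap_extend;
      E = std::max(e_open, e_ext);
      if (E < best - xdrop) break;
      H.push_back(E);
      F.push_back(NEG);
      codes.push_back((unsigned char)(1 | ((e_open >= e_ext) ? 4 : 0)));
    }
    hi_prev = (int)H.size() - 1;
    lo_prev = 0;
    row_lo[0] = 0;
    tb[0] = std::move(codes);
    Hprev = std::move(H);
    Fprev = std::move(F);
  }

  for (int i = 1; i <= m; ++i) {
    std::vector<int> H, F;
    std::vector<unsigned char> codes;
    int lo = lo_prev;
    H.reserve(hi_prev - lo + 4);
    int E = NEG;
    int first_alive = -1, last_alive = -1;
    int j = lo;
    while (j <= n) {
      // fetch previous-row cells
      int Hup = (j >= lo_prev && j <= hi_prev) ? Hprev[j - lo_prev] : NEG;
      int Fup = (j >= lo_prev && j <= hi_prev) ? Fprev[j - lo_prev] : NEG;
      int Hdiag = (j - 1 >= lo_prev && j - 1 <= hi_prev) ? Hprev[j - 1 - lo_prev] : NEG;

      int f_open = (Hup > NEG) ? Hup - gap_open - gap_extend : NEG;
      int f_ext  = (Fup > NEG) ? Fup - gap_extend : NEG;
      int Fv = std::max(f_open, f_ext);

      int e_open = (!H.empty() && H.back() > NEG) ? H.back() - gap_open - gap_extend : NEG;
      int e_ext  = (E > NEG) ? E - gap_extend : NEG;
      int Ev = std::max(e_open, e_ext);

      int diag = NEG;
      if (Hdiag > NEG && j >= 1)
        diag = Hdiag + subst(a[i - 1], b[j - 1], match, mismatch);

      int Hv = std::max(diag, std::max(Ev, Fv));
      int hsrc = (Hv == diag) ? 0 : (Hv == Ev ? 1 : 2);

      bool alive = std::max(Hv, std::max(Ev, Fv)) >= best - xdrop;
      if (!alive) {
        Hv = NEG; Ev = NEG; Fv = NEG;
        if (first_alive < 0) {
          // still searching for the row start: advance lo
          ++j; ++lo;
          continue;
        }
        // beyond the alive region: stop unless E could still revive (it
        // cannot once dead), and only continue to cover hi_prev + 1
        if (j > hi_prev + 1) break;
        H.push_back(NEG); F.push_back(NEG); codes.push_back(0);
        E = NEG;
        ++j;
        continue;
      }
      if (first_alive < 0) first_alive = j;
      last_alive = j;

      H.push_back(Hv); F.push_back(Fv);
      codes.push_back((unsigned char)(hsrc |
                      ((e_open >= e_ext) ? 4 : 0) |
                      ((f_open >= f_ext) ? 8 : 0)));
      E = Ev;

      if (Hv > NEG) {
        bool better = false;
        if (Hv > best) better = true;
        else if (Hv == best) {
          if (tie_mode == 1 && (i > bi || (i == bi && j > bj))) better = true;
          if (tie_mode == 2 && i > bi) better = true;
        }
        if (better) { best = Hv; bi = i; bj = j; }
      }
      ++j;
    }
    if (first_alive < 0) break; // row extinct: extension is over
    row_lo[i] = lo;
    tb[i] = std::move(codes);
    Hprev = std::move(H);
    Fprev = std::move(F);
    lo_prev = lo;
    hi_prev = lo + (int)Hprev.size() - 1;
    if (last_alive >= 0 && last_alive < hi_prev) {
      // trim dead tail
      int keep = last_alive - lo + 1;
      Hprev.resize(keep); Fprev.resize(keep); tb[i].resize(keep);
      hi_prev = last_alive;
    }
  }

  // traceback from (bi, bj)
  std::string ga, gb;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    unsigned char code = tb[i][j - row_lo[i]];
    if (state == 0) {
      int hsrc = code & 3;
      if (hsrc == 0) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        --i; --j;
      } else if (hsrc == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      bool open = (code & 4) != 0;
      --j;
      if (open) state = 0;
    } else {
      ga.push_back(a[i - 1]); gb.push_back('-');
      bool open = (code & 8) != 0;
      --i;
      if (open) state = 0;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  res.ai = bi; res.bj = bj; res.score = best;
  res.ga = ga; res.gb = gb;
  return res;
}

struct Hit {
  int qs, qe, ss, se;   // extension-orientation query coords
  char strand;
  int score, identities, mismatches, gapcols;
  std::string ga, gb;
};

static void aln_stats(const std::string& ga, const std::string& gb,
                      int& id, int& mm, int& gc) {
  id = mm = gc = 0;
  for (size_t k = 0; k < ga.size(); ++k) {
    if (ga[k] == '-' || gb[k] == '-') ++gc;
    else if (ga[k] == gb[k] && ga[k] != 'N') ++id;
    else ++mm;
  }
}

// q given in extension orientation (already reverse-complemented for '-')
static Hit extend_one(const std::string& q, const std::string& s,
                      int q0, int s0, int w,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int xdrop, char strand) {
  std::string qr(q.rbegin() + (q.size() - q0), q.rend());
  std::string sr(s.rbegin() + (s.size() - s0), s.rend());
  ExtResult L = xdrop_extend(qr, sr, match, mismatch, gap_open, gap_extend, xdrop, 0);
  ExtResult R = xdrop_extend(q.substr(q0 + w), s.substr(s0 + w),
                             match, mismatch, gap_open, gap_extend, xdrop, 0);
  Hit h;
  h.qs = q0 - L.ai; h.qe = q0 + w + R.ai;
  h.ss = s0 - L.bj; h.se = s0 + w + R.bj;
  h.strand = strand;
  h.score = L.score + R.score + w * match;
  std::string lga(L.ga.rbegin(), L.ga.rend());
  std::string lgb(L.gb.rbegin(), L.gb.rend());
  h.ga = lga + q.substr(q0, w) + R.ga;
  h.gb = lgb + s.substr(s0, w) + R.gb;
  aln_stats(h.ga, h.gb, h.identities, h.mismatches, h.gapcols);
  return h;
}

static bool encode_word(const std::string& s, int pos, int w, uint64_t& code) {
  code = 0;
  for (int k = 0; k < w; ++k) {
    int v;
    switch (s[pos + k]) {
    case 'A': v = 0; break;
    case 'C': v = 1; break;
    case 'G': v = 2; break;
    case 'T': v = 3; break;
    default: return false; // N or other: no seed
    }
    code = (code << 2) | (uint64_t)v;
  }
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int>> WordMap;

static WordMap index_words(const std::string& s, int w) {
  WordMap m;
  uint64_t code;
  for (int p = 0; p + w <= (int)s.size(); ++p)
    if (encode_word(s, p, w, code)) m[code].push_back(p);
  return m;
}

// [[Rcpp::export]]
DataFrame cpp_find_seeds(std::string query, std::string subject, int word_size) {
  std::vector<int> qpos, spos;
  std::vector<std::string> strand;
  const int w = word_size;
  if (w <= (int)query.size() && w <= (int)subject.size()) {
    WordMap qmap = index_words(query, w);
    std::string qrc = revcomp_str(query);
    WordMap qrcmap = index_words(qrc, w);
    uint64_t code;
    int qlen = (int)query.size();
    for (int j = 0; j + w <= (int)subject.size(); ++j) {
      if (!encode_word(subject, j, w, code)) continue;
      auto it = qmap.find(code);
      if (it != qmap.end())
        for (int p : it->second) { qpos.push_back(p); spos.push_back(j); strand.push_back("+"); }
      auto it2 = qrcmap.find(code);
      if (it2 != qrcmap.end())
        for (int p : it2->second) {
          qpos.push_back(qlen - w - p); spos.push_back(j); strand.push_back("-");
        }
    }
  }
  return DataFrame::create(_["qpos"] = qpos, _["spos"] = spos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_extend_seed(std::string query, std::string subject,
                     int qpos, int spos, std::string strand,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int word_size, int xdrop) {
  bool minus = (strand == "-");
  std::string q = minus ? revcomp_str(query) : query;
  int q0 = minus ? (int)query.size() - word_size - qpos : qpos;
  Hit h = extend_one(q, subject, q0, spos, word_size,
                     match, mismatch, gap_open, gap_extend, xdrop,
                     minus ? '-' : '+');
  int qlen = (int)query.size();
  int oqs = minus ? qlen - h.qe : h.qs;
  int oqe = minus ? qlen - h.qs : h.qe;
  return List::create(
    _["q_start"] = oqs, _["q_end"] = oqe,
    _["s_start"] = h.ss, _["s_end"] = h.se,
    _["strand"] = strand, _["score"] = h.score,
    _["length"] = (int)h.ga.size(),
    _["identities"] = h.identities, _["mismatches"] = h.mismatches,
    _["gap_columns"] = h.gapcols,
    _["aligned_query"] = h.ga, _["aligned_subject"] = h.gb);
}

// [[Rcpp::export]]
DataFrame cpp_search(std::string query, std::string subject,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int word_size, int xdrop, int min_score) {
  const int w = word_size;
  std::vector<Hit> hits;
  if (w <= (int)query.size() && w <= (int)subject.size()) {
    std::string qrc = revcomp_str(query);
    WordMap qmap = index_words(query, w);
    WordMap qrcmap = index_words(qrc, w);
    uint64_t code;
    for (int j = 0; j + w <= (int)subject.size(); ++j) {
      if (!encode_word(subject, j, w, code)) continue;
      for (int pass = 0; pass < 2; ++pass) {
        const WordMap& mp = pass == 0 ? qmap : qrcmap;
        const std::string& q = pass == 0 ? query : qrc;
        char st = pass == 0 ? '+' : '-';
        auto it = mp.find(code);
        if (it == mp.end()) continue;
        for (int p : it->second) {
          bool covered = false;
          for (const Hit& h : hits)
            if (h.strand == st && p >= h.qs && p + w <= h.qe &&
                j >= h.ss && j + w <= h.se) { covered = true; break; }
          if (covered) continue;
          hits.push_back(extend_one(q, subject, p, j, w, match, mismatch,
                                    gap_open, gap_extend, xdrop, st));
        }
      }
    }
  }
  // map '-' hits back to original query coordinates, filter, collapse
  int qlen = (int)query.size();
  std::vector<Hit> kept;
  for (Hit& h : hits) {
    if (h.score < min_score) continue;
    if (h.strand == '-') {
      int qs = qlen - h.qe, qe = qlen - h.qs;
      h.qs = qs; h.qe = qe;
    }
    kept.push_back(h);
  }
  // collapse: same-strand subject overlap (>= 1 bp) keeps best score;
  // ties -> leftmost subject start, then '+' strand
  std::sort(kept.begin(), kept.end(), [](const Hit& x, const Hit& y) {
    if (x.score != y.score) return x.score > y.score;
    if (x.ss != y.ss) return x.ss < y.ss;
    return x.strand == '+' && y.strand == '-';
  });
  std::vector<Hit> final_;
  for (const Hit& h : kept) {
    bool overl = false;
    for (const Hit& g : final_)
      if (g.strand == h.strand && h.ss < g.se && g.ss < h.se) { overl = true; break; }
    if (!overl) final_.push_back(h);
  }
  std::sort(final_.begin(), final_.end(), [](const Hit& x, const Hit& y) {
    if (x.ss != y.ss) return x.ss < y.ss;
    if (x.se != y.se) return x.se < y.se;
    return x.strand == '+' && y.strand == '-';
  });
  int nh = (int)final_.size();
  IntegerVector qs(nh), qe(nh), ss(nh), se(nh), sc(nh), len(nh), id(nh), mm(nh), gc(nh);
  CharacterVector st(nh), ga(nh), gb(nh);
  for (int k = 0; k < nh; ++k) {
    const Hit& h = final_[k];
    qs[k] = h.qs; qe[k] = h.qe; ss[k] = h.ss; se[k] = h.se;
    sc[k] = h.score; len[k] = (int)h.ga.size();
    id[k] = h.identities; mm[k] = h.mismatches; gc[k] = h.gapcols;
    st[k] = std::string(1, h.strand); ga[k] = h.ga; gb[k] = h.gb;
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = st, _["score"] = sc, _["length"] = len,
    _["identities"] = id, _["mismatches"] = mm, _["gap_columns"] = gc,
    _["aligned_query"] = ga, _["aligned_subject"] = gb,
    _["stringsAsFactors"] = false);
}

// Anchored gapped extension from the common origin of a and b (free far
// ends). tie_mode as in xdrop_extend; used for flank anchoring around
// insertion junctions.
// [[Rcpp::export]]
List cpp_anchored_extend(std::string a, std::string b,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int xdrop, int tie_mode) {
  ExtResult r = xdrop_extend(a, b, match, mismatch, gap_open, gap_extend,
                             xdrop, tie_mode);
  int id, mm, gc;
  aln_stats(r.ga, r.gb, id, mm, gc);
  return List::create(_["a_len"] = r.ai, _["b_len"] = r.bj,
                      _["score"] = r.score, _["identities"] = id,
                      _["mismatches"] = mm, _["gap_columns"] = gc,
                      _["aligned_a"] = r.ga, _["aligned_b"] = r.gb);
}

// Maximal tandem runs of TTAGGG ('+') / CCCTAA ('-'); same-strand runs
// separated by <= max_bridge non-motif bases merge into one array, with
// one interruption counted per merge.
// [[Rcpp::export]]
DataFrame cpp_scan_arrays(std::string seq, int max_bridge) {
  struct Arr { int start, end, units, inter; char strand; };
  std::vector<Arr> runs;
  const char* motifs[2] = { "TTAGGG", "CCCTAA" };
  const char strands[2] = { '+', '-' };
  int n = (int)seq.size();
  for (int m = 0; m < 2; ++m) {
    const char* mot = motifs[m];
    int i = 0;
    while (i + 6 <= n) {
      if (seq.compare(i, 6, mot) == 0) {
        int units = 1;
        int j = i + 6;
        while (j + 6 <= n && seq.compare(j, 6, mot) == 0) { ++units; j += 6; }
        runs.push_back({ i, j, units, 0, strands[m] });
        i = j;
      } else ++i;
    }
  }
  std::sort(runs.begin(), runs.end(),
            [](const Arr& x, const Arr& y) { return x.start < y.start; });
  // merge same-strand neighbours within max_bridge; an intervening
  // opposite-strand run blocks the merge (strands never mix)
  std::vector<Arr> merged;
  for (const Arr& r : runs) {
    bool joined = false;
    if (!merged.empty()) {
      Arr& p = merged.back();
      int gap = r.start - p.end;
      if (p.strand == r.strand && gap >= 0 && gap <= max_bridge) {
        p.end = r.end; p.units += r.units; p.inter += 1;
        joined = true;
      }
    }
    if (!joined) merged.push_back(r);
  }
  std::sort(merged.begin(), merged.end(),
            [](const Arr& x, const Arr& y) {
              return x.start < y.start || (x.start == y.start && x.strand == '+');
            });
  int k = (int)merged.size();
  IntegerVector st(k), en(k), un(k), in(k), len(k);
  CharacterVector sd(k);
  for (int i = 0; i < k; ++i) {
    st[i] = merged[i].start; en[i] = merged[i].end;
    un[i] = merged[i].units; in[i] = merged[i].inter;
    len[i] = merged[i].end - merged[i].start;
    sd[i] = std::string(1, merged[i].strand);
  }
  return DataFrame::create(_["start"] = st, _["end"] = en, _["strand"] = sd,
                           _["n_units"] = un, _["interruptions"] = in,
                           _["its_length"] = len,
                           _["stringsAsFactors"] = false);
}
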