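#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Allele codes used throughout: 0=A 1=C 2=G 3=T, 4=deletion pseudo-allele,
// -1 = N/unknown (never present in read codes).

// [[Rcpp::export(name = ".pileup_counts_cpp")]]
IntegerMatrix pileup_counts_cpp(IntegerVector starts, List codes, int target_len) {
  IntegerMatrix counts(5, target_len);
  int *cp = INTEGER(counts);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector cv = codes[i];
    int s = starts[i], len = cv.size();
    if (s < 0 || s + len > target_len)
      stop("read span outside target");
    const int *c = INTEGER(cv);
    for (int j = 0; j < len; ++j) {
      int a = c[j];
      if (a >= 0 && a <= 4) cp[(size_t)(s + j) * 5 + a]++;
    }
  }
  return counts;
}

// Plurality base call per column over base alleles only (deletion votes carry
// no emittable base in a coordinate-preserving consensus).  Tie -> lowest code
// (reference order A<C<G<T); zero base coverage -> -1 (N).
// [[Rcpp::export(name = ".consensus_call_cpp")]]
IntegerVector consensus_call_cpp(IntegerMatrix counts) {
  int L = counts.ncol();
  const int *cp = INTEGER(counts);
  IntegerVector out(L);
  for (int p = 0; p < L; ++p) {
    int best = -1, bestc = 0;
    const int *col = cp + (size_t)p * 5;
    for (int a = 0; a < 4; ++a)
      if (col[a] > bestc) { bestc = col[a]; best = a; }
    out[p] = best;
  }
  return out;
}

// Column-wise majority-vote correction of each read over its overlap-cluster
// members (member lists are 1-based and include the target itself).
// Rules: a column needs >= min_support member votes to be corrected; the
// plurality allele (over A,C,G,T,del) wins; ties keep the target's original
// allele.  An insertion at a junction is present in the corrected read iff a
// strict majority of covering members carries one there; under-supported
// columns keep the target's own insertions.
// [[Rcpp::export(name = ".correct_reads_cpp")]]
List correct_reads_cpp(IntegerVector starts, List codes, List ins_pos,
                       List ins_code, List members, int min_support) {
  int n = starts.size();
  std::vector<IntegerVector> codesv(n), iposv(n), icodev(n);
  for (int i = 0; i < n; ++i) {
    codesv[i] = codes[i];
    iposv[i] = ins_pos[i];
    icodev[i] = ins_code[i];
  }
  List out_codes(n), out_ipos(n), out_icode(n);
  for (int t = 0; t < n; ++t) {
    IntegerVector ct = codesv[t];
    int s = starts[t], len = ct.size(), e = s + len;
    std::vector<int> votes((size_t)5 * len, 0), ncov(len, 0),
        carriers(len, 0), ibase((size_t)4 * len, 0);
    IntegerVector mem = members[t];
    for (int mi = 0; mi < mem.size(); ++mi) {
      int m = mem[mi] - 1;
      IntegerVector cm = codesv[m];
      int sm = starts[m], em = sm + cm.size();
      int lo = std::max(s, sm), hi = std::min(e, em);
      const int *c = INTEGER(cm);
      for (int p = lo; p < hi; ++p) {
        votes[(size_t)c[p - sm] * len + (p - s)]++;
        ncov[p - s]++;
      }
      IntegerVector ip = iposv[m], ic = icodev[m];
      for (int j = 0; j < ip.size(); ++j) {
        int p = ip[j];
        if (p >= lo && p < hi) {
          carriers[p - s]++;
          ibase[(size_t)ic[j] * len + (p - s)]++;
        }
      }
    }
    std::vector<char> own_ins(len, 0);
    std::vector<int> own_ins_code(len, -1);
    IntegerVector ipt = iposv[t], ict = icodev[t];
    for (int j = 0; j < ipt.size(); ++j) {
      int col = ipt[j] - s;
      if (col >= 0 && col < len) { own_ins[col] = 1; own_ins_code[col] = ict[j]; }
    }
    IntegerVector nc(len);
    std::vector<int> newip, newic;
    for (int col = 0; col < len; ++col) {
      int orig = ct[col], nv = ncov[col], nb = orig;
      if (nv >= min_support) {
        int best = -1, bestc = -1;
        bool tie = false;
        for (int a = 0; a < 5; ++a) {
          int c = votes[(size_t)a * len + col];
          if (c > bestc) { bestc = c; best = a; tie = false; }
          else if (c == bestc) tie = true;
        }
        nb = tie ? orig : best;
        if (2 * carriers[col] > nv) {
          int bb = 0, bbc = -1;
          for (int a = 0; a < 4; ++a) {
            int c = ibase[(size_t)a * len + col];
            if (c > bbc) { bbc = c; bb = a; }
          }
          newip.push_back(col + s);
          newic.push_back(bb);
        }
      } else if (own_ins[col]) {
        newip.push_back(col + s);
        newic.push_back(own_ins_code[col]);
      }
      nc[col] = nb;
    }
    out_codes[t] = nc;
    out_ipos[t] = wrap(newip);
    out_icode[t] = wrap(newic);
  }
  return List::create(_["codes"] = out_codes, _["ins_pos"] = out_ipos,
                      _["ins_code"] = out_icode);
}

static inline bool encode_base(char b, uint64_t &code) {
  switch (b) {
    case 'A': case 'a': code = 0; return true;
    case 'C': case 'c': code = 1; return true;
    case 'G': case 'g': code = 2; return true;
    case 'T': case 't': code = 3; return true;
    default: return false;
  }
}

// Gapless seed-and-extend mapping of reads against a set of targets.
// Every k-mer of the read is used as a seed against an exact k-mer index of
// the targets; each candidate end-to-end gapless placement is scored by
// mismatch count and a read is mapped iff mismatches/length <= max_mm_rate.
// Equal-scoring placements are broken by lowest target index, then lowest
// target coordinate; only the winner is reported (primary).
// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(CharacterVector targets, CharacterVector reads,
                          int k, double max_mm_rate, bool random_ties) {
  int nt = targets.size();
  std::vector<std::string> tseq(nt);
  for (int i = 0; i < nt; ++i) tseq[i] = as<std::string>(targets[i]);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  std::unordered_multimap<uint64_t, uint64_t> index;  // kmer -> (target<<40)|pos
  size_t total = 0;
  for (int i = 0; i < nt; ++i) total += tseq[i].size();
  index.reserve(total);
  for (int ti = 0; ti < nt; ++ti) {
    const std::string &s = tseq[ti];
    uint64_t kmer = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      uint64_t b;
      if (encode_base(s[p], b)) {
        kmer = ((kmer << 2) | b) & mask;
        if (++run >= k)
          index.emplace(kmer, ((uint64_t)ti << 40) | (uint64_t)(p + 1 - k));
      } else {
        run = 0;
      }
    }
  }

  int nr = reads.size();
  IntegerVector out_t(nr, NA_INTEGER), out_pos(nr, NA_INTEGER),
      out_mm(nr, NA_INTEGER);
  std::vector<uint64_t> cand;
  for (int ri = 0; ri < nr; ++ri) {
    std::string q = as<std::string>(reads[ri]);
    int len = q.size();
    if (len < k) continue;
    cand.clear();
    uint64_t kmer = 0;
    int run = 0;
    for (int p = 0; p < len; ++p) {
      uint64_t b;
      if (encode_base(q[p], b)) {
        kmer = ((kmer << 2) | b) & mask;
        if (++run >= k) {
          int qoff = p + 1 - k;
          auto range = index.equal_range(kmer);
          for (auto it = range.first; it != range.second; ++it) {
            int ti = (int)(it->second >> 40);
            long tpos = (long)(it->second & ((1ULL << 40) - 1)) - qoff;
            if (tpos >= 0 && tpos + len <= (long)tseq[ti].size())
              cand.push_back(((uint64_t)ti << 40) | (uint64_t)tpos);
          }
        }
      } else {
        run = 0;
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    int best_mm = len + 1;
    int allow = (int)(max_mm_rate * len + 1e-9);
    std::vector<uint64_t> best;  // all equal-best placements, ascending
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int ti = (int)(cand[ci] >> 40);
      int tpos = (int)(cand[ci] & ((1ULL << 40) - 1));
      const std::string &s = tseq[ti];
      int mm = 0, cap = std::min(best_mm, allow);
      for (int j = 0; j < len; ++j) {
        char a = s[tpos + j], b = q[j];
        if (a >= 'a') a -= 32;
        if (b >= 'a') b -= 32;
        if (a != b || a == 'N') { if (++mm > cap) break; }
      }
      if (mm < best_mm) {
        best_mm = mm;
        best.clear();
        best.push_back(cand[ci]);
      } else if (mm == best_mm && mm <= allow) {
        best.push_back(cand[ci]);
      }
    }
    if (!best.empty() && (double)best_mm <= max_mm_rate * len + 1e-9) {
      size_t pick = 0;
      if (random_ties && best.size() > 1)
        pick = (size_t)(unif_rand() * best.size());
      if (pick >= best.size()) pick = best.size() - 1;
      out_t[ri] = (int)(best[pick] >> 40) + 1;
      out_pos[ri] = (int)(best[pick] & ((1ULL << 40) - 1));
      out_mm[ri] = best_mm;
    }
  }
  return DataFrame::create(_["target"] = out_t, _["tstart"] = out_pos,
                           _["n_mismatch"] = out_mm);
}
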