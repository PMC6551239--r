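#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <deque>
#include <vector>
#include <string>
#include <algorithm>
#include <numeric>
#include <cctype>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rcs(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static inline bool validKmer(const char* p, int k) {
  for (int i = 0; i < k; ++i) {
    const char c = p[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

typedef std::unordered_map<std::string, double> KmerMap;

// Canonical k-mer counting: each k-mer occurrence in a read is counted once
// under the lexicographic minimum of the k-mer and its reverse complement.
// Windows containing non-ACGT characters are skipped.
static KmerMap countCanonical(const CharacterVector& reads, int k) {
  KmerMap cnt;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string seq = as<std::string>(reads[r]);
    for (auto& c : seq) c = std::toupper((unsigned char)c);
    if ((int)seq.size() < k) continue;
    for (size_t i = 0; i + (size_t)k <= seq.size(); ++i) {
      if (!validKmer(seq.c_str() + i, k)) continue;
      std::string km = seq.substr(i, k);
      std::string rk = rcs(km);
      cnt[km < rk ? km : rk] += 1.0;
    }
  }
  return cnt;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
  KmerMap cnt = countCanonical(reads, k);
  std::vector<std::string> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  NumericVector n(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    n[i] = cnt[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = n);
}

// Condense the double-stranded de Bruijn graph of the reads into unitigs.
//
// Vertices are canonical k-mers; an oriented k-mer spells either the
// canonical sequence (+) or its reverse complement (-). Maximal
// non-branching chains are collapsed, never across a fold-back step
// x -> revcomp(x) (hairpin) and never around a cycle. Node sequences are
// stored in canonical orientation (lexicographic min of seq and revcomp).
//
// Returns node sequences, per-node summed k-mer counts, and the full
// twin-symmetric oriented edge set (orient: 0 = '+', 1 = '-').
// [[Rcpp::export]]
List cpp_condense(CharacterVector reads, int k) {
  KmerMap cnt = countCanonical(reads, k);

  auto canon = [&](const std::string& x) {
    std::string r = rcs(x);
    return x < r ? x : r;
  };
  auto present = [&](const std::string& x) {
    return cnt.count(canon(x)) > 0;
  };
  static const char* B = "ACGT";
  auto succs = [&](const std::string& x) {
    std::vector<std::string> v;
    std::string y = x.substr(1) + "A";
    for (int b = 0; b < 4; ++b) {
      y[k - 1] = B[b];
      if (present(y)) v.push_back(y);
    }
    return v;
  };
  auto preds = [&](const std::string& x) {
    std::vector<std::string> v;
    std::string y = "A" + x.substr(0, k - 1);
    for (int b = 0; b < 4; ++b) {
      y[0] = B[b];
      if (present(y)) v.push_back(y);
    }
    return v;
  };

  std::vector<std::string> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<std::string> visited;  // canonical k-mers already placed
  std::vector<std::string> nodeSeq;
  std::vector<double> nodeCov;

  for (auto& km : keys) {
    if (visited.count(km)) continue;
    std::deque<std::string> chain;
    chain.push_back(km);
    std::unordered_set<std::string> inChain;
    inChain.insert(km);

    while (true) {  // forward
      const std::string tail = chain.back();
      auto S = succs(tail);
      if (S.size() != 1) break;
      const std::string nx = S[0];
      if (nx == rcs(tail)) break;  // fold-back: never condense into the twin
      const std::string cn = canon(nx);
      if (inChain.count(cn) || visited.count(cn)) break;  // cycle / consumed
      if (preds(nx).size() != 1) break;
      chain.push_back(nx);
      inChain.insert(cn);
    }
    while (true) {  // backward
      const std::string head = chain.front();
      auto P = preds(head);
      if (P.size() != 1) break;
      const std::string pv = P[0];
      if (pv == rcs(head)) break;
      const std::string cn = canon(pv);
      if (inChain.count(cn) || visited.count(cn)) break;
      if (succs(pv).size() != 1) break;
      chain.push_front(pv);
      inChain.insert(cn);
    }

    std::string seq = chain.front();
    double cov = 0;
    for (auto& x : chain) {
      const std::string cn = canon(x);
      cov += cnt[cn];
      visited.insert(cn);
    }
    for (size_t i = 1; i < chain.size(); ++i) seq.push_back(chain[i][k - 1]);
    const std::string rs = rcs(seq);
    nodeSeq.push_back(seq < rs ? seq : rs);
    nodeCov.push_back(cov);
  }

  // deterministic ids: sort nodes by stored sequence
  std::vector<size_t> ord(nodeSeq.size());
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return nodeSeq[a] < nodeSeq[b];
  });

  const int N = (int)ord.size();
  CharacterVector seqOut(N);
  NumericVector covOut(N);
  std::vector<std::string> seqs(N);
  for (int i = 0; i < N; ++i) {
    seqs[i] = nodeSeq[ord[i]];
    seqOut[i] = seqs[i];
    covOut[i] = nodeCov[ord[i]];
  }

  // node-level edges via terminal k-mer overlaps
  std::unordered_map<std::string, std::pair<int, int>> startOf;
  for (int i = 0; i < N; ++i) {
    startOf[seqs[i].substr(0, k)] = {i + 1, 0};
    startOf[rcs(seqs[i]).substr(0, k)] = {i + 1, 1};
  }
  std::vector<int> ef, eo, et, ep;
  for (int i = 0; i < N; ++i) {
    for (int o = 0; o < 2; ++o) {
      const std::string sp = o ? rcs(seqs[i]) : seqs[i];
      std::string y = sp.substr(sp.size() - k + 1) + "A";
      for (int b = 0; b < 4; ++b) {
        y[k - 1] = B[b];
        auto it = startOf.find(y);
        if (it == startOf.end()) continue;
        if (!present(y)) continue;
        ef.push_back(i + 1); eo.push_back(o);
        et.push_back(it->second.first); ep.push_back(it->second.second);
      }
    }
  }
  IntegerMatrix edges(ef.size(), 4);
  for (size_t r = 0; r < ef.size(); ++r) {
    edges(r, 0) = ef[r]; edges(r, 1) = eo[r];
    edges(r, 2) = et[r]; edges(r, 3) = ep[r];
  }
  colnames(edges) = CharacterVector::create("from", "fromOr", "to", "toOr");
  return List::create(_["seq"] = seqOut, _["cov"] = covOut, _["edges"] = edges);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = rcs(as<std::string>(x[i]));
  }
  return out;
}
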