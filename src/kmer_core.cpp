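#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <deque>

using namespace Rcpp;

// 2-bit DNA code: A=0, C=1, G=2, T=3; first base of the k-mer occupies the
// highest-order bit pair. k is odd and <= 31 so a k-mer fits one uint64_t.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char bits2base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

static void check_k(int k) {
  if (k < 3 || k > 31 || (k % 2) == 0)
    stop("k must be an odd integer between 3 and 31, got %d", k);
}

// encode; returns false and sets bad_pos (0-based) on a non-ACGT character
static inline bool encode_code(const char* s, int k, uint64_t& code, int& bad_pos) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { bad_pos = i; return false; }
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline std::string decode_code(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bits2base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector seqs, int k) {
  check_k(k);
  if (k > 26)
    stop("k-mer codes for k > 26 exceed the exact integer range of R numerics; use the string representation");
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", i + 1, (int)strlen(s), k);
    uint64_t code; int bad;
    if (!encode_code(s, k, code, bad))
      stop("sequence %d: non-ACGT character '%c' at position %d", i + 1, s[bad], bad + 1);
    out[i] = (double)code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int k) {
  check_k(k);
  if (k > 26)
    stop("k-mer codes for k > 26 exceed the exact integer range of R numerics; use the string representation");
  int n = codes.size();
  CharacterVector out(n);
  double lim = std::pow(4.0, k);
  for (int i = 0; i < n; ++i) {
    double v = codes[i];
    if (ISNAN(v) || v < 0 || v >= lim || v != std::floor(v))
      stop("code %d is not a valid integer in [0, 4^k)", i + 1);
    out[i] = decode_code((uint64_t)v, k);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_revcomp_code(NumericVector codes, int k) {
  check_k(k);
  if (k > 26)
    stop("k-mer codes for k > 26 exceed the exact integer range of R numerics; use the string representation");
  int n = codes.size();
  NumericVector out(n);
  double lim = std::pow(4.0, k);
  for (int i = 0; i < n; ++i) {
    double v = codes[i];
    if (ISNAN(v) || v < 0 || v >= lim || v != std::floor(v))
      stop("code %d is not a valid integer in [0, 4^k)", i + 1);
    out[i] = (double)revcomp_code((uint64_t)v, k);
  }
  return out;
}

// reverse complement of arbitrary-length DNA strings (ACGTN, case-insensitive)
// [[Rcpp::export]]
CharacterVector cpp_revcomp_seq(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': case 'a': r[j] = 'T'; break;
        case 'C': case 'c': r[j] = 'G'; break;
        case 'G': case 'g': r[j] = 'C'; break;
        case 'T': case 't': r[j] = 'A'; break;
        case 'N': case 'n': r[j] = 'N'; break;
        default:
          stop("sequence %d: cannot reverse-complement character '%c'", i + 1, c);
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seqs, int k) {
  check_k(k);
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", i + 1, (int)strlen(s), k);
    uint64_t code; int bad;
    if (!encode_code(s, k, code, bad))
      stop("sequence %d: non-ACGT character '%c' at position %d", i + 1, s[bad], bad + 1);
    uint64_t rc = revcomp_code(code, k);
    out[i] = decode_code(std::min(code, rc), k);
  }
  return out;
}

// Rolling extraction of canonical k-mers from one sequence. Windows crossing
// a non-ACGT character are skipped; each surviving window costs O(1).
static void roll_kmers(const char* s, size_t len, int k,
                       std::vector<uint64_t>& out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((3ULL - (uint64_t)b) << shift);
    if (++run >= k) out.push_back(std::min(fwd, rev));
  }
}

// [[Rcpp::export]]
CharacterVector cpp_iterate_kmers(std::string seq, int k) {
  check_k(k);
  std::vector<uint64_t> codes;
  roll_kmers(seq.c_str(), seq.size(), k, codes);
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = decode_code(codes[i], k);
  return out;
}

// Count canonical k-mers over a set of reads; rows sorted by ascending code
// (equivalently lexicographic order of the canonical strings).
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  check_k(k);
  std::unordered_map<uint64_t, double> tab;
  std::vector<uint64_t> buf;
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    buf.clear();
    roll_kmers(s, strlen(s), k, buf);
    for (uint64_t c : buf) tab[c] += 1.0;
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int n = keys.size();
  CharacterVector kmer(n);
  NumericVector count(n);
  for (int i = 0; i < n; ++i) {
    kmer[i] = decode_code(keys[i], k);
    count[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// ---- bidirected de Bruijn graph compaction ---------------------------------

struct ONode { uint64_t code; bool fwd; };

// oriented k-mer value: the 2-bit word actually spelled by this orientation
static inline uint64_t oriented_val(const ONode& n, int k) {
  return n.fwd ? n.code : revcomp_code(n.code, k);
}

// Forward neighbors of an oriented node over the member set, sorted by
// appended base (the enumeration order below). Edges back to the same
// canonical node (homopolymer self-loops and hairpins into the node's own
// reverse complement) are artifacts of canonical identification, not of the
// underlying sequence, and are excluded: otherwise a k-mer whose reverse
// complement overlaps itself would spuriously branch and split the unitig
// spelling its locus.
static inline int forward_neighbors(const ONode& n, int k, uint64_t mask, int shift,
                                    const std::unordered_set<uint64_t>& members,
                                    ONode out[4]) {
  uint64_t w = oriented_val(n, k);
  int cnt = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    uint64_t ext = ((w << 2) | b) & mask;
    uint64_t rc = revcomp_code(ext, k);
    uint64_t canon = std::min(ext, rc);
    if (canon == n.code) continue;
    if (members.count(canon)) {
      out[cnt].code = canon;
      out[cnt].fwd = (canon == ext);
      ++cnt;
    }
  }
  (void)shift;
  return cnt;
}

static inline ONode flip(const ONode& n) { return ONode{n.code, !n.fwd}; }

// [[Rcpp::export]]
List cpp_forward_neighbors(CharacterVector members, std::string node,
                           std::string orientation, int k) {
  check_k(k);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  std::unordered_set<uint64_t> set;
  for (int i = 0; i < members.size(); ++i) {
    const char* s = CHAR(STRING_ELT(members, i));
    uint64_t code; int bad;
    if ((int)strlen(s) != k || !encode_code(s, k, code, bad))
      stop("member %d is not a valid k-mer", i + 1);
    if (revcomp_code(code, k) < code)
      stop("member %d ('%s') is not canonical", i + 1, s);
    set.insert(code);
  }
  uint64_t code; int bad;
  if ((int)node.size() != (size_t)k || !encode_code(node.c_str(), k, code, bad))
    stop("node is not a valid k-mer");
  if (revcomp_code(code, k) < code) stop("node is not canonical");
  if (!set.count(code)) stop("node is not a member of the k-mer set");
  ONode n{code, orientation == "+"};
  ONode nb[4];
  int m = forward_neighbors(n, k, mask, shift, set, nb);
  CharacterVector kmer(m), orient(m);
  for (int i = 0; i < m; ++i) {
    kmer[i] = decode_code(nb[i].code, k);
    orient[i] = nb[i].fwd ? "+" : "-";
  }
  return List::create(_["kmer"] = kmer, _["orientation"] = orient);
}

// Maximal unitigs of the bidirected dBG over a canonical k-mer set.
// Deterministic: nodes visited in ascending code order; extension only under
// the mutual-uniqueness rule (unique forward neighbor whose unique backward
// neighbor is the current node); hairpin edges x -> revcomp(x) never merge;
// isolated cycles are linearized at their smallest code. Output sequences are
// canonical (min of sequence and revcomp) and sorted.
// [[Rcpp::export]]
CharacterVector cpp_build_unitigs(CharacterVector kmers, int k) {
  check_k(k);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  int n = kmers.size();
  std::vector<uint64_t> codes;
  codes.reserve(n);
  std::unordered_set<uint64_t> members;
  members.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)strlen(s) != k)
      stop("k-mer %d has length %d, expected k = %d", i + 1, (int)strlen(s), k);
    uint64_t code; int bad;
    if (!encode_code(s, k, code, bad))
      stop("k-mer %d: non-ACGT character at position %d", i + 1, bad + 1);
    if (revcomp_code(code, k) < code)
      stop("k-mer %d ('%s') is not canonical", i + 1, s);
    if (!members.insert(code).second)
      stop("duplicate k-mer '%s'", s);
    codes.push_back(code);
  }
  std::sort(codes.begin(), codes.end());

  std::unordered_set<uint64_t> visited;
  visited.reserve(n * 2);
  std::vector<std::string> unitigs;
  ONode nb[4], back[4];

  for (uint64_t c : codes) {
    if (visited.count(c)) continue;
    visited.insert(c);
    std::deque<ONode> path;
    path.push_back(ONode{c, true});
    bool is_cycle = false;

    // forward extension from (c, +)
    ONode cur{c, true};
    while (true) {
      int m = forward_neighbors(cur, k, mask, shift, members, nb);
      if (m != 1) break;
      ONode nxt = nb[0];
      if (forward_neighbors(flip(nxt), k, mask, shift, members, back) != 1) break;
      if (nxt.code == c) {
        if (nxt.fwd) is_cycle = true;  // closed the loop in the same orientation
        break;                          // hairpin back to the start otherwise
      }
      if (visited.count(nxt.code)) break;  // repeat within the walk (hairpin mid-path)
      visited.insert(nxt.code);
      path.push_back(nxt);
      cur = nxt;
    }

    if (!is_cycle) {
      // backward extension: walk forward from (c, -) and prepend flipped
      cur = ONode{c, false};
      while (true) {
        int m = forward_neighbors(cur, k, mask, shift, members, nb);
        if (m != 1) break;
        ONode nxt = nb[0];
        if (forward_neighbors(flip(nxt), k, mask, shift, members, back) != 1) break;
        if (nxt.code == c || visited.count(nxt.code)) break;
        visited.insert(nxt.code);
        path.push_front(flip(nxt));
        cur = nxt;
      }
    }

    // spell the path
    std::string seq = decode_code(oriented_val(path.front(), k), k);
    for (size_t i = 1; i < path.size(); ++i) {
      uint64_t w = oriented_val(path[i], k);
      seq.push_back(bits2base((int)(w & 3ULL)));
    }
    // canonical output orientation
    std::string rc(seq.size(), 'A');
    for (size_t i = 0; i < seq.size(); ++i) {
      char ch = seq[seq.size() - 1 - i];
      rc[i] = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' : 'A';
    }
    unitigs.push_back(std::min(seq, rc));
  }

  std::sort(unitigs.begin(), unitigs.end());
  return wrap(unitigs);
}

// Constituent windows of each unitig: (unitig_id 0-based, offset 0-based,
// canonical k-mer, strand '+'/'-').
// [[Rcpp::export]]
List cpp_unitig_windows(CharacterVector seqs, int k) {
  check_k(k);
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    size_t len = strlen(CHAR(STRING_ELT(seqs, i)));
    if ((int)len < k) stop("unitig %d is shorter than k", i + 1);
    total += len - k + 1;
  }
  IntegerVector uid(total), off(total);
  CharacterVector kmer(total), strand(total);
  size_t pos = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = strlen(s);
    for (size_t j = 0; j + (size_t)k <= len; ++j) {
      uint64_t code; int bad;
      if (!encode_code(s + j, k, code, bad))
        stop("unitig %d: non-ACGT character at position %d", i + 1, (int)(j + bad + 1));
      uint64_t rc = revcomp_code(code, k);
      uid[pos] = i;
      off[pos] = (int)j;
      kmer[pos] = decode_code(std::min(code, rc), k);
      strand[pos] = (code <= rc) ? "+" : "-";
      ++pos;
    }
  }
  return List::create(_["unitig_id"] = uid, _["offset"] = off,
                      _["kmer"] = kmer, _["strand"] = strand);
}
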