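#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>

// Matching statistics for alignment-free distance estimation.
//
// For each position i of the query we need the length of the longest
// substring of the query starting at i that also occurs somewhere in the
// subject.  A suffix automaton of the reversed subject gives, while
// streaming the reversed query, the longest match *ending* at each
// position; reversing indices turns that into the start-based statistic.

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

struct SuffixAutomaton {
  std::vector<std::array<int, 4>> nxt;
  std::vector<int> link;
  std::vector<int> len;
  int last;

  explicit SuffixAutomaton(std::size_t cap) : last(0) {
    nxt.reserve(2 * cap + 4);
    link.reserve(2 * cap + 4);
    len.reserve(2 * cap + 4);
    nxt.push_back({{-1, -1, -1, -1}});
    link.push_back(-1);
    len.push_back(0);
  }

  void extend(int c) {
    int cur = static_cast<int>(nxt.size());
    nxt.push_back({{-1, -1, -1, -1}});
    len.push_back(len[last] + 1);
    link.push_back(-1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = static_cast<int>(nxt.size());
        nxt.push_back(nxt[q]);
        len.push_back(len[p] + 1);
        link.push_back(link[q]);
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

}  // namespace

// [[Rcpp::export(name = ".match_lengths_from")]]
Rcpp::IntegerVector match_lengths_from(const std::string& query,
                                       const std::string& subject) {
  const std::size_t nq = query.size();
  const std::size_t ns = subject.size();
  Rcpp::IntegerVector out(nq);
  if (nq == 0 || ns == 0) return out;

  SuffixAutomaton sa(ns);
  for (std::size_t i = ns; i-- > 0;) {
    int c = base_code(subject[i]);
    if (c < 0) Rcpp::stop("subject contains a non-ACGT symbol");
    sa.extend(c);
  }

  // Stream the reversed query; l tracks the current match length.
  int v = 0, l = 0;
  for (std::size_t j = nq; j-- > 0;) {
    int c = base_code(query[j]);
    if (c < 0) Rcpp::stop("query contains a non-ACGT symbol");
    while (v != 0 && sa.nxt[v][c] == -1) {
      v = sa.link[v];
      l = sa.len[v];
    }
    if (sa.nxt[v][c] != -1) {
      v = sa.nxt[v][c];
      ++l;
    } else {
      v = 0;
      l = 0;
    }
    out[j] = l;  // longest match starting at j (reversed stream)
  }
  return out;
}
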