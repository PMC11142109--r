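#include <Rcpp.h>
#include <map>
#include <vector>

using namespace Rcpp;

// Suffix automaton over an integer-coded text. Text codes: 1..4 for A,C,G,T;
// every separator and non-ACGT residue carries a unique negative code, so no
// pattern (coded over 1..4, with 0 for unmatchable residues) can ever match
// through one, and two such residues never match each other.
namespace {

struct SuffixAutomaton {
  std::vector<int> len, link;
  std::vector<std::map<int, int> > nxt;
  int last;

  explicit SuffixAutomaton(const IntegerVector& text) {
    size_t n = text.size();
    len.reserve(2 * n + 2);
    link.reserve(2 * n + 2);
    nxt.reserve(2 * n + 2);
    len.push_back(0);
    link.push_back(-1);
    nxt.push_back(std::map<int, int>());
    last = 0;
    for (size_t i = 0; i < n; ++i) extend(text[i]);
  }

  void extend(int c) {
    int cur = (int)len.size();
    len.push_back(len[last] + 1);
    link.push_back(-1);
    nxt.push_back(std::map<int, int>());
    int p = last;
    while (p != -1 && nxt[p].find(c) == nxt[p].end()) {
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
        int clone = (int)len.size();
        len.push_back(len[p] + 1);
        link.push_back(link[q]);
        nxt.push_back(nxt[q]);
        while (p != -1) {
          std::map<int, int>::iterator it = nxt[p].find(c);
          if (it == nxt[p].end() || it->second != q) break;
          it->second = clone;
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

// Matching statistics of one or more patterns against one coded text.
// ms[j] = length of the longest suffix of pattern[0..j] occurring in the text.
// [[Rcpp::export(name = ".sam_matching_statistics")]]
List sam_matching_statistics(IntegerVector text, List patterns) {
  SuffixAutomaton sam(text);
  int npat = patterns.size();
  List out(npat);
  for (int pi = 0; pi < npat; ++pi) {
    IntegerVector pat = patterns[pi];
    int m = pat.size();
    IntegerVector ms(m);
    int v = 0, l = 0;
    for (int j = 0; j < m; ++j) {
      int c = pat[j];
      if (c == 0) {  // unmatchable pattern residue: terminate any match
        v = 0;
        l = 0;
        ms[j] = 0;
        continue;
      }
      while (v != 0 && sam.nxt[v].find(c) == sam.nxt[v].end()) {
        v = sam.link[v];
        l = sam.len[v];
      }
      std::map<int, int>::iterator it = sam.nxt[v].find(c);
      if (it != sam.nxt[v].end()) {
        v = it->second;
        ++l;
      } else {
        l = 0;
      }
      ms[j] = l;
    }
    out[pi] = ms;
  }
  return out;
}
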