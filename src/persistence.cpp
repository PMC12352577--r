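#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Standard persistence pairing by boundary-matrix reduction over GF(2).
//
// Simplices arrive already sorted in a valid filtration order (value, dim,
// lexicographic vertex tuple), as flat 1-based vertex indices with offsets.
// Columns are kept as sorted index vectors; addition is symmetric difference.
// Returns one row per (birth simplex, death simplex) pair plus one row per
// unpaired (essential) positive simplex, with death = NA.

static inline uint64_t simplex_key(const int* v, int len) {
  // vertex indices fit in 16 bits each (n is capped far below 65535 upstream)
  uint64_t key = 0;
  for (int i = 0; i < len; ++i) key = (key << 16) | (uint64_t)(v[i] & 0xFFFF);
  return key;
}

static void sym_diff(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

// [[Rcpp::export(name = ".cpp_reduce_persistence")]]
NumericMatrix cpp_reduce_persistence(IntegerVector verts, IntegerVector offsets,
                                     NumericVector filt) {
  const int m = offsets.size() - 1;
  std::unordered_map<uint64_t, int> index;
  index.reserve(m * 2);
  std::vector<int> dims(m);

  for (int j = 0; j < m; ++j) {
    int a = offsets[j], b = offsets[j + 1];
    dims[j] = b - a - 1;
    index[simplex_key(&verts[a], b - a)] = j;
  }

  std::vector<int> pivot_owner(m, -1);           // row index -> column that has it as pivot
  std::vector<std::vector<int>> stored(m);       // reduced columns, by owning column
  std::vector<char> positive(m, 0), paired(m, 0);
  std::vector<std::pair<int, int>> pairs;
  std::vector<int> face(8);

  for (int j = 0; j < m; ++j) {
    int a = offsets[j], b = offsets[j + 1];
    int len = b - a;
    std::vector<int> col;
    if (len > 1) {
      col.reserve(len);
      for (int drop = 0; drop < len; ++drop) {
        int k = 0;
        for (int t = 0; t < len; ++t)
          if (t != drop) face[k++] = verts[a + t];
        auto it = index.find(simplex_key(face.data(), len - 1));
        if (it == index.end() || it->second >= j)
          stop("invalid filtration order: face of simplex %d missing or later", j + 1);
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int owner = pivot_owner[low];
        if (owner < 0) break;
        sym_diff(col, stored[owner]);
      }
    }
    if (col.empty()) {
      positive[j] = 1;
    } else {
      int low = col.back();
      pivot_owner[low] = j;
      stored[j] = std::move(col);
      paired[low] = 1;
      pairs.push_back(std::make_pair(low, j));
    }
  }

  int n_essential = 0;
  for (int j = 0; j < m; ++j)
    if (positive[j] && !paired[j]) ++n_essential;

  NumericMatrix out(pairs.size() + n_essential, 4);
  int r = 0;
  for (size_t t = 0; t < pairs.size(); ++t, ++r) {
    out(r, 0) = dims[pairs[t].first];
    out(r, 1) = filt[pairs[t].first];
    out(r, 2) = filt[pairs[t].second];
    out(r, 3) = 0;
  }
  for (int j = 0; j < m; ++j) {
    if (positive[j] && !paired[j]) {
      out(r, 0) = dims[j];
      out(r, 1) = filt[j];
      out(r, 2) = NA_REAL;
      out(r, 3) = 1;
      ++r;
    }
  }
  return out;
}
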