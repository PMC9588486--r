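// Standard persistence algorithm: column reduction of the boundary matrix
// over F2 in filtration order.  Columns arrive already sorted by
// (filtration value, dimension, lexicographic vertex tuple), so every face
// precedes its cofaces.  Returns, for each column, the index of the column
// it kills (0 if none), from which the R side assembles barcodes.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// flat: concatenated facet indices (1-based filtration positions) of all
// simplices in filtration order; lens[j] = number of facets of simplex j
// (0 for vertices).
// [[Rcpp::export]]
IntegerVector reduce_boundaries_cpp(IntegerVector flat, IntegerVector lens) {
  int m = lens.size();
  std::vector<std::vector<int>> cols(m);
  {
    int ptr = 0;
    for (int j = 0; j < m; ++j) {
      int l = lens[j];
      cols[j].assign(flat.begin() + ptr, flat.begin() + ptr + l);
      std::sort(cols[j].begin(), cols[j].end());
      ptr += l;
    }
  }
  std::vector<int> low_owner(m + 1, -1);  // low value -> reduced column
  IntegerVector kills(m, 0);
  std::vector<int> tmp;
  for (int j = 0; j < m; ++j) {
    std::vector<int>& col = cols[j];
    while (!col.empty()) {
      int low = col.back();
      int other = low_owner[low];
      if (other < 0) break;
      // col <- col XOR cols[other] (symmetric difference of sorted sets)
      const std::vector<int>& oc = cols[other];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    oc.begin(), oc.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int low = col.back();
      low_owner[low] = j;
      kills[j] = low;  // column j (1-based: j+1) kills the class born at low
    }
  }
  return kills;
}

// Triangle enumeration for the Vietoris-Rips complex: for each edge (u,v)
// (columns of `edges`, u < v), common neighbours w > v under the adjacency
// matrix.  Returns a 3 x T matrix of sorted vertex triples.
// [[Rcpp::export]]
IntegerMatrix vr_triangles_cpp(IntegerMatrix edges, LogicalMatrix adj) {
  int ne = edges.ncol(), n = adj.nrow();
  std::vector<int> out;
  for (int e = 0; e < ne; ++e) {
    int u = edges(0, e), v = edges(1, e);
    for (int w = v; w < n; ++w) {  // w is 1-based vertex w+1 > v
      if (adj(u - 1, w) && adj(v - 1, w)) {
        out.push_back(u); out.push_back(v); out.push_back(w + 1);
      }
    }
  }
  IntegerMatrix tri(3, out.size() / 3);
  std::copy(out.begin(), out.end(), tri.begin());
  return tri;
}
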