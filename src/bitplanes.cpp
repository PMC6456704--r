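// Bit-plane genotype store for exhaustive pair scanning.
//
// Each marker is encoded as three 64-bit-word bit vectors over samples, one
// per genotype class (dosage 0/1/2); a missing call sets no bit, so the
// validity vector is the OR of the three planes and every 2x3x3 pair table
// is a set of popcounts of AND-ed planes. This is exact counting, not an
// approximation: the contract is equality with a naive triple loop.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

struct GenoPlanes {
  int n;        // samples
  int m;        // markers
  int nwords;   // 64-bit words per plane
  std::vector<uint64_t> bits;  // layout: marker-major, 3 planes per marker

  const uint64_t* plane(int j, int g) const {
    return bits.data() + (static_cast<size_t>(j) * 3 + g) * nwords;
  }
};

static inline int popcount64(uint64_t x) {
  return __builtin_popcountll(x);
}

// [[Rcpp::export]]
SEXP cpp_encode_planes(IntegerMatrix geno) {
  int n = geno.nrow(), m = geno.ncol();
  int nwords = (n + 63) / 64;
  GenoPlanes* gp = new GenoPlanes();
  gp->n = n; gp->m = m; gp->nwords = nwords;
  gp->bits.assign(static_cast<size_t>(m) * 3 * nwords, 0ULL);
  for (int j = 0; j < m; ++j) {
    uint64_t* base = gp->bits.data() + (static_cast<size_t>(j) * 3) * nwords;
    for (int s = 0; s < n; ++s) {
      int g = geno(s, j);
      if (g == NA_INTEGER) continue;
      base[static_cast<size_t>(g) * nwords + (s >> 6)] |= 1ULL << (s & 63);
    }
  }
  XPtr<GenoPlanes> ptr(gp, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerMatrix cpp_plane_popcounts(SEXP planes) {
  XPtr<GenoPlanes> gp(planes);
  IntegerMatrix out(gp->m, 4);
  for (int j = 0; j < gp->m; ++j) {
    int valid = 0;
    for (int g = 0; g < 3; ++g) {
      const uint64_t* p = gp->plane(j, g);
      int c = 0;
      for (int w = 0; w < gp->nwords; ++w) c += popcount64(p[w]);
      out(j, g) = c;
      valid += c;
    }
    out(j, 3) = valid;
  }
  return out;
}

// Pack a 0/1 status vector into case/control word masks.
static void pack_status(const IntegerVector& status, int nwords,
                        std::vector<uint64_t>& case_w,
                        std::vector<uint64_t>& ctrl_w) {
  case_w.assign(nwords, 0ULL);
  ctrl_w.assign(nwords, 0ULL);
  int n = status.size();
  for (int s = 0; s < n; ++s) {
    if (status[s] == 1) case_w[s >> 6] |= 1ULL << (s & 63);
    else if (status[s] == 0) ctrl_w[s >> 6] |= 1ULL << (s & 63);
  }
}

// 18 counts for one pair, layout index = y + 2*g1 + 6*g2 (column-major for an
// R array of dim c(2, 3, 3)).
// [[Rcpp::export]]
IntegerVector cpp_pair_table(SEXP planes, int i, int j, IntegerVector status) {
  XPtr<GenoPlanes> gp(planes);
  if (i < 1 || i > gp->m || j < 1 || j > gp->m)
    stop("marker index out of range");
  if (status.size() != gp->n) stop("status length must equal sample count");
  int nwords = gp->nwords;
  std::vector<uint64_t> cw, tw;
  pack_status(status, nwords, cw, tw);
  IntegerVector out(18);
  for (int g1 = 0; g1 < 3; ++g1) {
    const uint64_t* p1 = gp->plane(i - 1, g1);
    for (int g2 = 0; g2 < 3; ++g2) {
      const uint64_t* p2 = gp->plane(j - 1, g2);
      int n_case = 0, n_ctrl = 0;
      for (int w = 0; w < nwords; ++w) {
        uint64_t both = p1[w] & p2[w];
        n_case += popcount64(both & cw[w]);
        n_ctrl += popcount64(both & tw[w]);
      }
      out[0 + 2 * g1 + 6 * g2] = n_ctrl;  // y = 0
      out[1 + 2 * g1 + 6 * g2] = n_case;  // y = 1
    }
  }
  return out;
}

// Tables for every pair (i, j) with from <= i <= to and i < j <= m.
// Returns the 18 counts per pair (rows) plus the 1-based marker indices.
// Status-masked planes are materialized once per call, so callers chunk over
// `from`/`to` to bound memory at large marker counts.
// [[Rcpp::export]]
List cpp_block_tables(SEXP planes, IntegerVector status, int from, int to) {
  XPtr<GenoPlanes> gp(planes);
  int m = gp->m, nwords = gp->nwords;
  if (from < 1 || to > m || from > to) stop("bad marker block");
  if (status.size() != gp->n) stop("status length must equal sample count");
  std::vector<uint64_t> cw, tw;
  pack_status(status, nwords, cw, tw);

  // masked planes: per marker, 3 genotype planes x 2 statuses
  std::vector<uint64_t> masked(static_cast<size_t>(m) * 6 * nwords);
  for (int j = 0; j < m; ++j)
    for (int g = 0; g < 3; ++g) {
      const uint64_t* p = gp->plane(j, g);
      uint64_t* out0 = masked.data() + (static_cast<size_t>(j) * 6 + 2 * g) * nwords;
      uint64_t* out1 = out0 + nwords;
      for (int w = 0; w < nwords; ++w) {
        out0[w] = p[w] & tw[w];   // controls
        out1[w] = p[w] & cw[w];   // cases
      }
    }

  R_xlen_t npairs = 0;
  for (int i = from; i <= to; ++i) npairs += m - i;
  IntegerMatrix counts(npairs, 18);
  IntegerVector pi(npairs), pj(npairs);
  R_xlen_t row = 0;
  for (int i = from - 1; i < to; ++i) {
    for (int j = i + 1; j < m; ++j) {
      for (int g1 = 0; g1 < 3; ++g1) {
        const uint64_t* a0 = masked.data() + (static_cast<size_t>(i) * 6 + 2 * g1) * nwords;
        const uint64_t* a1 = a0 + nwords;
        for (int g2 = 0; g2 < 3; ++g2) {
          const uint64_t* b0 = masked.data() + (static_cast<size_t>(j) * 6 + 2 * g2) * nwords;
          const uint64_t* b1 = b0 + nwords;
          int n0 = 0, n1 = 0;
          for (int w = 0; w < nwords; ++w) {
            n0 += popcount64(a0[w] & b0[w]);
            n1 += popcount64(a1[w] & b1[w]);
          }
          counts(row, 0 + 2 * g1 + 6 * g2) = n0;
          counts(row, 1 + 2 * g1 + 6 * g2) = n1;
        }
      }
      pi[row] = i + 1;
      pj[row] = j + 1;
      ++row;
    }
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["counts"] = counts);
}
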