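#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotype layout used by the simulator kernels: loci x haplotypes
// (one matrix column = one haplotype), so copying a chromosome segment
// of a gamete is a contiguous copy.

struct ChromSpan {
  int start, end;        // locus index range [start, end)
  double cm_lo, cm_hi;   // cM extent
};

// Founder haplotypes in linkage equilibrium: locus l is 1 with
// probability p[l], independently across haplotypes and loci.
// [[Rcpp::export]]
RawMatrix founder_pool_cpp(NumericVector p, int n_haps) {
  int L = p.size();
  RawMatrix out(L, n_haps);
  Rbyte *dst = out.begin();
  for (int h = 0; h < n_haps; ++h) {
    for (int l = 0; l < L; ++l) {
      *dst++ = (unif_rand() < p[l]) ? 1 : 0;
    }
  }
  return out;
}

static std::vector<ChromSpan> chrom_spans(const IntegerVector &chrom_id,
                                          const NumericVector &cm) {
  std::vector<ChromSpan> spans;
  int L = chrom_id.size();
  int s = 0;
  for (int i = 1; i <= L; ++i) {
    if (i == L || chrom_id[i] != chrom_id[s]) {
      ChromSpan sp;
      sp.start = s;
      sp.end = i;
      sp.cm_lo = cm[s];
      sp.cm_hi = cm[i - 1];
      spans.push_back(sp);
      s = i;
    }
  }
  return spans;
}

// ---- bit-packed haplotype storage (internal to the evolve loop) ----
// Haplotype h is a column of ceil(L/8) bytes; locus l lives at bit l%8
// (LSB first) of byte l/8. Packing costs one pass at the call boundary;
// the per-generation segment copies then move 8x fewer bytes.

static inline int get_bit(const Rbyte *col, int l) {
  return (col[l >> 3] >> (l & 7)) & 1;
}

// copy bit range [from, to) from src column to dst column
static void copy_bits(const Rbyte *src, Rbyte *dst, int from, int to) {
  if (to <= from) return;
  int b0 = from >> 3, b1 = (to - 1) >> 3;
  if (b0 == b1) {
    Rbyte mask = (Rbyte)(((0xFFu << (from & 7)) & (0xFFu >> (7 - ((to - 1) & 7)))));
    dst[b0] = (Rbyte)((dst[b0] & ~mask) | (src[b0] & mask));
    return;
  }
  if (from & 7) {
    Rbyte mask = (Rbyte)(0xFFu << (from & 7));
    dst[b0] = (Rbyte)((dst[b0] & ~mask) | (src[b0] & mask));
    ++b0;
  }
  int full_end = to >> 3;      // bytes [b0, full_end) are fully covered
  if (full_end > b0) std::copy(src + b0, src + full_end, dst + b0);
  if (to & 7) {
    Rbyte mask = (Rbyte)(0xFFu >> (8 - (to & 7)));
    dst[full_end] = (Rbyte)((dst[full_end] & ~mask) | (src[full_end] & mask));
  }
}

// Transmit one gamete from diploid parent p (packed columns 2p, 2p+1)
// into packed dest. Crossover count per chromosome is Poisson(length in
// Morgans), positions uniform on the chromosome's cM extent.
static void make_gamete(const Rbyte *pool, size_t bytes_per_hap, int p,
                        const std::vector<ChromSpan> &spans,
                        const NumericVector &cm, Rbyte *dest) {
  for (size_t c = 0; c < spans.size(); ++c) {
    const ChromSpan &sp = spans[c];
    int which = (unif_rand() < 0.5) ? 0 : 1;
    double len_m = (sp.cm_hi - sp.cm_lo) / 100.0;
    int k = (len_m > 0) ? (int)R::rpois(len_m) : 0;
    const Rbyte *h0 = pool + (size_t)(2 * p) * bytes_per_hap;
    const Rbyte *h1 = h0 + bytes_per_hap;
    if (k == 0) {
      copy_bits(which ? h1 : h0, dest, sp.start, sp.end);
      continue;
    }
    std::vector<double> xpos(k);
    for (int i = 0; i < k; ++i)
      xpos[i] = sp.cm_lo + unif_rand() * (sp.cm_hi - sp.cm_lo);
    std::sort(xpos.begin(), xpos.end());
    int cur = sp.start;
    for (int i = 0; i < k; ++i) {
      // first locus strictly beyond the crossover point
      const double *lo = &cm[0] + sp.start;
      const double *hi = &cm[0] + sp.end;
      int split = (int)(std::upper_bound(lo, hi, xpos[i]) - &cm[0]);
      if (split > cur) {
        copy_bits(which ? h1 : h0, dest, cur, split);
        cur = split;
      }
      which ^= 1;
    }
    if (cur < sp.end) copy_bits(which ? h1 : h0, dest, cur, sp.end);
  }
}

// Weighted (or uniform) parent index draw via inverse CDF on cumw.
static int draw_parent(const std::vector<double> &cumw, int n) {
  if (cumw.empty()) return (int)(unif_rand() * n) % n;
  double u = unif_rand() * cumw[n - 1];
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// Evolve a diploid Wright-Fisher population forward in time.
// haps: loci x (2*N_parent) raw 0/1 matrix. Returns loci x (2*n_offspring).
// sel_locus (0-based) with additive fitness 1, 1+s, 1+2s; -1 = neutral.
// [[Rcpp::export]]
RawMatrix wf_evolve_cpp(RawMatrix haps, NumericVector cm, IntegerVector chrom_id,
                        int n_offspring, int generations, int sel_locus, double s) {
  int L = haps.nrow();
  if (generations <= 0) return haps;
  std::vector<ChromSpan> spans = chrom_spans(chrom_id, cm);
  size_t bph = (size_t)((L + 7) / 8);
  int n_parent = haps.ncol() / 2;

  // pack the parent pool
  std::vector<Rbyte> packA(bph * 2 * std::max(n_parent, n_offspring), 0),
                     packB(bph * 2 * n_offspring, 0);
  for (int h = 0; h < haps.ncol(); ++h) {
    const Rbyte *colv = haps.begin() + (size_t)h * L;
    Rbyte *colp = packA.data() + (size_t)h * bph;
    for (int l = 0; l < L; ++l)
      if (colv[l]) colp[l >> 3] |= (Rbyte)(1u << (l & 7));
  }
  Rbyte *src = packA.data();
  Rbyte *dst = packB.data();

  std::vector<double> cumw;
  for (int g = 0; g < generations; ++g) {
    cumw.clear();
    if (sel_locus >= 0) {
      cumw.resize(n_parent);
      double acc = 0.0;
      for (int p = 0; p < n_parent; ++p) {
        int gt = get_bit(src + (size_t)(2 * p) * bph, sel_locus) +
                 get_bit(src + (size_t)(2 * p + 1) * bph, sel_locus);
        acc += 1.0 + s * gt;
        cumw[p] = acc;
      }
    }
    for (int i = 0; i < n_offspring; ++i) {
      int p1 = draw_parent(cumw, n_parent);
      int p2 = draw_parent(cumw, n_parent);
      make_gamete(src, bph, p1, spans, cm, dst + (size_t)(2 * i) * bph);
      make_gamete(src, bph, p2, spans, cm, dst + (size_t)(2 * i + 1) * bph);
    }
    std::swap(src, dst);
    n_parent = n_offspring;
  }

  // unpack
  RawMatrix out(L, 2 * n_offspring);
  for (int h = 0; h < 2 * n_offspring; ++h) {
    const Rbyte *colp = src + (size_t)h * bph;
    Rbyte *colv = out.begin() + (size_t)h * L;
    for (int l = 0; l < L; ++l) colv[l] = (Rbyte)get_bit(colp, l);
  }
  return out;
}

// Mean dosage r^2 within sliding recombination-distance categories.
// calls: samples x loci (NA allowed); loci sorted by (chrom, cm).
// Category k covers [bin_start + k*bin_step, bin_start + k*bin_step + bin_width).
// [[Rcpp::export]]
List r2_binned_cpp(IntegerMatrix calls, NumericVector cm, IntegerVector chrom_id,
                   double bin_start, double bin_step, double bin_width, int n_bins) {
  int n = calls.nrow(), L = calls.ncol();
  double d_max = bin_start + (n_bins - 1) * bin_step + bin_width;
  NumericVector sum_r2(n_bins), sum_r2_sq(n_bins);
  IntegerVector n_pairs(n_bins);

  for (int j = 0; j < L; ++j) {
    for (int k = j + 1; k < L && chrom_id[k] == chrom_id[j]; ++k) {
      double d = cm[k] - cm[j];
      if (d >= d_max) break;
      int b_max = (int)std::floor((d - bin_start) / bin_step + 1e-12);
      int b_min = (int)std::floor((d - bin_start - bin_width) / bin_step + 1e-12) + 1;
      if (b_max < 0) continue;
      if (b_min < 0) b_min = 0;
      if (b_max > n_bins - 1) b_max = n_bins - 1;
      if (b_min > b_max) continue;

      // pairwise-complete dosage correlation
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int m = 0;
      const int *xj = &calls[0] + (size_t)j * n;
      const int *xk = &calls[0] + (size_t)k * n;
      for (int i = 0; i < n; ++i) {
        if (xj[i] == NA_INTEGER || xk[i] == NA_INTEGER) continue;
        double x = xj[i], y = xk[i];
        sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
        ++m;
      }
      if (m < 2) continue;
      double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
      if (vx <= 0 || vy <= 0) continue;
      double cov = sxy - sx * sy / m;
      double r2 = (cov * cov) / (vx * vy);
      for (int b = b_min; b <= b_max; ++b) {
        sum_r2[b] += r2;
        sum_r2_sq[b] += r2 * r2;
        n_pairs[b] += 1;
      }
    }
  }
  return List::create(_["sum_r2"] = sum_r2, _["sum_r2_sq"] = sum_r2_sq,
                      _["n_pairs"] = n_pairs);
}

// Haplotype-partition bookkeeping for EHH. Haplotypes start in a single
// group at the core (both core alleles pooled, as XP-EHH requires) and are
// refined by each successive locus moving outward.
struct EhhState {
  std::vector<int> group;
  int n_groups;
  explicit EhhState(int H) : group(H, 0), n_groups(1) {}
  // refine by alleles at column `col` (length H)
  void refine(const int *col) {
    int H = group.size();
    std::vector<int> key(H);
    for (int i = 0; i < H; ++i) key[i] = group[i] * 2 + (col[i] ? 1 : 0);
    std::vector<int> remap(2 * n_groups, -1);
    int next = 0;
    for (int i = 0; i < H; ++i) {
      if (remap[key[i]] < 0) remap[key[i]] = next++;
      group[i] = remap[key[i]];
    }
    n_groups = next;
  }
};

// EHH over a haplotype subset [lo, hi) given the current partition.
static double ehh_of(const EhhState &st, int lo, int hi) {
  int n = hi - lo;
  if (n < 2) return NA_REAL;
  std::vector<int> cnt(st.n_groups, 0);
  for (int i = lo; i < hi; ++i) cnt[st.group[i]]++;
  double num = 0;
  for (int g = 0; g < st.n_groups; ++g)
    num += 0.5 * cnt[g] * (cnt[g] - 1.0);
  return num / (0.5 * n * (n - 1.0));
}

// Integrated EHH for target and reference populations at each core SNP.
// haps: haplotypes x loci; rows [0, n_target) = target, rest = reference.
// Each direction is truncated where the pooled EHH drops below `cutoff`
// (that extension's trapezoid segment is included), at a bp gap larger
// than max_gap_bp, or at the chromosome end.
// [[Rcpp::export]]
NumericMatrix ihh_scan_cpp(IntegerMatrix haps, int n_target, NumericVector cm,
                           IntegerVector chrom_id, NumericVector bp,
                           double cutoff, double max_gap_bp, IntegerVector cores) {
  int H = haps.nrow(), L = haps.ncol();
  NumericMatrix out(cores.size(), 2);
  std::vector<int> col(H);

  for (int ci = 0; ci < cores.size(); ++ci) {
    int core = cores[ci];
    double ihh_t = 0, ihh_r = 0;
    for (int dir = 0; dir < 2; ++dir) {
      EhhState st(H);
      double e_t = 1.0, e_r = 1.0, e_pool = 1.0;
      double cm_prev = cm[core];
      double bp_prev = bp[core];
      int step = dir ? 1 : -1;
      for (int l = core + step; l >= 0 && l < L; l += step) {
        if (chrom_id[l] != chrom_id[core]) break;
        if (std::abs(bp[l] - bp_prev) > max_gap_bp) break;
        const int *src = &haps[0] + (size_t)l * H;
        for (int i = 0; i < H; ++i) col[i] = src[i];
        st.refine(col.data());
        double nt = ehh_of(st, 0, n_target);
        double nr = ehh_of(st, n_target, H);
        double np = ehh_of(st, 0, H);
        double dcm = std::abs(cm[l] - cm_prev);
        ihh_t += 0.5 * (e_t + nt) * dcm;
        ihh_r += 0.5 * (e_r + nr) * dcm;
        e_t = nt; e_r = nr; e_pool = np;
        cm_prev = cm[l];
        bp_prev = bp[l];
        if (e_pool < cutoff) break;
      }
    }
    out(ci, 0) = ihh_t;
    out(ci, 1) = ihh_r;
  }
  return out;
}
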