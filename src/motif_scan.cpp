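#include <Rcpp.h>
using namespace Rcpp;

// Degenerate-consensus scanner over circular DNA. Each motif position is a
// bitmask over {A=1, C=2, G=4, T=8}; a subject base matching any allowed
// nucleotide costs 0 mismatches, anything else (including N) costs 1.

namespace {

inline int base_bit(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
    default:  return 0; // N or anything else: never matches
  }
}

inline int comp_mask(int m) {
  // A<->T (1<->8), C<->G (2<->4)
  int r = 0;
  if (m & 1) r |= 8;
  if (m & 8) r |= 1;
  if (m & 2) r |= 4;
  if (m & 4) r |= 2;
  return r;
}

void scan_one_strand(const std::vector<int>& bits, const std::vector<int>& mask,
                     int max_mm, bool circular, int start, char strand,
                     std::vector<int>& out_start, std::vector<std::string>& out_strand,
                     std::vector<int>& out_mm) {
  const int L = bits.size(), w = mask.size();
  int mm = 0;
  for (int j = 0; j < w; ++j) {
    int p = start + j;
    if (p >= L) { if (!circular) return; p -= L; }
    if (!(bits[p] & mask[j])) { ++mm; if (mm > max_mm) return; }
  }
  out_start.push_back(start);
  out_strand.push_back(std::string(1, strand));
  out_mm.push_back(mm);
}

} // namespace

// [[Rcpp::export(name = ".scan_motif")]]
DataFrame scan_motif_cpp(std::string seq, IntegerVector mask_fwd, int max_mm,
                         bool do_fwd, bool do_rev, bool circular) {
  const int L = seq.size(), w = mask_fwd.size();
  if (w > L) stop("motif longer than sequence");
  std::vector<int> bits(L);
  for (int i = 0; i < L; ++i) bits[i] = base_bit(seq[i]);
  std::vector<int> fwd(w), rev(w);
  for (int j = 0; j < w; ++j) fwd[j] = mask_fwd[j];
  for (int j = 0; j < w; ++j) rev[j] = comp_mask(fwd[w - 1 - j]);

  std::vector<int> out_start, out_mm;
  std::vector<std::string> out_strand;
  const int last = circular ? L - 1 : L - w;
  for (int s = 0; s <= last; ++s) {
    if (do_fwd) scan_one_strand(bits, fwd, max_mm, circular, s, '+',
                                out_start, out_strand, out_mm);
    if (do_rev) scan_one_strand(bits, rev, max_mm, circular, s, '-',
                                out_start, out_strand, out_mm);
  }
  return DataFrame::create(_["start"] = out_start, _["strand"] = out_strand,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}
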