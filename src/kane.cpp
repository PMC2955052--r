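#include <Rcpp.h>
using namespace Rcpp;

// Ungapped all-offset scan of a probe against a target, used for Kane's
// specificity criteria. Inosine ('I') in the probe matches any target
// base and counts as a match for both the identity and the stretch
// statistic. 'N' in the target matches nothing except probe inosine.

static inline bool base_match(char p, char t) {
  return p == 'I' || p == t;
}

static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (char &c : out) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return out;
}

struct ScanResult {
  double identity_pct;
  int longest_stretch;
  int position;   // 1-based offset on the scanned strand
  char strand;
};

static ScanResult scan_one(const std::string &probe,
                           const std::string &target) {
  const int L = probe.size();
  ScanResult best = {-1.0, 0, NA_INTEGER, '+'};
  const std::string strands[2] = {target, revcomp(target)};
  const char labels[2] = {'+', '-'};
  for (int s = 0; s < 2; ++s) {
    const std::string &t = strands[s];
    const int T = t.size();
    for (int off = 0; off + L <= T; ++off) {
      int matches = 0, run = 0, best_run = 0;
      for (int i = 0; i < L; ++i) {
        if (base_match(probe[i], t[off + i])) {
          ++matches;
          if (++run > best_run) best_run = run;
        } else {
          run = 0;
        }
      }
      double ident = 100.0 * matches / L;
      if (ident > best.identity_pct) {
        best.identity_pct = ident;
        best.position = off + 1;
        best.strand = labels[s];
      }
      if (best_run > best.longest_stretch) best.longest_stretch = best_run;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".kane_scan_cpp")]]
DataFrame kane_scan_cpp(CharacterVector probes, std::string target) {
  const int n = probes.size();
  NumericVector identity(n);
  IntegerVector stretch(n), position(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string p = as<std::string>(probes[i]);
    if ((int)p.size() > (int)target.size())
      stop("probe longer than target");
    ScanResult r = scan_one(p, target);
    identity[i] = r.identity_pct;
    stretch[i] = r.longest_stretch;
    position[i] = r.position;
    strand[i] = std::string(1, r.strand);
  }
  return DataFrame::create(
    _["identity_pct"] = identity,
    _["longest_stretch"] = stretch,
    _["position"] = position,
    _["strand"] = strand,
    _["stringsAsFactors"] = false);
}
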