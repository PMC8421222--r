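#include <Rcpp.h>
using namespace Rcpp;

// IUPAC bitmasks: A=1 C=2 G=4 T=8.  Read bases are only credited when
// concrete (A/C/G/T); an N in a read never satisfies a reference position.
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'M': return 3;  case 'R': return 5;  case 'W': return 9;  case 'S': return 6;
    case 'Y': return 10; case 'K': return 12; case 'V': return 7;  case 'H': return 11;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default:  return 0;
  }
}

static int concrete_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default:  return 0;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector x, CharacterVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    const char *b = CHAR(STRING_ELT(y, i));
    size_t la = strlen(a), lb = strlen(b);
    if (la != lb) stop("hamming distance requires equal lengths");
    int d = 0;
    for (size_t k = 0; k < la; ++k) if (a[k] != b[k]) ++d;
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_min_pairwise_dist(CharacterVector x) {
  R_xlen_t n = x.size();
  if (n < 2) return NA_INTEGER;
  int best = INT_MAX;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    size_t la = strlen(a);
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const char *b = CHAR(STRING_ELT(x, j));
      if (strlen(b) != la) stop("barcodes must have equal lengths");
      int d = 0;
      for (size_t k = 0; k < la && d < best; ++k) if (a[k] != b[k]) ++d;
      if (d < best) best = d;
    }
  }
  return best;
}

// Assign each prefix to the unique reference within max_mm mismatches.
// Returns 1-based reference index; 0 = unassigned, -1 = ambiguous tie.
// [[Rcpp::export]]
IntegerVector cpp_assign_barcodes(CharacterVector prefixes, CharacterVector refs,
                                  int max_mm) {
  R_xlen_t n = prefixes.size(), m = refs.size();
  std::vector<const char *> rp(m);
  size_t blen = m > 0 ? strlen(CHAR(STRING_ELT(refs, 0))) : 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    rp[j] = CHAR(STRING_ELT(refs, j));
    if (strlen(rp[j]) != blen) stop("reference barcodes must have equal lengths");
  }
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *p = CHAR(STRING_ELT(prefixes, i));
    if (strlen(p) != blen) stop("prefix length must equal barcode length");
    int best = max_mm + 1, best_j = 0, ties = 0;
    for (R_xlen_t j = 0; j < m; ++j) {
      int d = 0;
      const char *r = rp[j];
      for (size_t k = 0; k < blen && d <= best; ++k) if (p[k] != r[k]) ++d;
      if (d < best)      { best = d; best_j = (int)j + 1; ties = 1; }
      else if (d == best && d <= max_mm) ++ties;
    }
    out[i] = (best > max_mm) ? 0 : (ties > 1 ? -1 : best_j);
  }
  return out;
}

// Mismatch count of each read's first L bases against an IUPAC reference.
// Reads shorter than L get NA.
// [[Rcpp::export]]
IntegerVector cpp_mismatch_counts(CharacterVector seqs, std::string ref) {
  size_t L = ref.size();
  std::vector<int> rmask(L);
  for (size_t k = 0; k < L; ++k) rmask[k] = iupac_mask(ref[k]);
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    if (strlen(s) < L) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t k = 0; k < L; ++k)
      if ((rmask[k] & concrete_mask(s[k])) == 0) ++d;
    out[i] = d;
  }
  return out;
}

// Per-position base counts (rows A,C,G,T,N/other) over the first L bases.
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(CharacterVector seqs, int L) {
  IntegerMatrix out(5, L);
  R_xlen_t n = seqs.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) < L) stop("read shorter than profiled region");
    for (int k = 0; k < L; ++k) {
      int row;
      switch (s[k]) {
        case 'A': row = 0; break; case 'C': row = 1; break;
        case 'G': row = 2; break; case 'T': row = 3; break;
        default:  row = 4;
      }
      out(row, k) += 1;
    }
  }
  return out;
}

// Classify the first L bases against a concrete reference: number of
// mismatches, and when exactly one, its 1-based 5' position and read base.
// [[Rcpp::export]]
List cpp_classify_single(CharacterVector seqs, std::string ref) {
  size_t L = ref.size();
  R_xlen_t n = seqs.size();
  IntegerVector nmm(n), pos(n);
  CharacterVector base(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    if (strlen(s) < L) { nmm[i] = NA_INTEGER; pos[i] = NA_INTEGER; base[i] = NA_STRING; continue; }
    int d = 0, p1 = 0; char b1 = 0;
    for (size_t k = 0; k < L; ++k)
      if (s[k] != ref[k]) { ++d; if (d == 1) { p1 = (int)k + 1; b1 = s[k]; } }
    nmm[i] = d;
    if (d == 1) { pos[i] = p1; base[i] = std::string(1, b1); }
    else { pos[i] = NA_INTEGER; base[i] = NA_STRING; }
  }
  return List::create(_["n_mismatch"] = nmm, _["pos"] = pos, _["base"] = base);
}

// Best ungapped overlap merge of read pairs.  r2rc must already be the
// reverse complement of read 2 (and q2r its reversed quality).  Overlap o
// joins the suffix of r1 to the prefix of r2rc; candidates are scored by
// mismatch fraction (<= max_frac admissible), minimal fraction wins, ties
// to the longest overlap.  Consensus takes the higher-quality base.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                     CharacterVector q1, CharacterVector q2r,
                     int min_overlap, double max_frac) {
  R_xlen_t n = r1.size();
  CharacterVector seq(n), qual(n);
  IntegerVector ov(n);
  LogicalVector merged(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(r2rc, i));
    const char *qa = CHAR(STRING_ELT(q1, i));
    const char *qb = CHAR(STRING_ELT(q2r, i));
    int la = (int)strlen(a), lb = (int)strlen(b);
    int omax = la < lb ? la : lb;
    int best_o = -1;
    double best_frac = 2.0;
    for (int o = omax; o >= min_overlap; --o) {
      int allowed = (int)std::floor(max_frac * o);
      int d = 0;
      const char *as = a + (la - o);
      for (int k = 0; k < o && d <= allowed; ++k) if (as[k] != b[k]) ++d;
      if (d > allowed) continue;
      double frac = (double)d / (double)o;
      if (frac < best_frac) { best_frac = frac; best_o = o; }
      if (d == 0) break;  // 0 at the longest remaining overlap cannot be beaten
    }
    if (best_o < 0) {
      seq[i] = NA_STRING; qual[i] = NA_STRING; ov[i] = NA_INTEGER; merged[i] = false;
      continue;
    }
    int o = best_o, lm = la + lb - o;
    std::string ms(lm, 'N'), mq(lm, '!');
    for (int k = 0; k < la - o; ++k) { ms[k] = a[k]; mq[k] = qa[k]; }
    for (int k = 0; k < o; ++k) {
      int ia = la - o + k;
      if (a[ia] == b[k] || qa[ia] >= qb[k]) { ms[la - o + k] = a[ia]; }
      else                                   { ms[la - o + k] = b[k]; }
      mq[la - o + k] = qa[ia] >= qb[k] ? qa[ia] : qb[k];
    }
    for (int k = o; k < lb; ++k) { ms[la + k - o] = b[k]; mq[la + k - o] = qb[k]; }
    seq[i] = ms; qual[i] = mq; ov[i] = o; merged[i] = true;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = ov, _["merged"] = merged);
}

// Remove 3' adapter read-through: scan start positions left to right and
// trim at the first admissible suffix/prefix overlap (>= min_overlap bases,
// mismatch fraction <= max_frac), i.e. the longest trim.
// [[Rcpp::export]]
List cpp_trim_adapter(CharacterVector seqs, CharacterVector quals,
                      std::string adapter, int min_overlap, double max_frac) {
  R_xlen_t n = seqs.size();
  int lad = (int)adapter.size();
  CharacterVector seq(n), qual(n);
  IntegerVector trimmed(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    int ls = (int)strlen(s);
    int cut = ls;
    for (int st = 0; st <= ls - min_overlap; ++st) {
      int o = ls - st; if (o > lad) o = lad;
      if (o < min_overlap) break;
      int allowed = (int)std::floor(max_frac * o);
      int d = 0;
      for (int k = 0; k < o && d <= allowed; ++k) if (s[st + k] != adapter[k]) ++d;
      if (d <= allowed) { cut = st; break; }
    }
    seq[i] = std::string(s, s + cut);
    qual[i] = std::string(q, q + cut);
    trimmed[i] = ls - cut;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual, _["trimmed"] = trimmed);
}

// Uniform substitution errors using R's RNG (so set.seed() governs output).
// Each base mutates with probability rate to one of the three other bases.
// [[Rcpp::export]]
List cpp_add_errors(CharacterVector seqs, double rate) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  List poslist(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int> hits;
    if (rate > 0) {
      for (size_t k = 0; k < s.size(); ++k) {
        if (unif_rand() < rate) {
          char cur = s[k];
          char nb;
          do { nb = bases[(int)std::floor(unif_rand() * 4.0) % 4]; } while (nb == cur);
          s[k] = nb;
          hits.push_back((int)k + 1);
        }
      }
    }
    out[i] = s;
    poslist[i] = IntegerVector(hits.begin(), hits.end());
  }
  return List::create(_["seq"] = out, _["error_positions"] = poslist);
}
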