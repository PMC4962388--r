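#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp_str(const char* s, int L) {
  std::string out(L, 'N');
  for (int i = 0; i < L; ++i) out[i] = comp_base(s[L - 1 - i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    out[i] = revcomp_str(s, (int) std::strlen(s));
  }
  return out;
}

// i.i.d. uniform DNA strings from R's RNG (reproducible under set.seed)
// [[Rcpp::export]]
CharacterVector cpp_random_dna(int n, IntegerVector len) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    int L = len[len.size() == 1 ? 0 : i];
    buf.assign(L, 'A');
    // 8 bases per uniform draw (16 of the ~53 mantissa bits)
    for (int j = 0; j < L; j += 8) {
      uint32_t bitsv = (uint32_t) (unif_rand() * 65536.0);
      if (bitsv > 65535u) bitsv = 65535u;
      int jmax = std::min(L, j + 8);
      for (int k = j; k < jmax; ++k) {
        buf[k] = B[bitsv & 3u];
        bitsv >>= 2;
      }
    }
    out[i] = buf;
  }
  return out;
}

// Per-cycle substitution errors; returns mutated reads and per-read error counts.
// err_by_cycle is recycled positionally: cycle j (0-based) uses err_by_cycle[min(j, len-1)].
// [[Rcpp::export]]
List cpp_mutate_reads(CharacterVector reads, NumericVector err_by_cycle) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int n = reads.size(), np = err_by_cycle.size();
  CharacterVector out(n);
  IntegerVector nerr(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int L = (int) std::strlen(s);
    buf.assign(s, L);
    int e = 0;
    for (int j = 0; j < L; ++j) {
      double p = err_by_cycle[j < np ? j : np - 1];
      if (p > 0.0 && unif_rand() < p) {
        int c = base_code(buf[j]);
        int alt = (int) (unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        // pick uniformly among the three other bases
        int b = (alt >= c && c >= 0) ? alt + 1 : alt;
        buf[j] = B[b & 3];
        ++e;
      }
    }
    out[i] = buf;
    nerr[i] = e;
  }
  return List::create(_["seq"] = out, _["n_err"] = nerr);
}

// 3' quality trimming (running-sum rule) + 3' adapter removal by suffix/prefix overlap.
// [[Rcpp::export]]
List cpp_trim(CharacterVector seq, CharacterVector qual, int cutoff,
              std::string adapter, int min_overlap) {
  int n = seq.size();
  CharacterVector oseq(n), oqual(n);
  int alen = (int) adapter.size();
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    int L = (int) std::strlen(s);
    if ((int) std::strlen(q) != L)
      stop("sequence/quality length mismatch at read %d", i + 1);
    // quality: remove the 3' suffix maximizing sum(cutoff - q); only if the max is positive
    int cut = L, best = 0, run = 0;
    for (int j = L - 1; j >= 0; --j) {
      run += cutoff - ((int) q[j] - 33);
      if (run > best) { best = run; cut = j; }
    }
    int L2 = (best > 0) ? cut : L;
    // adapter: longest suffix of the read equal to a prefix of the adapter, >= min_overlap
    if (alen > 0) {
      int kmax = std::min(L2, alen);
      for (int k = kmax; k >= min_overlap; --k) {
        if (std::memcmp(s + (L2 - k), adapter.data(), (size_t) k) == 0) { L2 -= k; break; }
      }
    }
    oseq[i] = std::string(s, (size_t) L2);
    oqual[i] = std::string(q, (size_t) L2);
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// ---------------------------------------------------------------------------
// Local alignment: affine-gap Smith-Waterman with traceback.
// Gap of length L costs gap_open + gap_ext * L (BLAST-style existence/extension).
// ---------------------------------------------------------------------------

struct Aln {
  int score = 0;
  int rs = 0, re = 0, gs = 0, ge = 0;  // 1-based inclusive, aligned orientation
  std::string cigar;
};

// Banded affine-gap Smith-Waterman around diagonal d (gene_pos ~ read_pos + d),
// with traceback. Alignment paths are confined to |j - i - d| <= band.
static bool smith_waterman(const std::string& r, const char* g, int gl,
                           int d, int band, int match, int mismatch,
                           int go, int ge, Aln& out) {
  const int m = (int) r.size(), n = gl;
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  static std::vector<int> H, E, F;
  static std::vector<int8_t> tbH, tbE, tbF;  // tbH: 0 stop, 1 diag, 2 E (D), 3 F (I)
  size_t cells = (size_t) (m + 1) * (size_t) W;
  H.assign(cells, NEG); E.assign(cells, NEG); F.assign(cells, NEG);
  tbH.assign(cells, 0); tbE.assign(cells, 0); tbF.assign(cells, 0);
  // row 0: empty-prefix cells inside the band start at 0
  for (int c = 0; c < W; ++c) {
    int j = d - band + c;
    if (j >= 0 && j <= n) H[c] = 0;
  }
  int bi = 0, bc = 0, bscore = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + d - band), jhi = std::min(n, i + d + band);
    size_t row = (size_t) i * W, prow = (size_t) (i - 1) * W;
    for (int j = jlo; j <= jhi; ++j) {
      int c = j - (i + d - band);
      size_t idx = row + c;
      // E from left neighbor (i, j-1) at col c-1
      int hleft = (c - 1 >= 0) ? H[row + c - 1] : NEG;
      int eleft = (c - 1 >= 0) ? E[row + c - 1] : NEG;
      int e_open = (hleft <= NEG / 2) ? NEG : hleft - go - ge;
      int e_ext = (eleft <= NEG / 2) ? NEG : eleft - ge;
      int Ev = std::max(e_open, e_ext);
      tbE[idx] = (int8_t) (e_ext > e_open ? 1 : 0);
      E[idx] = Ev;
      // F from up neighbor (i-1, j) at col c+1
      int hup = (c + 1 < W) ? H[prow + c + 1] : NEG;
      int fup = (c + 1 < W) ? F[prow + c + 1] : NEG;
      int f_open = (hup <= NEG / 2) ? NEG : hup - go - ge;
      int f_ext = (fup <= NEG / 2) ? NEG : fup - ge;
      int Fv = std::max(f_open, f_ext);
      tbF[idx] = (int8_t) (f_ext > f_open ? 1 : 0);
      F[idx] = Fv;
      // diagonal neighbor (i-1, j-1) is the same col in the previous row
      int hdiag = H[prow + c];
      int sub = (hdiag <= NEG / 2) ? NEG
                : hdiag + ((r[i - 1] == g[j - 1]) ? match : mismatch);
      int Hv = 0; int8_t tb = 0;
      if (sub > Hv) { Hv = sub; tb = 1; }
      if (Ev > Hv) { Hv = Ev; tb = 2; }
      if (Fv > Hv) { Hv = Fv; tb = 3; }
      H[idx] = Hv; tbH[idx] = tb;
      if (Hv > bscore) { bscore = Hv; bi = i; bc = c; }
    }
  }
  if (bscore <= 0) return false;
  // traceback
  std::string ops;
  int i = bi, c = bc;
  int bj = bi + d - band + bc;
  int j = bj;
  int state = 0;  // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t) i * W + c;
    if (state == 0) {
      int8_t tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) { ops.push_back('M'); --i; --j; }  // col unchanged
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      int8_t tb = tbE[idx];
      --j; --c;
      if (tb == 0) state = 0;
    } else {
      ops.push_back('I');
      int8_t tb = tbF[idx];
      --i; ++c;
      if (tb == 0) state = 0;
    }
  }
  out.score = bscore;
  out.rs = i + 1; out.re = bi; out.gs = j + 1; out.ge = bj;
  // run-length encode reversed ops
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cig += std::to_string(k2 - k);
    cig.push_back(ops[k]);
    k = k2;
  }
  out.cigar = cig;
  return true;
}

// Ungapped X-drop extension around an exact seed; returns best ungapped score.
static int ungapped_seed_score(const std::string& r, const char* g, int gl,
                               int rp, int gp, int k, int match, int mismatch,
                               int xdrop) {
  int score = k * match;
  int cur = 0, best_gain = 0;
  int i = rp + k, j = gp + k;
  while (i < (int) r.size() && j < gl) {
    cur += (r[i] == g[j]) ? match : mismatch;
    if (cur > best_gain) best_gain = cur;
    if (cur < best_gain - xdrop) break;
    ++i; ++j;
  }
  score += best_gain;
  cur = 0; best_gain = 0;
  i = rp - 1; j = gp - 1;
  while (i >= 0 && j >= 0) {
    cur += (r[i] == g[j]) ? match : mismatch;
    if (cur > best_gain) best_gain = cur;
    if (cur < best_gain - xdrop) break;
    --i; --j;
  }
  return score + best_gain;
}

// Map reads against a gene database grouped into classes; report the best hit
// per (read, class) passing the E-value threshold.
// Genes must arrive sorted by (class, gene name): ties on score resolve to the
// earliest gene in that order, '+' strand before '-'.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads,
                        CharacterVector genes, IntegerVector gene_class,
                        NumericVector class_len, double lambda, double K,
                        double evalue_max, int seed_len, int match,
                        int mismatch, int gap_open, int gap_ext, int gate) {
  const int n_reads = reads.size(), n_genes = genes.size();
  const int n_class = class_len.size();
  const uint32_t kmask = (seed_len >= 16) ? 0xFFFFFFFFu : ((1u << (2 * seed_len)) - 1u);
  const size_t ksize = (size_t) kmask + 1;

  // k-mer index over genes
  std::vector<int32_t> head(ksize, -1);
  std::vector<uint64_t> bits(ksize / 64 + 1, 0);
  std::vector<int32_t> nxt, idx_gene, idx_pos;
  std::vector<const char*> gseq(n_genes);
  std::vector<int> glen(n_genes);
  for (int g = 0; g < n_genes; ++g) {
    gseq[g] = CHAR(STRING_ELT(genes, g));
    glen[g] = (int) std::strlen(gseq[g]);
    uint32_t kmer = 0; int valid = 0;
    for (int p = 0; p < glen[g]; ++p) {
      int c = base_code(gseq[g][p]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t) c) & kmask;
      if (++valid >= seed_len) {
        int pos = p - seed_len + 1;
        nxt.push_back(head[kmer]);
        head[kmer] = (int32_t) idx_gene.size();
        idx_gene.push_back(g);
        idx_pos.push_back(pos);
        bits[kmer >> 6] |= (1ull << (kmer & 63));
      }
    }
  }

  std::vector<int> out_read, out_class, out_gene, out_score;
  std::vector<int> out_rs, out_re, out_gs, out_ge;
  std::vector<double> out_ev;
  std::vector<std::string> out_cigar, out_strand;

  // per-gene scratch, stamped by (read, strand) pass id
  std::vector<int> stamp(n_genes, -1), best_ug(n_genes, 0);
  std::vector<int> last_diag(n_genes, 0), last_pos(n_genes, 0);
  std::vector<int> diag_plus(n_genes, 0), diag_minus(n_genes, 0);
  std::vector<int> cand;  // genes passing gate for current read (dedup across strands)
  std::vector<int8_t> cand_strand(n_genes, 0);  // bit1 '+', bit2 '-'
  std::vector<int> cand_stamp(n_genes, -1);
  int pass_id = 0;

  for (int ri = 0; ri < n_reads; ++ri) {
    const char* rs0 = CHAR(STRING_ELT(reads, ri));
    int rl = (int) std::strlen(rs0);
    if (rl < seed_len) continue;
    std::string fwd(rs0, (size_t) rl);
    std::string rev = revcomp_str(rs0, rl);
    cand.clear();
    int read_mark = 2 * ri;
    for (int st = 0; st < 2; ++st) {
      const std::string& r = (st == 0) ? fwd : rev;
      ++pass_id;
      uint32_t kmer = 0; int valid = 0;
      for (int p = 0; p < rl; ++p) {
        int c = base_code(r[p]);
        if (c < 0) {
          if (r[p] != 'N')
            stop("non-DNA character '%c' in read %d", r[p], ri + 1);
          valid = 0; kmer = 0; continue;
        }
        kmer = ((kmer << 2) | (uint32_t) c) & kmask;
        if (++valid < seed_len) continue;
        if (!(bits[kmer >> 6] & (1ull << (kmer & 63)))) continue;
        int rpos = p - seed_len + 1;
        for (int32_t e = head[kmer]; e >= 0; e = nxt[e]) {
          int g = idx_gene[e], gp = idx_pos[e];
          int diag = rpos - gp;
          if (stamp[g] == pass_id) {
            // skip seeds continuing the previous seed on the same diagonal
            if (last_diag[g] == diag && last_pos[g] >= rpos - 1) { last_pos[g] = rpos; continue; }
          } else {
            stamp[g] = pass_id; best_ug[g] = 0; last_diag[g] = diag; last_pos[g] = rpos;
          }
          last_diag[g] = diag; last_pos[g] = rpos;
          int sc = ungapped_seed_score(r, gseq[g], glen[g], rpos, gp, seed_len,
                                       match, mismatch, 12);
          if (sc > best_ug[g]) {
            best_ug[g] = sc;
            if (st == 0) diag_plus[g] = gp - rpos; else diag_minus[g] = gp - rpos;
          }
          if (best_ug[g] >= gate) {
            if (cand_stamp[g] != read_mark) {
              cand_stamp[g] = read_mark; cand_strand[g] = 0; cand.push_back(g);
            }
            cand_strand[g] |= (int8_t) (st == 0 ? 1 : 2);
          }
        }
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());  // gene order == (class, name) order
    // best per class with deterministic ties: gene asc, '+' before '-'
    std::vector<int> best_cls(n_class, -1);
    std::vector<Aln> best_aln(n_class);
    std::vector<int> best_gene(n_class, -1);
    std::vector<char> best_st(n_class, '+');
    for (int g : cand) {
      int cl = gene_class[g];
      for (int st = 0; st < 2; ++st) {
        if (!(cand_strand[g] & (st == 0 ? 1 : 2))) continue;
        const std::string& r = (st == 0) ? fwd : rev;
        Aln a;
        int d = (st == 0) ? diag_plus[g] : diag_minus[g];
        if (!smith_waterman(r, gseq[g], glen[g], d, 12, match, mismatch,
                            gap_open, gap_ext, a))
          continue;
        if (best_cls[cl] < 0 || a.score > best_aln[cl].score) {
          best_cls[cl] = 1; best_aln[cl] = a; best_gene[cl] = g;
          best_st[cl] = (st == 0) ? '+' : '-';
        }
      }
    }
    for (int cl = 0; cl < n_class; ++cl) {
      if (best_cls[cl] < 0) continue;
      const Aln& a = best_aln[cl];
      double ev = K * (double) rl * class_len[cl] * std::exp(-lambda * (double) a.score);
      if (ev > evalue_max) continue;
      out_read.push_back(ri + 1);
      out_class.push_back(cl + 1);
      out_gene.push_back(best_gene[cl] + 1);
      out_score.push_back(a.score);
      out_ev.push_back(ev);
      out_strand.push_back(std::string(1, best_st[cl]));
      out_rs.push_back(a.rs); out_re.push_back(a.re);
      out_gs.push_back(a.gs); out_ge.push_back(a.ge);
      out_cigar.push_back(a.cigar);
    }
  }

  return DataFrame::create(
      _["read"] = out_read, _["class"] = out_class, _["gene"] = out_gene,
      _["strand"] = out_strand, _["score"] = out_score, _["evalue"] = out_ev,
      _["r_start"] = out_rs, _["r_end"] = out_re,
      _["g_start"] = out_gs, _["g_end"] = out_ge, _["cigar"] = out_cigar,
      _["stringsAsFactors"] = false);
}

// Pileup of aligned reads on one gene. Coordinates/cigars follow cpp_map_reads
// conventions: r_start refers to the aligned orientation ('-' hits supply the
// reverse complement). Insertions (I) consume read only; deletions (D) gene only.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(std::string gene, CharacterVector reads,
                         CharacterVector strand, IntegerVector r_start,
                         IntegerVector g_start, CharacterVector cigar) {
  int L = (int) gene.size();
  IntegerMatrix counts(4, L);
  int n = reads.size();
  for (int i = 0; i < n; ++i) {
    const char* s0 = CHAR(STRING_ELT(reads, i));
    int rl = (int) std::strlen(s0);
    std::string r = (CHAR(STRING_ELT(strand, i))[0] == '-') ? revcomp_str(s0, rl)
                                                            : std::string(s0, (size_t) rl);
    const char* cg = CHAR(STRING_ELT(cigar, i));
    int rp = r_start[i] - 1, gp = g_start[i] - 1;
    int num = 0;
    for (const char* p = cg; *p; ++p) {
      if (*p >= '0' && *p <= '9') { num = num * 10 + (*p - '0'); continue; }
      if (*p == 'M') {
        for (int k = 0; k < num; ++k) {
          if (gp < 0 || gp >= L) stop("pileup interval outside gene bounds");
          int c = base_code(r[rp]);
          if (c >= 0) counts(c, gp) += 1;
          ++rp; ++gp;
        }
      } else if (*p == 'I') {
        rp += num;
      } else if (*p == 'D') {
        gp += num;
      } else stop("bad cigar op '%c'", *p);
      num = 0;
    }
  }
  return counts;
}

// Greedy per-base consensus extension of a contig 3' end from candidate reads.
// A read is anchored at the placement minimizing mismatches over an overlap of
// >= min_overlap bases (<= max_mismatch); anchored reads vote for the next base,
// which is appended iff supported by >= min_reads votes at >= agree_ratio majority.
// [[Rcpp::export]]
List cpp_extend_contig(std::string contig, CharacterVector reads, int min_overlap,
                       int max_mismatch, int min_reads, double agree_ratio,
                       int max_ext) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int n = reads.size();
  std::vector<std::string> rs(n);
  std::vector<long> off(n, -1);
  for (int i = 0; i < n; ++i) rs[i] = CHAR(STRING_ELT(reads, i));
  std::vector<int> support;
  std::string reason = "";
  int appended = 0;
  while (appended < max_ext) {
    int L = (int) contig.size();
    // (re)anchor unanchored reads against the current contig end
    for (int i = 0; i < n; ++i) {
      if (off[i] >= 0) continue;
      int rl = (int) rs[i].size();
      if (rl <= min_overlap) continue;
      int best_m = max_mismatch + 1, best_p = -1;
      int plo = std::max(0, L - rl + 1);
      for (int p = L - min_overlap; p >= plo; --p) {
        int ov = L - p;
        int mm = 0;
        for (int k = 0; k < ov; ++k) {
          if (contig[p + k] != rs[i][k] && ++mm > max_mismatch) break;
        }
        if (mm < best_m) { best_m = mm; best_p = p; }
      }
      if (best_p >= 0 && best_m <= max_mismatch) off[i] = best_p;
    }
    // vote on the base at position L
    int cnt[4] = {0, 0, 0, 0}, total = 0;
    for (int i = 0; i < n; ++i) {
      if (off[i] < 0) continue;
      long vi = (long) L - off[i];
      if (vi >= 0 && vi < (long) rs[i].size()) {
        int c = base_code(rs[i][vi]);
        if (c >= 0) { cnt[c] += 1; ++total; }
      }
    }
    if (total == 0) { reason = "no_candidates_at_edge"; break; }
    int top = 0;
    for (int c = 1; c < 4; ++c) if (cnt[c] > cnt[top]) top = c;
    if (cnt[top] < min_reads || (double) cnt[top] / (double) total < agree_ratio) {
      reason = "low_support"; break;
    }
    contig.push_back(B[top]);
    support.push_back(cnt[top]);
    ++appended;
  }
  if (appended >= max_ext) reason = "max_ext";
  return List::create(_["seq"] = contig, _["n_appended"] = appended,
                      _["support"] = IntegerVector(support.begin(), support.end()),
                      _["stop_reason"] = reason);
}
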