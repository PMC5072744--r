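#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Seed-and-extend ungapped read mapper.
//
// Host chromosomes and the provirus are indexed together so every read
// competes across both references; mapping quality is derived from the
// best-vs-second-best score gap and co-optimal placements force mapq 0.
// Extension reports the maximal-scoring contiguous segment (match +1,
// mismatch -3), which yields soft-clipped-style partial alignments for
// chimeric junction reads without gapped alignment.

struct MapIndex {
  std::vector<std::string> names;
  std::string cat;                 // refs concatenated, k 'N's between
  std::vector<int64_t> off;        // start of each ref in cat
  std::vector<int64_t> len;
  int k;
  int max_hits;
  std::unordered_map<uint64_t, std::vector<uint32_t> > kmers;
};

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".mapper_build")]]
SEXP mapper_build(CharacterVector ref_names, CharacterVector ref_seqs,
                  int k, int max_hits) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  MapIndex* mi = new MapIndex();
  mi->k = k;
  mi->max_hits = max_hits;
  int64_t pos = 0;
  for (int i = 0; i < ref_seqs.size(); ++i) {
    std::string s = as<std::string>(ref_seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = toupper(s[j]);
    if ((int64_t)s.size() < k)
      Rf_warning("reference '%s' shorter than k; not indexed",
                 as<std::string>(ref_names[i]).c_str());
    mi->names.push_back(as<std::string>(ref_names[i]));
    mi->off.push_back(pos);
    mi->len.push_back((int64_t)s.size());
    mi->cat += s;
    mi->cat += std::string(k, 'N');
    pos += (int64_t)s.size() + k;
  }
  const uint64_t mask = (k == 31) ? ~0ULL >> 2 : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0;
  int valid = 0;
  for (size_t i = 0; i < mi->cat.size(); ++i) {
    int c = base2code(mi->cat[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      std::vector<uint32_t>& v = mi->kmers[kmer];
      if ((int)v.size() < mi->max_hits)
        v.push_back((uint32_t)(i - k + 1));
    }
  }
  XPtr<MapIndex> xp(mi, true);
  return xp;
}

struct Cand {
  int ref; int64_t start, end; int strand;   // strand +1/-1
  int qstart, qend, matched, mism, score;
};

static void extend_diag(const MapIndex* mi, const std::string& rd,
                        int64_t diag, int ref, int strand, int rlen,
                        std::vector<Cand>& out) {
  int64_t roff = mi->off[ref], rl = mi->len[ref];
  int qlo = (int)std::max((int64_t)0, roff - diag);
  int qhi = (int)std::min((int64_t)rlen, roff + rl - diag);
  if (qhi - qlo < mi->k) return;
  // Kadane over +1 (match) / -3 (mismatch)
  int best = 0, cur = 0, curs = qlo, bs = qlo, be = qlo;
  for (int q = qlo; q < qhi; ++q) {
    int sc = (rd[q] == mi->cat[diag + q]) ? 1 : -3;
    if (cur <= 0) { cur = sc; curs = q; } else cur += sc;
    if (cur > best) { best = cur; bs = curs; be = q + 1; }
  }
  if (best <= 0) return;
  int matched = 0;
  for (int q = bs; q < be; ++q)
    if (rd[q] == mi->cat[diag + q]) ++matched;
  Cand c;
  c.ref = ref; c.strand = strand;
  c.start = diag + bs - roff; c.end = diag + be - roff;
  c.matched = matched; c.mism = (be - bs) - matched;
  c.score = best;
  if (strand > 0) { c.qstart = bs; c.qend = be; }
  else { c.qstart = rlen - be; c.qend = rlen - bs; }  // original read coords
  out.push_back(c);
}

static int find_ref(const MapIndex* mi, int64_t gpos) {
  int lo = 0, hi = (int)mi->off.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (mi->off[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

static void map_one_strand(const MapIndex* mi, const std::string& rd,
                           int strand, int max_cand, int stride,
                           std::vector<Cand>& cands) {
  const int k = mi->k;
  int rlen = (int)rd.size();
  if (rlen < k) return;
  // seed k-mers at `stride` spacing plus the read tail; any exact segment
  // of >= k + stride - 1 bp is guaranteed a seed
  std::vector<std::pair<int64_t, int> > votes;   // (diag, count)
  votes.reserve(8);
  int qpos = 0;
  bool tail_done = false;
  while (true) {
    if (qpos > rlen - k) {
      if (tail_done || rlen - k < 0) break;
      qpos = rlen - k;
      tail_done = true;
    }
    uint64_t kmer = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base2code(rd[qpos + j]);
      if (c < 0) { ok = false; break; }
      kmer = (kmer << 2) | (uint64_t)c;
    }
    if (ok) {
      std::unordered_map<uint64_t, std::vector<uint32_t> >::const_iterator
        it = mi->kmers.find(kmer);
      if (it != mi->kmers.end()) {
        for (size_t j = 0; j < it->second.size(); ++j) {
          int64_t d = (int64_t)it->second[j] - qpos;
          bool found = false;
          for (size_t v = 0; v < votes.size(); ++v)
            if (votes[v].first == d) { votes[v].second++; found = true; break; }
          if (!found && votes.size() < 128) votes.push_back(std::make_pair(d, 1));
        }
      }
    }
    if (tail_done) break;
    qpos += stride;
  }
  if (votes.empty()) return;
  std::vector<std::pair<int, int64_t> > diags;   // (-votes, diag)
  diags.reserve(votes.size());
  for (size_t v = 0; v < votes.size(); ++v)
    diags.push_back(std::make_pair(-votes[v].second, votes[v].first));
  std::sort(diags.begin(), diags.end());
  int n = std::min((int)diags.size(), max_cand);
  for (int i = 0; i < n; ++i) {
    int64_t diag = diags[i].second;
    // a seed on this diagonal lies within one reference (separators kill
    // spanning k-mers); locate the reference via any in-bounds position
    int64_t probe = diag + (int64_t)rd.size() / 2;
    if (probe < 0) probe = diag;
    if (probe >= (int64_t)mi->cat.size()) probe = (int64_t)mi->cat.size() - 1;
    int ref = find_ref(mi, probe);
    extend_diag(mi, rd, diag, ref, strand, (int)rd.size(), cands);
  }
}

// [[Rcpp::export(name = ".mapper_map")]]
List mapper_map(SEXP xp_, CharacterVector reads, int max_cand, int stride) {
  XPtr<MapIndex> xp(xp_);
  const MapIndex* mi = xp.get();
  std::vector<int> o_read, o_ref, o_strand, o_qs, o_qe, o_matched,
    o_mism, o_score, o_mapq, o_ncoopt, o_best;
  std::vector<double> o_start, o_end;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    for (size_t j = 0; j < fwd.size(); ++j) fwd[j] = toupper(fwd[j]);
    std::string rev(fwd.rbegin(), fwd.rend());
    for (size_t j = 0; j < rev.size(); ++j) rev[j] = comp(rev[j]);
    std::vector<Cand> cands;
    map_one_strand(mi, fwd, +1, max_cand, stride, cands);
    map_one_strand(mi, rev, -1, max_cand, stride, cands);
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.score > b.score; });
    // drop duplicate placements (same ref/start/strand)
    std::vector<Cand> uq;
    for (size_t i = 0; i < cands.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < uq.size(); ++j)
        if (uq[j].ref == cands[i].ref && uq[j].strand == cands[i].strand &&
            std::llabs(uq[j].start - cands[i].start) < 5) { dup = true; break; }
      if (!dup) uq.push_back(cands[i]);
    }
    int bestsc = uq[0].score;
    int ncoopt = 0;
    for (size_t i = 0; i < uq.size(); ++i) if (uq[i].score == bestsc) ++ncoopt;
    int second = (uq.size() > 1) ? uq[1].score : 0;
    int mapq = (ncoopt > 1) ? 0 : std::min(60, 2 * (bestsc - second));
    if (mapq < 0) mapq = 0;
    // emit best candidate per reference, best-first, capped
    std::vector<bool> seen(mi->names.size(), false);
    int emitted = 0;
    for (size_t i = 0; i < uq.size() && emitted < 4; ++i) {
      if (seen[uq[i].ref]) continue;
      seen[uq[i].ref] = true;
      const Cand& c = uq[i];
      o_read.push_back(r + 1);
      o_ref.push_back(c.ref + 1);
      o_start.push_back((double)c.start);
      o_end.push_back((double)c.end);
      o_strand.push_back(c.strand);
      o_qs.push_back(c.qstart);
      o_qe.push_back(c.qend);
      o_matched.push_back(c.matched);
      o_mism.push_back(c.mism);
      o_score.push_back(c.score);
      o_mapq.push_back(mapq);
      o_ncoopt.push_back(ncoopt);
      o_best.push_back(i == 0 ? 1 : 0);
      ++emitted;
    }
  }
  return List::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["start"] = wrap(o_start), _["end"] = wrap(o_end),
    _["strand"] = wrap(o_strand), _["qstart"] = wrap(o_qs),
    _["qend"] = wrap(o_qe), _["matched"] = wrap(o_matched),
    _["mismatches"] = wrap(o_mism), _["score"] = wrap(o_score),
    _["mapq"] = wrap(o_mapq), _["n_cooptimal"] = wrap(o_ncoopt),
    _["best"] = wrap(o_best));
}

// [[Rcpp::export(name = ".mapper_refs")]]
CharacterVector mapper_refs(SEXP xp_) {
  XPtr<MapIndex> xp(xp_);
  return wrap(xp.get()->names);
}

// [[Rcpp::export(name = ".mapper_kmer_hits")]]
NumericVector mapper_kmer_hits(SEXP xp_, std::string kmer) {
  XPtr<MapIndex> xp(xp_);
  const MapIndex* mi = xp.get();
  if ((int)kmer.size() != mi->k) stop("query length must equal k");
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base2code(kmer[i]);
    if (c < 0) return NumericVector(0);
    code = (code << 2) | (uint64_t)c;
  }
  std::unordered_map<uint64_t, std::vector<uint32_t> >::const_iterator it =
    mi->kmers.find(code);
  if (it == mi->kmers.end()) return NumericVector(0);
  NumericVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i];
  return out;
}
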