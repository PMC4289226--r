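// Performance-critical inner loops: read-pair overlap scanning, k-mer seeded
// ungapped read mapping, greedy exact-overlap seed extension, and the
// pruning (Felsenstein) likelihood over the 61-codon state space.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Read-pair merging.
//
// r1 and r2rc (mate 2 already reverse-complemented) are scanned for the
// overlap layout of a short-insert library: the insert starts at the start
// of r1 and ends at the end of r2rc.  Candidate insert lengths L imply an
// overlap of len1 + len2 - L (L <= len1 + len2).  For each candidate the
// matches-minus-mismatches score over the overlap is computed; the best
// score wins, ties broken toward the longer overlap (smaller L).
// 'N' never matches and carries quality 0.

// [[Rcpp::export]]
List cpp_merge_pair(std::string r1, std::string r2rc,
                    IntegerVector q1, IntegerVector q2rc,
                    int min_overlap, double max_mismatch_frac) {
  int n1 = (int)r1.size(), n2 = (int)r2rc.size();
  if (n1 == 0 || n2 == 0 || (int)q1.size() != n1 || (int)q2rc.size() != n2)
    return List::create(_["merged"] = false);

  int best_L = -1, best_score = INT_MIN, best_ov = 0, best_mm = 0;
  // Candidate insert length L; r1 position p aligns with r2rc position
  // p - (L - n2).  Overlapping columns span the insert only, so adapter
  // read-through (L < read length) never pollutes the comparison.
  for (int L = n1 + n2 - min_overlap; L >= 1; --L) {
    int s1 = L - n2;
    int start = std::max(0, s1);
    int end = std::min(n1, L);
    int ov = end - start;
    if (ov < min_overlap) continue;
    int match = 0, mm = 0;
    for (int k = 0; k < ov; ++k) {
      char a = r1[start + k], b = r2rc[start - s1 + k];
      if (a == 'N' || b == 'N' || a != b) ++mm; else ++match;
    }
    int score = match - mm;
    if (score > best_score || (score == best_score && ov > best_ov)) {
      best_score = score; best_L = L; best_ov = ov; best_mm = mm;
    }
  }
  if (best_L < 0) return List::create(_["merged"] = false);
  if ((double)best_mm / (double)best_ov > max_mismatch_frac)
    return List::create(_["merged"] = false);

  // Build consensus over the insert (length best_L); positions beyond the
  // insert end in either read are read-through and discarded.
  int L = best_L;
  std::string cons(std::min(L, n1 + n2), 'N');
  IntegerVector cq(cons.size());
  int s1 = L - n2; // r2rc covers insert positions s1..L-1
  int all_n = 0, used = 0;
  for (int p = 0; p < (int)cons.size(); ++p) {
    bool in1 = p < n1;
    bool in2 = p >= s1;
    char a = in1 ? r1[p] : 0;
    char b = in2 ? r2rc[p - s1] : 0;
    int qa = in1 ? q1[p] : -1;
    int qb = in2 ? q2rc[p - s1] : -1;
    if (in1 && a == 'N') qa = 0;
    if (in2 && b == 'N') qb = 0;
    char base; int q;
    if (in1 && in2) {
      ++used;
      if (a == b && a != 'N') { base = a; q = qa + qb; if (q > 93) q = 93; }
      else { if (qa >= qb) { base = a; q = qa - qb; } else { base = b; q = qb - qa; }
             if (base == 'N') q = 0; }
      if (a == 'N' && b == 'N') ++all_n;
    } else if (in1) { base = a; q = qa; }
    else { base = b; q = qb; }
    cons[p] = base; cq[p] = q;
  }
  if (used > 0 && all_n == used) return List::create(_["merged"] = false);
  return List::create(_["merged"] = true, _["sequence"] = cons,
                      _["quality"] = cq, _["overlap"] = best_ov,
                      _["mismatches"] = best_mm, _["insert_length"] = L);
}

// ---------------------------------------------------------------------------
// k-mer seeded ungapped mapping of reads against a small reference set.

struct RefIndex {
  std::vector<std::string> refs;
  int k;
  std::unordered_map<std::string, std::vector<std::pair<int,int>>> pos; // kmer -> (ref, pos)
};

static void index_refs(RefIndex &idx) {
  for (int r = 0; r < (int)idx.refs.size(); ++r) {
    const std::string &s = idx.refs[r];
    if ((int)s.size() < idx.k) continue;
    for (int p = 0; p + idx.k <= (int)s.size(); ++p)
      idx.pos[s.substr(p, idx.k)].push_back(std::make_pair(r, p));
  }
}

static char comp(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G';
               case 'G': return 'C'; case 'T': return 'A'; default: return 'N'; }
}
static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// Evaluate one candidate placement: read aligned to ref with read position 0
// at ref offset 'off' (may be negative / overhang).  Returns identity over
// the overlapping columns and the overlap length.
static void eval_place(const std::string &read, const std::string &ref,
                       int off, int min_span, double &ident, int &span) {
  int start = std::max(0, -off);
  int end = std::min((int)read.size(), (int)ref.size() - off);
  span = end - start;
  ident = -1.0;
  if (span < min_span) return;
  int match = 0;
  for (int i = start; i < end; ++i) if (read[i] == ref[off + i]) ++match;
  ident = (double)match / (double)span;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs,
                   int k, double min_identity, int min_span) {
  RefIndex idx; idx.k = k;
  idx.refs.reserve(refs.size());
  for (int i = 0; i < refs.size(); ++i) idx.refs.push_back(as<std::string>(refs[i]));
  index_refs(idx);

  int n = reads.size();
  List hits(n);            // per read: integer matrix (ref, offset) of ties
  NumericVector identity(n);
  IntegerVector strand(n); // 1 forward, -1 reverse, 0 unmapped

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    double best = -1.0;
    std::vector<int> best_ref, best_off; int best_strand = 0;
    for (int s = 0; s < 2; ++s) {
      const std::string &read = (s == 0) ? fwd : rev;
      if ((int)read.size() < idx.k) continue;
      std::unordered_map<long long, bool> seen;
      // a handful of seed k-mers spread over the read
      for (int sp = 0; sp + idx.k <= (int)read.size(); sp += idx.k) {
        auto it = idx.pos.find(read.substr(sp, idx.k));
        if (it == idx.pos.end()) continue;
        for (auto &rp : it->second) {
          int off = rp.second - sp;
          long long key = (long long)rp.first * 1000003LL + (off + 500);
          if (seen.count(key)) continue;
          seen[key] = true;
          double ident; int span;
          eval_place(read, idx.refs[rp.first], off, min_span, ident, span);
          if (ident < 0) continue;
          if (ident > best + 1e-12) {
            best = ident; best_ref.clear(); best_off.clear();
            best_ref.push_back(rp.first); best_off.push_back(off);
            best_strand = (s == 0) ? 1 : -1;
          } else if (std::abs(ident - best) <= 1e-12) {
            bool dup = false;
            for (size_t u = 0; u < best_ref.size(); ++u)
              if (best_ref[u] == rp.first) { dup = true; break; }
            if (!dup) { best_ref.push_back(rp.first); best_off.push_back(off); }
          }
        }
      }
    }
    if (best >= min_identity && !best_ref.empty()) {
      IntegerMatrix m(best_ref.size(), 2);
      for (size_t u = 0; u < best_ref.size(); ++u) {
        m(u, 0) = best_ref[u] + 1; m(u, 1) = best_off[u];
      }
      hits[i] = m; identity[i] = best; strand[i] = best_strand;
    } else {
      hits[i] = R_NilValue; identity[i] = NA_REAL; strand[i] = 0;
    }
  }
  return List::create(_["hits"] = hits, _["identity"] = identity,
                      _["strand"] = strand);
}

// ---------------------------------------------------------------------------
// Greedy exact-overlap seed extension.

static int max_exact_overlap_right(const std::string &contig,
                                   const std::string &read, int min_overlap) {
  // largest o < read length with read[0..o-1] == contig tail of length o
  int L = (int)contig.size(), R = (int)read.size();
  for (int o = std::min(L, R - 1); o >= min_overlap; --o) {
    if (contig.compare(L - o, o, read, 0, o) == 0) return o;
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_extend_seed(std::string seed, CharacterVector reads,
                     int min_overlap, int max_length) {
  std::vector<std::string> pool;
  pool.reserve(2 * reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    pool.push_back(s);
    pool.push_back(revcomp(s));
  }
  std::string contig = seed;
  bool grew = true;
  int steps = 0;
  while (grew && (int)contig.size() <= max_length) {
    grew = false;
    // right extension
    int best_gain = 0; std::string best_add;
    for (auto &r : pool) {
      int o = max_exact_overlap_right(contig, r, min_overlap);
      if (o > 0) {
        int gain = (int)r.size() - o;
        if (gain > best_gain) { best_gain = gain; best_add = r.substr(o); }
      }
    }
    if (best_gain > 0) { contig += best_add; grew = true; }
    // left extension: work on reverse complement of the contig
    std::string rc = revcomp(contig);
    best_gain = 0; best_add.clear();
    for (auto &r : pool) {
      int o = max_exact_overlap_right(rc, r, min_overlap);
      if (o > 0) {
        int gain = (int)r.size() - o;
        if (gain > best_gain) { best_gain = gain; best_add = r.substr(o); }
      }
    }
    if (best_gain > 0) { rc += best_add; contig = revcomp(rc); grew = true; }
    if (++steps > 100000) break;
  }
  return List::create(_["contig"] = contig, _["steps"] = steps);
}

// ---------------------------------------------------------------------------
// Pruning likelihood over the 61-codon state space.
//
// Inputs follow the ape 'phylo' encoding: edge matrix (parent, child) in
// 1-based node ids with tips 1..ntip, root = ntip + 1.  P is a cube with one
// transition matrix per edge.  tip_states is an ntip x npatterns matrix of
// 0-based codon states (-1 = missing / fully ambiguous).  Returns the
// per-pattern site likelihoods (natural scale with a log scaler per pattern).

// [[Rcpp::export]]
List cpp_prune_site_lik(IntegerMatrix edge, int ntip, arma::cube P,
                        IntegerMatrix tip_states, NumericVector root_freqs) {
  int nstate = root_freqs.size();
  int npat = tip_states.ncol();
  int nnode = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  // partial likelihoods: one nstate x npat matrix per node
  std::vector<arma::mat> part(nnode + 1);
  std::vector<bool> have(nnode + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  // post-order: ape's reorder(phy, "postorder") guarantees children appear
  // before their parent edge; we require the caller to pass a postorder edge
  // matrix.
  for (int e = 0; e < edge.nrow(); ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    arma::mat childL;
    if (child <= ntip) {
      childL.set_size(nstate, npat);
      for (int p = 0; p < npat; ++p) {
        int st = tip_states(child - 1, p);
        if (st < 0) childL.col(p).ones();
        else { childL.col(p).zeros(); childL(st, p) = 1.0; }
      }
    } else {
      childL = part[child];
    }
    arma::mat up = arma::mat(P.slice(e)) * childL; // P is row-stochastic: up(i,p) = sum_j P_ij L_j
    if (!have[parent]) { part[parent] = up; have[parent] = true; }
    else part[parent] %= up;
  }
  int root = ntip + 1;
  arma::mat rootL = part[root];
  // rescale to avoid underflow
  arma::rowvec mx = arma::max(rootL, 0);
  arma::rowvec sitelik(npat);
  arma::vec pi(root_freqs.begin(), nstate, false);
  for (int p = 0; p < npat; ++p) {
    double m = mx(p);
    if (m <= 0) { sitelik(p) = 0; continue; }
    sitelik(p) = arma::dot(pi, rootL.col(p) / m);
    logscale(p) = std::log(m);
  }
  return List::create(_["sitelik"] = NumericVector(sitelik.begin(), sitelik.end()),
                      _["logscale"] = NumericVector(logscale.begin(), logscale.end()));
}

// ---------------------------------------------------------------------------
// Site-class mixture log-likelihood for GY94 codon models.
//
// 'type' encodes the single-step structure of the 61x61 codon space:
// 0 = not a single-nucleotide change; 1 = synonymous transversion;
// 2 = synonymous transition; 3 = nonsynonymous transversion;
// 4 = nonsynonymous transition.  Q is built per site class (omega), scaled
// by the mixture-averaged rate so branch lengths are expected substitutions
// per codon, and the pruning recursion runs over a postorder edge list.

// [[Rcpp::export]]
double cpp_codon_mixture_loglik(IntegerMatrix edge, int ntip,
                                NumericVector el, IntegerMatrix tip_states,
                                NumericVector weights, NumericVector pi,
                                IntegerMatrix type, double kappa,
                                NumericVector omegas, NumericVector props,
                                double scale) {
  const int ns = pi.size();
  const int ncls = omegas.size();
  const int npat = tip_states.ncol();
  const int nedge = edge.nrow();

  arma::vec api(pi.begin(), ns);
  arma::vec sq = arma::sqrt(api);

  // per-class rate matrices and rates
  std::vector<arma::mat> Qs(ncls);
  arma::vec rates(ncls);
  for (int c = 0; c < ncls; ++c) {
    arma::mat Q(ns, ns, arma::fill::zeros);
    for (int i = 0; i < ns; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < ns; ++j) {
        int tp = type(i, j);
        if (tp == 0 || i == j) continue;
        double q = api(j);
        if (tp == 2 || tp == 4) q *= kappa;
        if (tp >= 3) q *= omegas[c];
        Q(i, j) = q; rowsum += q;
      }
      Q(i, i) = -rowsum;
    }
    rates(c) = -arma::dot(api, Q.diag());
    Qs[c] = Q;
  }
  double mean_rate = 0.0;
  for (int c = 0; c < ncls; ++c) mean_rate += props[c] * rates(c);
  if (mean_rate <= 0) return -1e12;

  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  arma::mat mixlik(ncls, npat, arma::fill::zeros);
  arma::mat mixlog(ncls, npat, arma::fill::zeros);

  for (int c = 0; c < ncls; ++c) {
    // symmetrized eigendecomposition
    arma::mat B = Qs[c];
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j)
        B(i, j) *= sq(i) / sq(j);
    B = 0.5 * (B + B.t());
    arma::vec eval; arma::mat evec;
    if (!arma::eig_sym(eval, evec, B)) return -1e12;
    arma::mat right = evec; right.each_col() /= sq;
    arma::mat left = evec.t(); left.each_row() %= sq.t();

    std::vector<arma::mat> part(nnode + 1);
    std::vector<bool> have(nnode + 1, false);
    arma::rowvec logscale(npat, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      int parent = edge(e, 0), child = edge(e, 1);
      double t = el[e] * scale / mean_rate;
      arma::vec ex = arma::exp(eval * t);
      arma::mat P = right * arma::diagmat(ex) * left;
      P.clamp(0.0, arma::datum::inf);
      arma::mat childL;
      if (child <= ntip) {
        childL.set_size(ns, npat);
        for (int p = 0; p < npat; ++p) {
          int st = tip_states(child - 1, p);
          if (st < 0) childL.col(p).ones();
          else { childL.col(p).zeros(); childL(st, p) = 1.0; }
        }
      } else childL = part[child];
      arma::mat up = P * childL;
      if (!have[parent]) { part[parent] = up; have[parent] = true; }
      else part[parent] %= up;
      // rescale occasionally via parent max when values get tiny
      if (child > ntip) part[child].reset();
    }
    int root = ntip + 1;
    arma::mat &rootL = part[root];
    for (int p = 0; p < npat; ++p) {
      double m = rootL.col(p).max();
      if (m <= 0) { mixlik(c, p) = 0; mixlog(c, p) = 0; continue; }
      mixlik(c, p) = arma::dot(api, rootL.col(p) / m);
      mixlog(c, p) = std::log(m);
    }
  }
  double lnL = 0.0;
  for (int p = 0; p < npat; ++p) {
    double m = mixlog.col(p).max();
    double lik = 0.0;
    for (int c = 0; c < ncls; ++c)
      lik += props[c] * mixlik(c, p) * std::exp(mixlog(c, p) - m);
    if (lik <= 0) return -1e12;
    lnL += weights[p] * (std::log(lik) + m);
  }
  return lnL;
}

// Depth accumulation: add coverage of intervals [start, end] (1-based,
// clipped) onto a depth vector.
// [[Rcpp::export]]
NumericVector cpp_accumulate_depth(int len, IntegerVector start, IntegerVector end) {
  NumericVector depth(len);
  for (int i = 0; i < start.size(); ++i) {
    int a = std::max(1, start[i]), b = std::min(len, end[i]);
    for (int p = a; p <= b; ++p) depth[p - 1] += 1.0;
  }
  return depth;
}
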