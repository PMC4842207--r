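#include <Rcpp.h>
using namespace Rcpp;

// Single-locus genealogy under the n-deme structured coalescent with
// stepwise mutation.
//
//   n_copies      gene copies sampled per deme (2 * diploid sample size)
//   n_gene        gene copies per deme (2N); pairwise coalescence rate
//                 within a deme is 1/n_gene per generation
//   mig           backward migration rates: mig(i, j) is the
//                 per-generation probability that a lineage currently in
//                 deme i traces its parent to deme j
//   mu            mutation rate per copy per generation; each mutation
//                 shifts the repeat count by +1 or -1 with equal
//                 probability (unbounded SMM)
//   root_allele   repeat count assigned to the MRCA (an arbitrary offset;
//                 all differentiation statistics are invariant to it)
//   isolation_gap time in generations inserted between forced joins of
//                 lineages that can never coalesce through migration
//                 (isolated demes); large gaps make the joined subtrees
//                 effectively unrelated at the locus
//   max_events    hard cap on coalescence + migration events; exceeding
//                 it aborts with an error (guards near-non-ergodic
//                 migration matrices)
//
// Uses R's RNG, so set.seed() in R makes the draw deterministic.

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(IntegerVector n_copies, double n_gene, NumericMatrix mig,
                   double mu, int root_allele, double isolation_gap,
                   double max_events) {
  const int D = n_copies.size();
  int K = 0;
  for (int d = 0; d < D; ++d) K += n_copies[d];
  if (K < 1) stop("no gene copies sampled");
  if (K == 1) {
    return List::create(_["alleles"] = IntegerVector::create(root_allele),
                        _["tmrca"] = 0.0, _["tree_length"] = 0.0,
                        _["forced_join"] = false);
  }
  const int n_nodes = 2 * K - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> ntime(n_nodes, 0.0);
  std::vector< std::vector<int> > act(D);
  int idx = 0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < n_copies[d]; ++k) act[d].push_back(idx++);

  std::vector<double> out_rate(D, 0.0);
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < D; ++j)
      if (j != d) out_rate[d] += mig(d, j);

  int next_node = K, n_active = K;
  double t = 0.0, events = 0.0;
  bool forced = false;
  std::vector<double> rate(2 * D);

  while (n_active > 1) {
    double tot = 0.0;
    for (int d = 0; d < D; ++d) {
      const double nd = (double)act[d].size();
      rate[2 * d] = 0.5 * nd * (nd - 1.0) / n_gene;
      rate[2 * d + 1] = nd * out_rate[d];
      tot += rate[2 * d] + rate[2 * d + 1];
    }
    if (tot <= 0.0) { forced = true; break; }
    if (++events > max_events)
      stop("coalescent event cap exceeded; is the migration matrix (nearly) non-ergodic?");
    t += R::exp_rand() / tot;

    double u = unif_rand() * tot;
    int cat = 2 * D - 1;
    for (int c = 0; c < 2 * D; ++c) {
      if (u < rate[c]) { cat = c; break; }
      u -= rate[c];
    }
    // numeric slack can leave cat pointing at a zero-rate category; walk
    // back to the last positive one
    while (cat > 0 && rate[cat] <= 0.0) --cat;
    const int d = cat / 2;
    std::vector<int> &ad = act[d];
    const int nd = (int)ad.size();

    if (cat % 2 == 0) {            // coalescence within deme d
      int i1 = (int)(unif_rand() * nd); if (i1 >= nd) i1 = nd - 1;
      int i2 = (int)(unif_rand() * (nd - 1)); if (i2 >= nd - 1) i2 = nd - 2;
      if (i2 >= i1) ++i2;
      const int a = ad[i1], b = ad[i2];
      const int p = next_node++;
      parent[a] = p; parent[b] = p; ntime[p] = t;
      // remove both lineages (higher slot first), then add the parent
      const int hi = (i1 > i2) ? i1 : i2, lo = (i1 > i2) ? i2 : i1;
      ad[hi] = ad.back(); ad.pop_back();
      ad[lo] = ad.back(); ad.pop_back();
      ad.push_back(p);
      --n_active;
    } else {                       // migration out of deme d
      int i1 = (int)(unif_rand() * nd); if (i1 >= nd) i1 = nd - 1;
      double v = unif_rand() * out_rate[d];
      int dest = -1;
      for (int j = 0; j < D; ++j) {
        if (j == d) continue;
        if (v < mig(d, j)) { dest = j; break; }
        v -= mig(d, j);
      }
      if (dest < 0) { for (int j = D - 1; j >= 0; --j) if (j != d && mig(d, j) > 0) { dest = j; break; } }
      const int node = ad[i1];
      ad[i1] = ad.back(); ad.pop_back();
      act[dest].push_back(node);
    }
  }

  if (forced && n_active > 1) {
    // isolated subtrees: join them at deeply separated times
    std::vector<int> rem;
    for (int d = 0; d < D; ++d)
      for (size_t k = 0; k < act[d].size(); ++k) rem.push_back(act[d][k]);
    int cur = rem[0];
    for (size_t k = 1; k < rem.size(); ++k) {
      t += isolation_gap;
      const int p = next_node++;
      parent[cur] = p; parent[rem[k]] = p; ntime[p] = t;
      cur = p;
    }
  }

  // drop stepwise mutations along branches, root first (parents always
  // have larger node index than their children)
  std::vector<int> allele(n_nodes);
  allele[n_nodes - 1] = root_allele;
  double tree_len = 0.0;
  for (int i = n_nodes - 2; i >= 0; --i) {
    const double len = ntime[parent[i]] - ntime[i];
    tree_len += len;
    const int k = (int)R::rpois(mu * len);
    const int up = (k > 0) ? (int)R::rbinom((double)k, 0.5) : 0;
    allele[i] = allele[parent[i]] + 2 * up - k;
  }

  IntegerVector tips(K);
  for (int i = 0; i < K; ++i) tips[i] = allele[i];
  return List::create(_["alleles"] = tips, _["tmrca"] = t,
                      _["tree_length"] = tree_len,
                      _["forced_join"] = forced);
}
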