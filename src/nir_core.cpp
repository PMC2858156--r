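#include <RcppArmadillo.h>

#include <algorithm>
#include <set>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve the normal equations restricted to the 0-based index set `idx` by a
// Cholesky factorization of the subset Gram matrix.  Returns false when the
// submatrix is not positive definite (linearly dependent regressors); the
// caller treats that as a singular candidate, never as an error.
static bool chol_subset_solve(const arma::mat& G, const arma::vec& xty,
                              double yty, const arma::uvec& idx,
                              arma::vec& coef, double& rss) {
  arma::mat Gs = G.submat(idx, idx);
  arma::vec rhs = xty.elem(idx);
  arma::mat R;
  if (!arma::chol(R, Gs)) return false;
  if (!R.is_finite()) return false;
  coef = arma::solve(arma::trimatu(R),
                     arma::solve(arma::trimatl(R.t()), rhs));
  if (!coef.is_finite()) return false;
  // rss = y'y - b'X y: algebraic form, never re-touches the data matrix
  rss = yty - arma::dot(coef, rhs);
  if (rss < 0.0) rss = 0.0;
  return true;
}

// [[Rcpp::export]]
List cpp_subset_solve(const arma::mat& G, const arma::vec& xty, double yty,
                      const IntegerVector& subset0) {
  arma::uvec idx(subset0.size());
  for (int t = 0; t < subset0.size(); ++t)
    idx[t] = static_cast<arma::uword>(subset0[t]);
  arma::vec coef;
  double rss = 0.0;
  if (!chol_subset_solve(G, xty, yty, idx, coef, rss))
    return List::create(_["singular"] = true);
  return List::create(
      _["singular"] = false,
      _["coefficients"] = NumericVector(coef.begin(), coef.end()),
      _["rss"] = rss);
}

struct BeamCand {
  std::vector<int> s;  // sorted 0-based regressor indices
  double rss;
};

static bool cand_less(const BeamCand& a, const BeamCand& b) {
  if (a.rss != b.rss) return a.rss < b.rss;
  return a.s < b.s;  // lexicographic tie-break for determinism
}

// Greedy forward selection with a beam of `beam_width` candidate sets.
// Step 1 scores every single regressor; step s extends every surviving set
// with every unused candidate, deduplicates identical sets, scores each and
// keeps the best beam_width.  Singular candidates are dropped from the beam.
// n_evals counts every deduplicated candidate evaluation (including singular
// attempts).
// [[Rcpp::export]]
List cpp_greedy_gene(const arma::mat& G, const arma::vec& xty, double yty,
                     const IntegerVector& candidates0, int k, int beam_width) {
  double n_eval = 0;
  std::vector<int> cand(candidates0.begin(), candidates0.end());
  std::sort(cand.begin(), cand.end());
  std::vector<BeamCand> beam;

  {  // step 1: all single-variable regressions
    std::vector<BeamCand> pool;
    arma::vec coef;
    double rss;
    for (int c : cand) {
      n_eval += 1;
      arma::uvec idx(1);
      idx[0] = static_cast<arma::uword>(c);
      if (chol_subset_solve(G, xty, yty, idx, coef, rss))
        pool.push_back(BeamCand{std::vector<int>(1, c), rss});
    }
    std::sort(pool.begin(), pool.end(), cand_less);
    if (static_cast<int>(pool.size()) > beam_width) pool.resize(beam_width);
    beam = pool;
  }

  for (int step = 2; step <= k && !beam.empty(); ++step) {
    std::set<std::vector<int> > seen;
    std::vector<BeamCand> pool;
    arma::vec coef;
    double rss;
    for (const BeamCand& b : beam) {
      for (int c : cand) {
        if (std::binary_search(b.s.begin(), b.s.end(), c)) continue;
        std::vector<int> ns(b.s);
        ns.insert(std::upper_bound(ns.begin(), ns.end(), c), c);
        if (!seen.insert(ns).second) continue;  // same set from another parent
        n_eval += 1;
        arma::uvec idx(ns.size());
        for (size_t t = 0; t < ns.size(); ++t)
          idx[t] = static_cast<arma::uword>(ns[t]);
        if (chol_subset_solve(G, xty, yty, idx, coef, rss))
          pool.push_back(BeamCand{ns, rss});
      }
    }
    std::sort(pool.begin(), pool.end(), cand_less);
    if (static_cast<int>(pool.size()) > beam_width) pool.resize(beam_width);
    beam = pool;
  }

  if (beam.empty() || static_cast<int>(beam[0].s.size()) != k)
    return List::create(_["failed"] = true, _["n_evals"] = n_eval);

  // Final pick: minimal rss; rss values equal to within 1e-12 relative are
  // tied and resolved toward the lexicographically smallest subset so the
  // result cannot depend on evaluation order or bit-level jitter.
  double best = beam[0].rss;
  double tol = 1e-12 * std::max(1.0, std::max(best, yty));
  size_t pick = 0;
  for (size_t i = 1; i < beam.size(); ++i) {
    if (beam[i].rss <= best + tol && beam[i].s < beam[pick].s) pick = i;
  }
  arma::uvec idx(beam[pick].s.size());
  IntegerVector subset1(beam[pick].s.size());
  for (size_t t = 0; t < beam[pick].s.size(); ++t) {
    idx[t] = static_cast<arma::uword>(beam[pick].s[t]);
    subset1[t] = beam[pick].s[t] + 1;  // back to 1-based
  }
  arma::vec coef;
  double rss;
  chol_subset_solve(G, xty, yty, idx, coef, rss);
  return List::create(
      _["failed"] = false, _["subset"] = subset1,
      _["coefficients"] = NumericVector(coef.begin(), coef.end()),
      _["rss"] = rss, _["n_evals"] = n_eval);
}
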