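# Reduced-representation simulations for statistical calibration of the
# group-comparison stage. They draw FNC matrices straight from the synthetic
# generator's factor model (no volumes, no training) so hundreds of
# repetitions stay cheap.

#' Power of the node-strength comparison under an injected FNC effect
#'
#' For each simulation seed: draw a cohort-level factor-loading template,
#' estimate the between-subject noise sd of node strength from a pilot group
#' of unaffected matrices, inject an additive correlation shift on the effect
#' nodes' incident edges sized so the expected strength difference equals
#' `effect_multiple` times that sd, then test a top-10-style family of nodes
#' (the effect nodes plus the first non-effect nodes) with Mann-Whitney and
#' Benjamini-Hochberg correction within the family. A seed counts as a
#' success when every injected node is significant after FDR.
#'
#' @param n_seeds number of simulation repetitions.
#' @param n_per_group subjects per group.
#' @param effect_nodes indices of injected nodes.
#' @param effect_multiple effect size in units of the strength noise sd.
#' @param n_nodes FNC matrix size.
#' @param fnc_noise factor-loading noise sd (as in the generator).
#' @param n_tests size of the tested family.
#' @param alpha significance level on adjusted p-values.
#' @param seed base seed.
#' @return list with `success_rate`, `per_seed` logical vector and the
#'   per-seed `delta` used.
#' @export
simulate_fnc_power <- function(n_seeds = 20, n_per_group = 40,
                               effect_nodes = 1:3, effect_multiple = 3,
                               n_nodes = 53, fnc_noise = 0.1, n_tests = 10,
                               alpha = 0.05, seed = 1L) {
  q <- 4L
  family <- c(effect_nodes,
              setdiff(seq_len(n_nodes), effect_nodes)[seq_len(n_tests - length(effect_nodes))])
  runs <- lapply(seq_len(n_seeds), function(s) {
    with_seed(seed + 104729L * s, {
      B0 <- matrix(stats::rnorm(n_nodes * q, sd = 0.5), n_nodes, q)
      pilot <- vapply(seq_len(n_per_group), function(i)
        node_strength(sample_fnc(B0, fnc_noise)), numeric(n_nodes))
      sd_strength <- mean(apply(pilot, 1, stats::sd))
      delta <- effect_multiple * sd_strength / (n_nodes - 1)
      neg <- vapply(seq_len(n_per_group), function(i)
        node_strength(sample_fnc(B0, fnc_noise)), numeric(n_nodes))
      pos <- vapply(seq_len(n_per_group), function(i)
        node_strength(sample_fnc(B0, fnc_noise, effect_nodes, delta)), numeric(n_nodes))
      p <- vapply(family, function(nd) mann_whitney(neg[nd, ], pos[nd, ])$p, numeric(1))
      p_fdr <- fdr_bh(p)
      list(ok = all(p_fdr[seq_along(effect_nodes)] < alpha), delta = delta)
    })
  })
  per_seed <- vapply(runs, `[[`, logical(1), "ok")
  list(success_rate = mean(per_seed), per_seed = per_seed,
       delta = vapply(runs, `[[`, numeric(1), "delta"))
}

#' Type-I calibration of the group comparison under the null
#'
#' Repeatedly draws two groups of FNC matrices with no injected effect,
#' computes node strengths for a family of nodes, applies Mann-Whitney with
#' Benjamini-Hochberg correction within the family, and records whether the
#' whole table is non-significant at `alpha`. Group sizes default to the exact
#' Mann-Whitney regime.
#'
#' @param n_sims number of null simulations.
#' @param n_per_group subjects per group.
#' @param n_tests family size.
#' @param n_nodes FNC matrix size.
#' @param fnc_noise factor-loading noise sd.
#' @param alpha significance level on adjusted p-values.
#' @param seed base seed.
#' @return list with `all_ns_rate` (proportion of simulations with zero
#'   rejections) and `n_rejections` per simulation.
#' @export
simulate_null_calibration <- function(n_sims = 500, n_per_group = 10,
                                      n_tests = 10, n_nodes = 53,
                                      fnc_noise = 0.1, alpha = 0.05, seed = 1L) {
  q <- 4L
  nrej <- vapply(seq_len(n_sims), function(s) {
    with_seed(seed + 15485863L + s, {
      B0 <- matrix(stats::rnorm(n_nodes * q, sd = 0.5), n_nodes, q)
      g1 <- vapply(seq_len(n_per_group), function(i)
        node_strength(sample_fnc(B0, fnc_noise)), numeric(n_nodes))
      g2 <- vapply(seq_len(n_per_group), function(i)
        node_strength(sample_fnc(B0, fnc_noise)), numeric(n_nodes))
      p <- vapply(seq_len(n_tests), function(nd)
        mann_whitney(g1[nd, ], g2[nd, ])$p, numeric(1))
      sum(fdr_bh(p) < alpha)
    })
  }, numeric(1))
  list(all_ns_rate = mean(nrej == 0L), n_rejections = as.integer(nrej))
}
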