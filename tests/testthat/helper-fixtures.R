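# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from stored data.

# small symmetric FNC-like correlation matrix
toy_fnc <- function(n = 5, seed = 1) {
  B <- amynet:::with_seed(seed, matrix(rnorm(n * 3, sd = 0.5), n, 3))
  R <- stats::cov2cor(tcrossprod(B) + diag(n))
  connectivity_matrix(R, "FNC")
}

# small symmetric SC-like count matrix
toy_sc <- function(n = 6, seed = 1, lambda = 8) {
  S <- amynet:::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::rpois(n * (n - 1) / 2, lambda)
    m + t(m)
  })
  connectivity_matrix(S, "SC")
}

# a small model configuration that exercises every branch quickly
tiny_config <- function(...) {
  model_config(grid_extents = c(8, 8, 8), n_fnc_nodes = 5, n_sc_nodes = 6,
               dense_smri = c(12, 10, 8), latent_dim = 7, gcn_hidden = 3,
               cheb_hidden = 3, fusion_hidden = c(9, 4), ...)
}

tiny_input <- function(config, seed = 1) {
  amynet:::with_seed(seed, {
    vol <- array(runif(prod(config$grid_extents)), config$grid_extents)
    fnc <- toy_fnc(config$n_fnc_nodes, seed = seed)
    sc <- toy_sc(config$n_sc_nodes, seed = seed)
    prepare_subject_input(vol, fnc, sc, config)
  })
}

# In-memory cohort for trainer/explain unit tests: an fMRI-only problem where
# the POS group has a node-strength shift, so it is easily separable. Built
# directly as a cohort_data structure (no files involved).
tiny_fmri_cohort <- function(n_per_group = 8, n_nodes = 5, delta = 0.6, seed = 1) {
  config <- model_config(n_fnc_nodes = n_nodes, gcn_hidden = 3,
                         latent_dim = 7, fusion_hidden = c(9, 4),
                         modality = "fmri")
  subjects <- list()
  amynet:::with_seed(seed, {
    B0 <- matrix(rnorm(n_nodes * 3, sd = 0.5), n_nodes, 3)
    for (i in seq_len(2 * n_per_group)) {
      label <- if (i <= n_per_group) "NEG" else "POS"
      R <- amynet:::sample_fnc(B0, 0.05,
                               effect_nodes = if (label == "POS") 1:2 else integer(0),
                               delta = delta)
      cm <- connectivity_matrix(R, "FNC")
      id <- sprintf("T%03d", i)
      subjects[[id]] <- list(id = id, label = label,
                             input = prepare_subject_input(fnc = cm, config = config),
                             fnc = cm, sc = NULL, vol = NULL)
    }
  })
  labels <- vapply(subjects, `[[`, character(1), "label")
  structure(subjects, labels = labels, config = config, class = "cohort_data")
}

# generate a small on-disk cohort once per session and reuse it
small_cohort_spec <- function(...) {
  synthetic_cohort_spec(n_per_subgroup = c(2, 2, 2, 2, 2, 2),
                        grid_extents = c(16, 16, 16), n_regions = 8,
                        noise_sd_gm = 0.03, seed = 7, ...)
}

.small_cohort_cache <- new.env()
small_cohort <- function() {
  if (is.null(.small_cohort_cache$res)) {
    dir <- file.path(tempdir(), "amynet-small-cohort")
    .small_cohort_cache$res <- generate_cohort(small_cohort_spec(), dir)
  }
  .small_cohort_cache$res
}

# exhaustive shortest-path enumeration oracle for small graphs: edge length
# = 1/weight, ordered-pair normalisation by (n-1)(n-2)
brute_betweenness <- function(A) {
  n <- nrow(A)
  paths_between <- function(s, t) {
    out <- list()
    rec <- function(node, visited, len) {
      if (node == t) { out[[length(out) + 1]] <<- list(v = visited, len = len); return() }
      for (nb in seq_len(n)) {
        if (A[node, nb] > 0 && !(nb %in% visited))
          rec(nb, c(visited, nb), len + 1 / A[node, nb])
      }
    }
    rec(s, s, 0)
    out
  }
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    short <- ps[lens <= min(lens) + 1e-12]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(p) v %in% p$v, logical(1)))
      b[v] <- b[v] + through / length(short)
    }
  }
  b / ((n - 1) * (n - 2))
}

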