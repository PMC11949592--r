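# Graph summary metrics and the two-group statistics.

test_that("node strength is the signed row sum without the diagonal", {
  R <- matrix(0.3, 3, 3); diag(R) <- 1
  expect_equal(unname(node_strength(connectivity_matrix(R, "FNC"))), rep(0.6, 3))
  mix <- diag(3)
  mix[1, 2] <- mix[2, 1] <- 0.5
  mix[1, 3] <- mix[3, 1] <- -0.5
  s <- node_strength(connectivity_matrix(mix, "FNC"))
  expect_equal(unname(s[1]), 0)     # signed cancellation
  expect_equal(unname(node_strength(connectivity_matrix(mix, "FNC"),
                                    absolute = TRUE)[1]), 1)
  m6 <- toy_fnc(6, seed = 2)
  oracle <- rowSums(m6$values) - diag(m6$values)
  expect_lt(max(abs(node_strength(m6) - oracle)), 1e-12)
  # permutation equivariance
  perm <- c(3, 1, 2, 6, 4, 5)
  sp <- node_strength(connectivity_matrix(m6$values[perm, perm], "FNC"))
  expect_equal(unname(sp), unname(node_strength(m6)[perm]), tolerance = 1e-12)
})

test_that("betweenness matches closed forms on path and star graphs", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 5
  b <- betweenness_centrality(connectivity_matrix(path, "SC"))
  expect_equal(unname(b), c(0, 1, 0))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 3
  bs <- betweenness_centrality(connectivity_matrix(star, "SC"))
  expect_equal(unname(bs), c(1, 0, 0, 0, 0))
  compl <- matrix(2, 4, 4); diag(compl) <- 0
  expect_equal(unname(betweenness_centrality(connectivity_matrix(compl, "SC"))),
               rep(0, 4))
  expect_error(betweenness_centrality(connectivity_matrix(matrix(0, 3, 3), "SC")),
               "all-zero")
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  for (s in 1:50) {
    n <- 3 + (s %% 4)
    A <- amynet:::with_seed(s + 500, {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- rpois(n * (n - 1) / 2, 3) * (runif(n * (n - 1) / 2) > 0.25)
      m + t(m)
    })
    if (all(A == 0)) next
    b <- betweenness_centrality(connectivity_matrix(A, "SC"))
    expect_lt(max(abs(b - brute_betweenness(A))), 1e-10)
  }
})

test_that("Mann-Whitney uses the exact distribution where applicable", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)   # 2/choose(6,3)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1.0)
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.0, 4.4, 0.7, 6.6)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p matches full enumeration up to (4,4)", {
  exact_oracle <- function(x, y) {
    pooled <- c(x, y)
    m <- length(x)
    U_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    combos <- utils::combn(length(pooled), m)
    Us <- apply(combos, 2, function(ix) {
      xs <- pooled[ix]; ys <- pooled[-ix]
      sum(outer(xs, ys, ">"))
    })
    mu <- m * (length(y)) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
  }
  set.seed(77)
  for (i in 1:12) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    x <- round(runif(m, 0, 100), 3)
    y <- round(runif(n, 0, 100), 3)
    expect_equal(mann_whitney(x, y)$p, exact_oracle(x, y), tolerance = 1e-12,
                 label = sprintf("sizes (%d,%d)", m, n))
  }
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- fdr_bh(p)
    # independent step-up oracle: p * m / rank with cumulative minimum
    m <- length(p)
    o <- order(p)
    stepup <- p[o] * m / seq_len(m)
    stepup <- rev(cummin(rev(stepup)))
    oracle <- pmin(stepup[order(o)], 1)
    expect_equal(adj, oracle, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("feature extraction matches direct computation on a toy cohort", {
  data <- tiny_fmri_cohort(n_per_group = 2)
  feats <- extract_features(data, c("n01", "n03"), "fmri")
  expect_equal(nrow(feats), 8)   # 4 subjects x 2 regions
  for (r in seq_len(nrow(feats))) {
    s <- data[[feats$subject_id[r]]]
    expect_equal(feats$value[r],
                 unname(node_strength(s$fnc)[feats$region[r]]), tolerance = 1e-12)
  }
  expect_error(extract_features(data, "bogus", "fmri"), "unknown region")
  # constant volume -> every ROI mean equals the constant
  grid <- array(rep(1:2, each = 32), c(4, 4, 4))
  at <- atlas_partition(grid, c("a", "b"))
  data2 <- data
  data2[[1]]$vol <- array(0.42, c(4, 4, 4))
  f2 <- extract_features(data2, c("a", "b"), "smri", atlas = at,
                         ids = names(data2)[1])
  expect_equal(f2$value, c(0.42, 0.42))
})

test_that("group comparison derives directions from medians and flags trends", {
  set.seed(42)
  feats <- do.call(rbind, lapply(1:3, function(r) {
    shift <- c(3, 0, 0)[r]
    data.frame(subject_id = sprintf("s%02d", 1:24),
               group = rep(c("NEG", "POS"), each = 12),
               modality = "fmri", region = paste0("reg", r),
               value = c(rnorm(12), rnorm(12) + shift))
  }))
  tab <- compare_groups(feats, alpha = 0.05)
  r1 <- tab[tab$region == "reg1", ]
  expect_equal(r1$direction, "NEG < POS")
  expect_true(r1$p_fdr >= r1$p_raw)
  # significant rows always agree with the sign of the median difference
  sig <- tab[tab$direction != "n.s.", ]
  for (i in seq_len(nrow(sig))) {
    fr <- feats[feats$region == sig$region[i], ]
    md <- median(fr$value[fr$group == "NEG"]) - median(fr$value[fr$group == "POS"])
    expect_equal(sig$direction[i], if (md > 0) "NEG > POS" else "NEG < POS")
  }
  f <- tempfile(fileext = ".tsv")
  write_stats_table(tab, f)
  expect_equal(nrow(utils::read.delim(f)), 3)
})

test_that("an injected single-region effect is detected after FDR across seeds", {
  pw <- simulate_fnc_power(n_seeds = 10, n_per_group = 40, effect_nodes = 1,
                           effect_multiple = 3, seed = 2)
  expect_gte(pw$success_rate, 0.9)
})
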