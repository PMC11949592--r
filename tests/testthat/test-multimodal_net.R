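# Architecture contracts: latent sizes, branch behaviour, spectral filtering,
# fusion, and deterministic initialisation.

test_that("default architecture produces 100-feature latents and 300 fused", {
  cfg <- model_config()
  st <- init_model(cfg, seed = 1)
  expect_equal(cfg$fused_dim, 300)
  vol <- array(runif(prod(cfg$grid_extents)), cfg$grid_extents)
  l_s <- smri_branch_forward(st, vol)
  l_f <- fmri_branch_forward(st, fnc_to_graph(toy_fnc(53, seed = 1)))
  l_d <- dmri_branch_forward(st, sc_to_graph(toy_sc(84, seed = 1)))
  expect_length(l_s, 100)
  expect_length(l_f, 100)
  expect_length(l_d, 100)
  out <- fuse_and_classify(st, l_s, l_f, l_d)
  expect_length(out$fused, 300)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_error(fuse_and_classify(st, l_s[1:50], l_f, l_d), "latent length")
})

test_that("zero volume with zero biases yields a zero sMRI latent", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 2)   # biases are zero at init
  suppressWarnings(
    expect_equal(smri_branch_forward(st, array(0, cfg$grid_extents)),
                 rep(0, cfg$latent_dim)))
  expect_error(smri_branch_forward(st, array(0, c(4, 4, 4))), "grid")
})

test_that("conv+ReLU+maxpool stack is positively homogeneous", {
  # nonnegative input, nonnegative weights: doubling the input doubles the
  # pre-dense activations (conv is linear, ReLU and max commute with positive
  # scaling)
  x <- array(runif(6^3), c(6, 6, 6, 1))
  W1 <- abs(amynet:::with_seed(3, matrix(rnorm(27 * 2), 27, 2)))
  W2 <- abs(amynet:::with_seed(4, matrix(rnorm(27 * 2 * 2), 54, 2)))
  run <- function(x) {
    a1 <- amynet:::relu(amynet:::conv3d_fwd(x, W1, c(0, 0))$y)
    a2 <- amynet:::relu(amynet:::conv3d_fwd(a1, W2, c(0, 0))$y)
    amynet:::maxpool_fwd(a2)$y
  }
  y1 <- run(x)
  y2 <- run(2 * x)
  expect_lt(max(abs(y2 - 2 * y1)), 1e-10)
})

test_that("an edgeless FNC graph gives identical node embeddings", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 5)
  A0 <- matrix(0, cfg$n_fnc_nodes, cfg$n_fnc_nodes)
  fw <- amynet:::fmri_fwd(st$par, cfg, A0)
  # with unit features and no mixing every node row equals the hand-computed
  # single-node update
  h1_single <- amynet:::relu(drop(st$par[["fmri.gc1.Wself"]]) * 1 + st$par[["fmri.gc1.b"]])
  for (i in seq_len(cfg$n_fnc_nodes))
    expect_equal(unname(fw$H1[i, ]), unname(h1_single), tolerance = 1e-12)
  z2_single <- drop(h1_single %*% st$par[["fmri.gc2.Wself"]]) + st$par[["fmri.gc2.b"]]
  h2_single <- amynet:::relu(z2_single)
  flat_oracle <- as.vector(matrix(h2_single, cfg$n_fnc_nodes,
                                  cfg$gcn_hidden, byrow = TRUE))
  latent_oracle <- drop(crossprod(st$par[["fmri.dense.W"]], flat_oracle)) +
    st$par[["fmri.dense.b"]]
  expect_equal(unname(fw$latent), unname(latent_oracle), tolerance = 1e-12)
})

test_that("the graph readout is node-order aware", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 6)
  A <- toy_fnc(cfg$n_fnc_nodes, seed = 7)$values
  diag(A) <- 0
  perm <- c(2, 1, 3, 5, 4)
  l1 <- amynet:::fmri_fwd(st$par, cfg, A)$latent
  l2 <- amynet:::fmri_fwd(st$par, cfg, A[perm, perm])$latent
  expect_gt(max(abs(l1 - l2)), 1e-8)
})

test_that("Chebyshev filtering matches an eigendecomposition oracle", {
  for (s in 1:6) {
    n <- sample(3:6, 1)
    A <- amynet:::with_seed(s, {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- rpois(n * (n - 1) / 2, 4)
      m + t(m)
    })
    L <- amynet:::sym_laplacian(A)
    eig <- eigen(L, symmetric = TRUE)
    lam_max <- max(eig$values)
    # package lambda_max by power iteration agrees with eigen
    expect_lt(abs(amynet:::power_lambda_max(L) - lam_max), 1e-4 * max(1, lam_max))
    Lt_oracle <- 2 * L / lam_max - diag(n)
    # spectral oracle: T_k(Lt) = V T_k(Lambda) V' with scalar Chebyshev
    eo <- eigen(Lt_oracle, symmetric = TRUE)
    chebT <- function(k, x) cos(k * acos(pmin(pmax(x, -1), 1)))
    H <- matrix(1, n, 1)
    W <- array(amynet:::with_seed(s + 100, rnorm(1 * 2 * 3)), c(1, 2, 3))
    b <- c(0.1, -0.2)
    Z_oracle <- matrix(0, n, 2)
    for (k in 0:2) {
      Tk <- eo$vectors %*% (chebT(k, eo$values) * t(eo$vectors))
      Z_oracle <- Z_oracle + (Tk %*% H) %*% matrix(W[, , k + 1], 1, 2)
    }
    Z_oracle <- Z_oracle + rep(b, each = n)
    Tk_pkg <- amynet:::cheb_polynomials(amynet:::scaled_laplacian(A, tol = 1e-12), 3)
    Z_pkg <- amynet:::cheb_fwd(H, Tk_pkg, W, b)
    expect_lt(max(abs(Z_pkg - Z_oracle)), 1e-8)
  }
})

test_that("a 2-node toy graph matches the hand-derived Chebyshev recursion", {
  A <- matrix(c(0, 3, 3, 0), 2)
  # normalised Laplacian of a single weighted edge: [[1,-1],[-1,1]]
  L <- amynet:::sym_laplacian(A)
  expect_lt(max(abs(L - matrix(c(1, -1, -1, 1), 2))), 1e-12)
  # lambda_max = 2, so Ltilde = L - I = [[0,-1],[-1,0]]
  Lt <- amynet:::scaled_laplacian(A)
  expect_lt(max(abs(Lt - matrix(c(0, -1, -1, 0), 2))), 1e-6)
  Tk <- amynet:::cheb_polynomials(Lt, 3)
  # T2 = 2 Lt^2 - I = I for this graph
  expect_lt(max(abs(Tk[[3]] - diag(2))), 1e-6)
  W <- array(c(0.5, 1.25, -2), c(1, 1, 3))
  H <- matrix(1, 2, 1)
  z <- amynet:::cheb_fwd(H, Tk, W, 0)
  # hand computation: 0.5*T0*1 + 1.25*T1*1 - 2*T2*1 per node
  expect_equal(as.vector(z), c(0.5 + 1.25 * (-1) - 2,
                               0.5 + 1.25 * (-1) - 2), tolerance = 1e-10)
})

test_that("K = 1 Chebyshev reduces to a dense map of the node features", {
  cfg <- tiny_config(cheb_k = 1)
  st <- init_model(cfg, seed = 8)
  g <- sc_to_graph(toy_sc(cfg$n_sc_nodes, seed = 9))
  fw <- dmri_branch_forward(st, g)
  # T0 = I: first layer is feature-wise affine, independent of the graph
  W1 <- matrix(st$par[["dmri.cheb1.W"]][, , 1], 1, cfg$cheb_hidden)
  h1 <- amynet:::relu(matrix(1, cfg$n_sc_nodes, 1) %*% W1 +
                        rep(st$par[["dmri.cheb1.b"]], each = cfg$n_sc_nodes))
  W2 <- matrix(st$par[["dmri.cheb2.W"]][, , 1], cfg$cheb_hidden, cfg$cheb_hidden)
  h2 <- amynet:::relu(h1 %*% W2 + rep(st$par[["dmri.cheb2.b"]], each = cfg$n_sc_nodes))
  oracle <- drop(crossprod(st$par[["dmri.dense.W"]], as.vector(h2))) +
    st$par[["dmri.dense.b"]]
  expect_equal(unname(fw), unname(oracle), tolerance = 1e-10)
  g2 <- sc_to_graph(toy_sc(cfg$n_sc_nodes, seed = 10))
  expect_equal(dmri_branch_forward(st, g2), fw, tolerance = 1e-12)
})

test_that("initialisation is deterministic and reports the layer plan", {
  cfg <- tiny_config()
  s1 <- init_model(cfg, seed = 42)
  s2 <- init_model(cfg, seed = 42)
  expect_identical(s1$par, s2$par)
  s3 <- init_model(cfg, seed = 43)
  expect_gt(max(abs(s1$par[["fusion.dense1.W"]] - s3$par[["fusion.dense1.W"]])), 0)
  sm <- model_summary(s1)
  expect_equal(unname(sm$layers$smri), c(6L, 3L, 4L))
  expect_equal(unname(sm$layers$classifier), 3L)
  bad <- cfg
  bad$fused_dim <- 123L
  expect_error(init_model(bad, 1), "fused_dim")
})

test_that("inference is deterministic and branches are isolated in fusion", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 11)
  inp <- tiny_input(cfg, seed = 12)
  f1 <- amynet:::full_forward(st, inp)
  f2 <- amynet:::full_forward(st, inp)
  expect_identical(f1$logits, f2$logits)
  # zeroing the sMRI input changes only its latent segment pre-classifier
  inp0 <- inp
  inp0$vol <- array(0, cfg$grid_extents)
  f0 <- amynet:::full_forward(st, inp0)
  expect_false(isTRUE(all.equal(f0$latents$smri, f1$latents$smri)))
  expect_identical(f0$latents$fmri, f1$latents$fmri)
  expect_identical(f0$latents$dmri, f1$latents$dmri)
})

test_that("equal logits give a (0.5, 0.5) prediction", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 13)
  st$par[["fusion.dense3.W"]][] <- 0
  st$par[["fusion.dense3.b"]][] <- 1.7
  out <- fuse_and_classify(st, rep(1, 7), rep(2, 7), rep(3, 7))
  expect_equal(out$probs, c(0.5, 0.5))
})

test_that("graph branches reject mismatched node counts and negative SC", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 14)
  expect_error(fmri_branch_forward(st, fnc_to_graph(toy_fnc(7, seed = 1))), "nodes")
  expect_error(dmri_branch_forward(st, sc_to_graph(toy_sc(9, seed = 1))), "nodes")
})
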