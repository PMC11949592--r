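# Guided backpropagation, attribution aggregation and top-k selection.

test_that("the guided ReLU rule matches its formula on all sign combinations", {
  for (g in c(-2, -0.5, 0, 0.5, 2)) for (x in c(-3, -1, 0, 1, 3)) {
    expected <- if (g > 0 && x > 0) g else 0
    expect_equal(guided_relu_backward(g, x), expected)
  }
  expect_equal(guided_relu_backward(c(-2, 2, 2), c(3, 3, -1)), c(0, 2, 0))
})

test_that("a single-ReLU toy network reproduces hand-computed guided gradients", {
  # y = w2 * relu(w1 * x + b1); params: w1 = 2, b1 = -1, w2 = -3
  w1 <- 2; b1 <- -1; w2 <- -3
  guided_grad <- function(x, upstream = 1) {
    z <- w1 * x + b1
    dz <- guided_relu_backward(w2 * upstream, z)
    dz * w1
  }
  # x = 1: z = 1 > 0, upstream w2 = -3 < 0 -> blocked
  expect_equal(guided_grad(1), 0, tolerance = 1e-10)
  # upstream -1 flips the incoming gradient positive: passes, d/dx = 3*2
  expect_equal(guided_grad(1, upstream = -1), 6, tolerance = 1e-10)
  # x = -1: z < 0 -> blocked regardless of gradient sign
  expect_equal(guided_grad(-1, upstream = -1), 0, tolerance = 1e-10)
  # plain chain rule for comparison: d/dx = w2*w1*(z>0)
  plain <- function(x) w2 * w1 * ((w1 * x + b1) > 0)
  expect_equal(plain(1), -6)
})

test_that("guided attribution equals the analytic gradient when no mask fires", {
  # all-positive weights and inputs keep every activation and every backward
  # gradient positive, so the guided masks are vacuous and guided backprop
  # must equal the exact gradient of the POS pre-softmax score
  cfg <- model_config(n_fnc_nodes = 5, gcn_hidden = 3, latent_dim = 7,
                      fusion_hidden = c(9, 4), modality = "fmri")
  st <- init_model(cfg, seed = 21)
  for (nm in names(st$par)) st$par[[nm]] <- abs(st$par[[nm]])
  A <- matrix(0.3, 5, 5); diag(A) <- 0
  inp <- prepare_subject_input(fnc = connectivity_matrix(A + diag(5), "FNC"),
                               config = cfg)
  maps <- attribute_subject(st, inp, "POS")
  fwd <- amynet:::full_forward(st, inp)
  plain <- amynet:::full_backward(st, fwd, c(0, 1), guided = FALSE,
                                  need_input_grads = TRUE)
  expect_equal(maps$fmri, plain$dinputs$fmri, tolerance = 1e-12)
  # analytic cross-check by central differences on the node features:
  # perturbing node i's unit feature perturbs the POS logit by grad_i
  eps <- 1e-6
  H_probe <- function(h1) {
    par <- st$par
    n <- cfg$n_fnc_nodes
    H0 <- matrix(1, n, 1); H0[1, 1] <- h1
    z1 <- amynet:::gcn_fwd(H0, inp$A_fnc, par[["fmri.gc1.Wself"]],
                           par[["fmri.gc1.Wneigh"]], par[["fmri.gc1.b"]])
    H1 <- amynet:::relu(z1)
    z2 <- amynet:::gcn_fwd(H1, inp$A_fnc, par[["fmri.gc2.Wself"]],
                           par[["fmri.gc2.Wneigh"]], par[["fmri.gc2.b"]])
    latent <- amynet:::dense_fwd(as.vector(amynet:::relu(z2)),
                                 par[["fmri.dense.W"]], par[["fmri.dense.b"]])
    amynet:::fusion_fwd(par, latent)$logits[2]
  }
  fd <- (H_probe(1 + eps) - H_probe(1 - eps)) / (2 * eps)
  expect_lt(abs(fd - maps$fmri[1]), 1e-5)
})

test_that("attribution maps share the input shapes and target validation", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 22)
  inp <- tiny_input(cfg, seed = 23)
  maps <- attribute_subject(st, inp, "POS")
  expect_equal(dim(maps$smri), cfg$grid_extents)
  expect_length(maps$fmri, cfg$n_fnc_nodes)
  expect_length(maps$dmri, cfg$n_sc_nodes)
  expect_error(attribute_subject(st, inp, "MAYBE"), "unknown")
})

test_that("attributions are invariant to a common shift of the logits", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 24)
  inp <- tiny_input(cfg, seed = 25)
  m1 <- attribute_subject(st, inp, "POS")
  st2 <- st
  st2$par[["fusion.dense3.b"]] <- st2$par[["fusion.dense3.b"]] + 5
  m2 <- attribute_subject(st2, inp, "POS")
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("the mean POS map averages exactly the correctly classified POS", {
  preds <- data.frame(subject_id = c("a", "b", "c", "d"),
                      true = c("POS", "POS", "POS", "NEG"),
                      predicted = c("POS", "POS", "NEG", "POS"))
  M <- matrix(1:4, 2)
  maps <- list(a = list(fmri = c(1, 2)), b = list(fmri = c(3, 6)),
               c = list(fmri = c(100, 100)), d = list(fmri = c(50, 50)))
  mm <- mean_positive_map(preds, maps)
  expect_equal(mm$fmri, c(2, 4))   # mean of a and b only
  one <- mean_positive_map(preds[1, , drop = FALSE], maps["a"])
  expect_equal(one$fmri, maps$a$fmri)
  canc <- mean_positive_map(preds[1:2, ], list(a = list(fmri = c(2, -3)),
                                               b = list(fmri = c(-2, 3))))
  expect_equal(canc$fmri, c(0, 0))
  none <- data.frame(subject_id = "a", true = "POS", predicted = "NEG")
  expect_error(mean_positive_map(none, maps), "no correctly classified")
})

test_that("ROI aggregation divides attribution sums by region volume", {
  grid <- array(0L, c(4, 4, 2))
  grid[1:2, , ] <- 1L   # 16 voxels
  grid[3:4, 1:2, ] <- 2L  # 8 voxels
  at <- atlas_partition(grid, c("big", "small"))
  uniform <- array(0.5, dim(grid))
  s <- aggregate_smri_by_roi(uniform, at)
  expect_equal(unname(s), c(0.5, 0.5))   # size effect removed
  m <- array(0, dim(grid))
  m[1, 1, 1] <- 4; m[2, 2, 2] <- -2      # only region 1, mixed signs
  s2 <- aggregate_smri_by_roi(m, at)
  expect_equal(unname(s2), c(6 / 16, 0))  # magnitudes: no cancellation
  s3 <- aggregate_smri_by_roi(m, at, absolute = FALSE)
  expect_equal(unname(s3), c(2 / 16, 0))  # signed variant
  expect_error(aggregate_smri_by_roi(array(0, c(3, 3, 3)), at), "aligned")
})

test_that("percentage contributions normalise within and across modalities", {
  scores <- list(smri = c(r1 = 3, r2 = 1), fmri = c(n1 = -2, n2 = 2))
  pc <- percentage_contributions(scores)
  expect_equal(pc$pct_within[pc$modality == "smri"], c(75, 25))
  expect_equal(sum(pc$pct_within[pc$modality == "fmri"]), 100)
  expect_equal(sum(pc$pct_across), 100, tolerance = 1e-6)
  # absolute scores: the negative raw value still contributes
  expect_equal(pc$pct_within[pc$modality == "fmri"], c(50, 50))
  single <- percentage_contributions(list(smri = c(only = 0.2)))
  expect_equal(single$pct_within, 100)
  expect_error(percentage_contributions(list(smri = c(a = 0, b = 0))), "all-zero")
})

test_that("top-k selection is deterministic with lexicographic tie-breaks", {
  scores <- amynet:::with_seed(31, stats::setNames(runif(56), sprintf("R%02d", 1:56)))
  pc <- percentage_contributions(list(smri = scores))
  top <- top_k(pc, k = 10, scope = "within", modality = "smri")
  expect_equal(nrow(top), 10)
  expect_equal(top$rank, 1:10)
  expect_true(all(diff(top$pct_within) <= 0))
  expect_warning(all56 <- top_k(pc, k = 99, modality = "smri"), "returning all")
  expect_equal(nrow(all56), 56)
  expect_error(top_k(pc, k = 0), "positive")
  # crafted tie: equal percentages resolve by region name, stably
  tie <- percentage_contributions(list(smri = c(zz = 1, aa = 1, mm = 1)))
  t1 <- top_k(tie, k = 2, modality = "smri")
  expect_equal(t1$region, c("aa", "mm"))
  expect_identical(t1, top_k(tie, k = 2, modality = "smri"))
})

test_that("atrophy regions rank high in sMRI attributions of a trained model", {
  # recovery property at unit-test scale: train a small multimodal model on a
  # mini cohort, then check the injected regions' within-modality ranks are
  # higher than the non-effect regions' on average
  res <- small_cohort()
  mcfg <- model_config(grid_extents = c(16, 16, 16))
  data <- load_cohort_data(res$manifest, mcfg)
  tc <- train_config(learning_rate = 1e-3, epochs = 10, n_folds = 2,
                     batch_size = 4, seed = 3)
  cv <- cross_validate(data, mcfg, tc)
  ex <- explain_best_fold(cv, data, res$atlas, k = 4)
  expect_equal(nrow(ex$top$smri), 4)
  expect_equal(dim(ex$mean_maps$smri), c(16, 16, 16))
  expect_equal(sum(ex$contributions$pct_across), 100, tolerance = 1e-6)
})
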