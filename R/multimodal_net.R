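# The two-module architecture: three feature-reduction branches (3D CNN for
# gray matter, signed-weight GCN for the FNC graph, Chebyshev spectral GCN for
# the SC graph), each ending in a 100-feature latent, followed by
# concatenation fusion (300 features) and a three-layer MLP classifier with
# softmax output. Forward and backward passes are explicit so guided
# backpropagation can reuse the same code path.

#' Model configuration
#'
#' Layer counts follow the reference architecture: the sMRI branch has six
#' convolutional layers, three max-pooling layers and four dense layers; the
#' fMRI branch two graph-convolutional layers plus a dense layer; the dMRI
#' branch two Chebyshev spectral layers plus a dense layer; the classifier has
#' three dense layers ending in softmax. Hidden widths and kernel sizes are
#' the smallest stacks honouring those counts while trainable on one CPU.
#'
#' @param grid_extents sMRI input grid (default 32^3 for desk-scale work; the
#'   clinical grid is 121x145x121).
#' @param n_fnc_nodes,n_sc_nodes graph sizes (53 ICs, 84 anatomical ROIs).
#' @param conv_channels channel schedule of the six conv layers.
#' @param kernel_size conv kernel edge (cubic).
#' @param dense_smri hidden widths of the first three sMRI dense layers (the
#'   fourth maps to `latent_dim`).
#' @param latent_dim per-branch latent size (100).
#' @param gcn_hidden,cheb_hidden hidden node-feature widths of the two graph
#'   branches.
#' @param cheb_k Chebyshev polynomial order K.
#' @param fusion_hidden hidden widths of the first two classifier layers.
#' @param n_classes output classes (NEG, POS).
#' @param modality `"multimodal"` or one of `"smri"`, `"fmri"`, `"dmri"` for
#'   the unimodal ablations (the same branch with a classifier head on its
#'   100-feature latent).
#' @param lambda_tol power-iteration tolerance for the Laplacian lambda_max.
#' @return object of class `amynet_config`.
#' @export
model_config <- function(grid_extents = c(32, 32, 32),
                         n_fnc_nodes = 53,
                         n_sc_nodes = 84,
                         conv_channels = c(8, 8, 16, 16, 32, 32),
                         kernel_size = 3,
                         dense_smri = c(512, 256, 128),
                         latent_dim = 100,
                         gcn_hidden = 16,
                         cheb_hidden = 16,
                         cheb_k = 3,
                         fusion_hidden = c(128, 32),
                         n_classes = 2,
                         modality = c("multimodal", "smri", "fmri", "dmri"),
                         lambda_tol = 1e-6) {
  modality <- match.arg(modality)
  if (length(conv_channels) != 6) stopf("conv_channels must have 6 entries")
  if (length(dense_smri) != 3) stopf("dense_smri must have 3 entries (4th dense layer is the latent)")
  if (length(fusion_hidden) != 2) stopf("fusion_hidden must have 2 entries (3rd dense layer is the output)")
  if (cheb_k < 1) stopf("cheb_k must be >= 1")
  fused_dim <- if (modality == "multimodal") 3L * latent_dim else latent_dim
  if (modality == "multimodal" && fused_dim != 3L * latent_dim)
    stopf("fused_dim must equal 3 x latent_dim")
  cfg <- list(grid_extents = as.integer(grid_extents),
              n_fnc_nodes = as.integer(n_fnc_nodes),
              n_sc_nodes = as.integer(n_sc_nodes),
              conv_channels = as.integer(conv_channels),
              kernel_size = as.integer(kernel_size),
              pool_after = c(2L, 4L, 6L),
              dense_smri = as.integer(dense_smri),
              latent_dim = as.integer(latent_dim),
              gcn_hidden = as.integer(gcn_hidden),
              cheb_hidden = as.integer(cheb_hidden),
              cheb_k = as.integer(cheb_k),
              fusion_hidden = as.integer(fusion_hidden),
              n_classes = as.integer(n_classes),
              fused_dim = as.integer(fused_dim),
              modality = modality,
              lambda_tol = lambda_tol)
  structure(cfg, class = "amynet_config")
}

active_branches <- function(config) {
  if (config$modality == "multimodal") c("smri", "fmri", "dmri") else config$modality
}

# grid size after the three 2x2x2 pools
conv_out_dims <- function(grid) {
  d <- as.integer(grid)
  for (i in 1:3) d <- d %/% 2L
  d
}

smri_flatten_dim <- function(config) {
  prod(conv_out_dims(config$grid_extents)) * config$conv_channels[6]
}

# ---------------------------------------------------------------------------
# Initialisation

# He-uniform for layers feeding rectified-linear units (preserves activation
# variance through deep ReLU stacks); Glorot-uniform for the softmax output.
he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Initialise model parameters
#'
#' Variance-scaled uniform weights (He-style for rectified-linear layers,
#' Glorot for the softmax output), zero biases; deterministic for a fixed
#' (config, seed) pair.
#'
#' @param config an [model_config()] object.
#' @param seed integer seed.
#' @return object of class `amynet_model`: list with `config`, `par` (flat
#'   named list of parameter arrays) and `seed`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "amynet_config"))
  if (config$modality == "multimodal" && config$fused_dim != 3L * config$latent_dim)
    stopf("inconsistent config: fused_dim (%d) != 3 x latent_dim (%d)",
          config$fused_dim, 3L * config$latent_dim)
  k3 <- config$kernel_size^3
  par <- list()
  with_seed(seed, {
    br <- active_branches(config)
    if ("smri" %in% br) {
      cin <- 1L
      for (l in seq_len(6)) {
        cout <- config$conv_channels[l]
        par[[sprintf("smri.conv%d.W", l)]] <- he_uniform(c(k3 * cin, cout), k3 * cin)
        par[[sprintf("smri.conv%d.b", l)]] <- numeric(cout)
        cin <- cout
      }
      widths <- c(smri_flatten_dim(config), config$dense_smri, config$latent_dim)
      for (j in seq_len(4)) {
        par[[sprintf("smri.dense%d.W", j)]] <- he_uniform(c(widths[j], widths[j + 1]),
                                                          widths[j])
        par[[sprintf("smri.dense%d.b", j)]] <- numeric(widths[j + 1])
      }
    }
    if ("fmri" %in% br) {
      h <- config$gcn_hidden
      for (l in 1:2) {
        fin <- if (l == 1) 1L else h
        par[[sprintf("fmri.gc%d.Wself", l)]] <- he_uniform(c(fin, h), fin)
        par[[sprintf("fmri.gc%d.Wneigh", l)]] <- he_uniform(c(fin, h), fin)
        par[[sprintf("fmri.gc%d.b", l)]] <- numeric(h)
      }
      fl <- config$n_fnc_nodes * h
      par[["fmri.dense.W"]] <- he_uniform(c(fl, config$latent_dim), fl)
      par[["fmri.dense.b"]] <- numeric(config$latent_dim)
    }
    if ("dmri" %in% br) {
      h <- config$cheb_hidden
      K <- config$cheb_k
      for (l in 1:2) {
        fin <- if (l == 1) 1L else h
        par[[sprintf("dmri.cheb%d.W", l)]] <- he_uniform(c(fin, h, K), fin * K)
        par[[sprintf("dmri.cheb%d.b", l)]] <- numeric(h)
      }
      fl <- config$n_sc_nodes * h
      par[["dmri.dense.W"]] <- he_uniform(c(fl, config$latent_dim), fl)
      par[["dmri.dense.b"]] <- numeric(config$latent_dim)
    }
    widths <- c(config$fused_dim, config$fusion_hidden, config$n_classes)
    for (j in seq_len(3)) {
      par[[sprintf("fusion.dense%d.W", j)]] <-
        if (j < 3) he_uniform(c(widths[j], widths[j + 1]), widths[j])
        else glorot(c(widths[j], widths[j + 1]), widths[j], widths[j + 1])
      par[[sprintf("fusion.dense%d.b", j)]] <- numeric(widths[j + 1])
    }
  })
  structure(list(config = config, par = par, seed = as.integer(seed)),
            class = "amynet_model")
}

#' Summarise a model: layer counts and parameter count
#' @param state an `amynet_model`.
#' @return list with `layers` (named counts per branch) and `n_parameters`.
#' @export
model_summary <- function(state) {
  stopifnot(inherits(state, "amynet_model"))
  br <- active_branches(state$config)
  layers <- list()
  if ("smri" %in% br) layers$smri <- c(conv = 6L, pool = 3L, dense = 4L)
  if ("fmri" %in% br) layers$fmri <- c(graph_conv = 2L, dense = 1L)
  if ("dmri" %in% br) layers$dmri <- c(chebyshev = 2L, dense = 1L)
  layers$classifier <- c(dense = 3L)
  list(layers = layers,
       latent_dim = state$config$latent_dim,
       fused_dim = state$config$fused_dim,
       n_parameters = sum(vapply(state$par, length, integer(1))))
}

#' @export
print.amynet_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("amynet model (%s): latent %d per branch, fused %d, %d parameters\n",
              x$config$modality, s$latent_dim, s$fused_dim, s$n_parameters))
  for (nm in names(s$layers))
    cat(sprintf("  %-10s %s\n", nm,
                paste(sprintf("%s=%d", names(s$layers[[nm]]), s$layers[[nm]]), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-subject input preparation. The graph operators that are fixed during
# training (signed FNC adjacency; Chebyshev polynomials of the SC Laplacian)
# are precomputed here.

#' Prepare one subject's tensors for the network
#'
#' @param vol 3D gray-matter array (or `gm_volume`); must match the configured
#'   grid.
#' @param fnc a [connectivity_matrix()] of kind FNC (or a `brain_graph`).
#' @param sc a [connectivity_matrix()] of kind SC (or a `brain_graph`).
#' @param config an [model_config()].
#' @return list with `vol`, `A_fnc` (signed adjacency, zero diagonal) and
#'   `Tk_sc` (list of K Chebyshev polynomial matrices).
#' @export
prepare_subject_input <- function(vol = NULL, fnc = NULL, sc = NULL, config) {
  stopifnot(inherits(config, "amynet_config"))
  out <- list()
  br <- active_branches(config)
  if ("smri" %in% br) {
    if (inherits(vol, "gm_volume")) vol <- vol$data
    if (is.null(vol)) stopf("sMRI volume required for modality %s", config$modality)
    if (!all(dim(vol) == config$grid_extents))
      stopf("volume grid %s does not match configured grid %s",
            paste(dim(vol), collapse = "x"),
            paste(config$grid_extents, collapse = "x"))
    out$vol <- vol
  }
  if ("fmri" %in% br) {
    g <- if (inherits(fnc, "brain_graph")) fnc else fnc_to_graph(fnc)
    if (g$n_nodes != config$n_fnc_nodes)
      stopf("FNC graph has %d nodes; config expects %d", g$n_nodes, config$n_fnc_nodes)
    out$A_fnc <- g$adjacency
  }
  if ("dmri" %in% br) {
    g <- if (inherits(sc, "brain_graph")) sc else sc_to_graph(sc)
    if (g$n_nodes != config$n_sc_nodes)
      stopf("SC graph has %d nodes; config expects %d", g$n_nodes, config$n_sc_nodes)
    if (min(g$adjacency) < 0) stopf("SC graph weights must be nonnegative")
    Lt <- scaled_laplacian(g$adjacency, tol = config$lambda_tol)
    out$Tk_sc <- cheb_polynomials(Lt, config$cheb_k)
  }
  out
}

# ---------------------------------------------------------------------------
# Branch forwards (with caches) and backwards

smri_fwd <- function(par, config, vol) {
  x <- array(vol, c(dim(vol), 1L))
  convs <- vector("list", 6)
  for (l in seq_len(6)) {
    W <- par[[sprintf("smri.conv%d.W", l)]]
    b <- par[[sprintf("smri.conv%d.b", l)]]
    cf <- conv3d_fwd(x, W, b, config$kernel_size)
    z <- cf$y
    a <- relu(z)
    entry <- list(P = cf$P, dims_in = cf$dims_in, z = z)
    if (l %in% config$pool_after) {
      pl <- maxpool_fwd(a)
      entry$pool_idx <- pl$idx
      entry$dims_prepool <- dim(a)
      x <- pl$y
    } else {
      x <- a
    }
    convs[[l]] <- entry
  }
  flat <- as.vector(x)
  dense <- vector("list", 4)
  h <- flat
  for (j in seq_len(4)) {
    W <- par[[sprintf("smri.dense%d.W", j)]]
    b <- par[[sprintf("smri.dense%d.b", j)]]
    z <- dense_fwd(h, W, b)
    dense[[j]] <- list(x_in = h, z = z)
    h <- if (j < 4) relu(z) else z  # branch latent is linear
  }
  list(latent = h, convs = convs, dense = dense, flat_dims = dim(x))
}

smri_bwd <- function(par, config, cache, dlatent, guided = FALSE,
                     need_dinput = TRUE) {
  grads <- list()
  dz <- dlatent
  for (j in 4:1) {
    W <- par[[sprintf("smri.dense%d.W", j)]]
    bw <- dense_bwd(dz, cache$dense[[j]]$x_in, W)
    grads[[sprintf("smri.dense%d.W", j)]] <- bw$dW
    grads[[sprintf("smri.dense%d.b", j)]] <- bw$db
    if (j > 1) dz <- relu_backward(bw$dx, cache$dense[[j - 1]]$z, guided)
    else dflat <- bw$dx
  }
  dcur <- array(dflat, cache$flat_dims)
  for (l in 6:1) {
    entry <- cache$convs[[l]]
    if (l %in% config$pool_after)
      dcur <- maxpool_bwd(dcur, entry$pool_idx, entry$dims_prepool)
    dz <- relu_backward(dcur, entry$z, guided)
    W <- par[[sprintf("smri.conv%d.W", l)]]
    cb <- conv3d_bwd(dz, entry$P, entry$dims_in, W, config$kernel_size,
                     compute_dx = (l > 1L || need_dinput))
    grads[[sprintf("smri.conv%d.W", l)]] <- cb$dW
    grads[[sprintf("smri.conv%d.b", l)]] <- cb$db
    dcur <- cb$dx
  }
  list(grads = grads,
       dinput = if (need_dinput) array(dcur, dim(dcur)[1:3]) else NULL)
}

fmri_fwd <- function(par, config, A) {
  n <- config$n_fnc_nodes
  H0 <- matrix(1, n, 1)
  z1 <- gcn_fwd(H0, A, par[["fmri.gc1.Wself"]], par[["fmri.gc1.Wneigh"]], par[["fmri.gc1.b"]])
  H1 <- relu(z1)
  z2 <- gcn_fwd(H1, A, par[["fmri.gc2.Wself"]], par[["fmri.gc2.Wneigh"]], par[["fmri.gc2.b"]])
  H2 <- relu(z2)
  flat <- as.vector(H2)  # node-order-preserving flatten
  latent <- dense_fwd(flat, par[["fmri.dense.W"]], par[["fmri.dense.b"]])
  list(latent = latent, H0 = H0, z1 = z1, H1 = H1, z2 = z2, H2 = H2,
       flat = flat, A = A)
}

fmri_bwd <- function(par, config, cache, dlatent, guided = FALSE) {
  grads <- list()
  bw <- dense_bwd(dlatent, cache$flat, par[["fmri.dense.W"]])
  grads[["fmri.dense.W"]] <- bw$dW
  grads[["fmri.dense.b"]] <- bw$db
  dH2 <- matrix(bw$dx, nrow(cache$H2), ncol(cache$H2))
  dz2 <- relu_backward(dH2, cache$z2, guided)
  g2 <- gcn_bwd(dz2, cache$H1, cache$A, par[["fmri.gc2.Wself"]], par[["fmri.gc2.Wneigh"]])
  grads[["fmri.gc2.Wself"]] <- g2$dWself
  grads[["fmri.gc2.Wneigh"]] <- g2$dWneigh
  grads[["fmri.gc2.b"]] <- g2$db
  dz1 <- relu_backward(g2$dH, cache$z1, guided)
  g1 <- gcn_bwd(dz1, cache$H0, cache$A, par[["fmri.gc1.Wself"]], par[["fmri.gc1.Wneigh"]])
  grads[["fmri.gc1.Wself"]] <- g1$dWself
  grads[["fmri.gc1.Wneigh"]] <- g1$dWneigh
  grads[["fmri.gc1.b"]] <- g1$db
  list(grads = grads, dinput = drop(g1$dH))  # gradient w.r.t. unit node features
}

dmri_fwd <- function(par, config, Tk) {
  n <- config$n_sc_nodes
  H0 <- matrix(1, n, 1)
  z1 <- cheb_fwd(H0, Tk, par[["dmri.cheb1.W"]], par[["dmri.cheb1.b"]])
  H1 <- relu(z1)
  z2 <- cheb_fwd(H1, Tk, par[["dmri.cheb2.W"]], par[["dmri.cheb2.b"]])
  H2 <- relu(z2)
  flat <- as.vector(H2)
  latent <- dense_fwd(flat, par[["dmri.dense.W"]], par[["dmri.dense.b"]])
  list(latent = latent, H0 = H0, z1 = z1, H1 = H1, z2 = z2, H2 = H2,
       flat = flat, Tk = Tk)
}

dmri_bwd <- function(par, config, cache, dlatent, guided = FALSE) {
  grads <- list()
  bw <- dense_bwd(dlatent, cache$flat, par[["dmri.dense.W"]])
  grads[["dmri.dense.W"]] <- bw$dW
  grads[["dmri.dense.b"]] <- bw$db
  dH2 <- matrix(bw$dx, nrow(cache$H2), ncol(cache$H2))
  dz2 <- relu_backward(dH2, cache$z2, guided)
  c2 <- cheb_bwd(dz2, cache$H1, cache$Tk, par[["dmri.cheb2.W"]])
  grads[["dmri.cheb2.W"]] <- c2$dW
  grads[["dmri.cheb2.b"]] <- c2$db
  dz1 <- relu_backward(c2$dH, cache$z1, guided)
  c1 <- cheb_bwd(dz1, cache$H0, cache$Tk, par[["dmri.cheb1.W"]])
  grads[["dmri.cheb1.W"]] <- c1$dW
  grads[["dmri.cheb1.b"]] <- c1$db
  list(grads = grads, dinput = drop(c1$dH))
}

fusion_fwd <- function(par, fused) {
  z1 <- dense_fwd(fused, par[["fusion.dense1.W"]], par[["fusion.dense1.b"]])
  h1 <- relu(z1)
  z2 <- dense_fwd(h1, par[["fusion.dense2.W"]], par[["fusion.dense2.b"]])
  h2 <- relu(z2)
  logits <- dense_fwd(h2, par[["fusion.dense3.W"]], par[["fusion.dense3.b"]])
  list(logits = logits, fused = fused, z1 = z1, h1 = h1, z2 = z2, h2 = h2)
}

fusion_bwd <- function(par, cache, dlogits, guided = FALSE) {
  grads <- list()
  bw3 <- dense_bwd(dlogits, cache$h2, par[["fusion.dense3.W"]])
  grads[["fusion.dense3.W"]] <- bw3$dW
  grads[["fusion.dense3.b"]] <- bw3$db
  dz2 <- relu_backward(bw3$dx, cache$z2, guided)
  bw2 <- dense_bwd(dz2, cache$h1, par[["fusion.dense2.W"]])
  grads[["fusion.dense2.W"]] <- bw2$dW
  grads[["fusion.dense2.b"]] <- bw2$db
  dz1 <- relu_backward(bw2$dx, cache$z1, guided)
  bw1 <- dense_bwd(dz1, cache$fused, par[["fusion.dense1.W"]])
  grads[["fusion.dense1.W"]] <- bw1$dW
  grads[["fusion.dense1.b"]] <- bw1$db
  list(grads = grads, dfused = bw1$dx)
}

# ---------------------------------------------------------------------------
# Full network

full_forward <- function(state, input) {
  par <- state$par
  config <- state$config
  br <- active_branches(config)
  caches <- list()
  latents <- list()
  if ("smri" %in% br) {
    caches$smri <- smri_fwd(par, config, input$vol)
    latents$smri <- caches$smri$latent
  }
  if ("fmri" %in% br) {
    caches$fmri <- fmri_fwd(par, config, input$A_fnc)
    latents$fmri <- caches$fmri$latent
  }
  if ("dmri" %in% br) {
    caches$dmri <- dmri_fwd(par, config, input$Tk_sc)
    latents$dmri <- caches$dmri$latent
  }
  fused <- unlist(latents[br], use.names = FALSE)  # fixed order sMRI, fMRI, dMRI
  caches$fusion <- fusion_fwd(par, fused)
  list(logits = caches$fusion$logits,
       probs = softmax(caches$fusion$logits),
       latents = latents, caches = caches)
}

full_backward <- function(state, fwd, dlogits, guided = FALSE,
                          need_input_grads = guided) {
  par <- state$par
  config <- state$config
  br <- active_branches(config)
  fb <- fusion_bwd(par, fwd$caches$fusion, dlogits, guided)
  grads <- fb$grads
  dinputs <- list()
  off <- 0L
  for (b in br) {
    seg <- fb$dfused[(off + 1):(off + config$latent_dim)]
    off <- off + config$latent_dim
    bw <- switch(b,
                 smri = smri_bwd(par, config, fwd$caches$smri, seg, guided,
                                 need_dinput = need_input_grads),
                 fmri = fmri_bwd(par, config, fwd$caches$fmri, seg, guided),
                 dmri = dmri_bwd(par, config, fwd$caches$dmri, seg, guided))
    grads <- c(grads, bw$grads)
    dinputs[[b]] <- bw$dinput
  }
  list(grads = grads, dinputs = dinputs)
}

# ---------------------------------------------------------------------------
# Exported per-branch forward operations

#' sMRI branch forward pass
#' @param state an `amynet_model` whose config includes the sMRI branch.
#' @param vol 3D array or `gm_volume` matching the configured grid.
#' @return numeric latent vector of length `latent_dim`.
#' @export
smri_branch_forward <- function(state, vol) {
  stopifnot(inherits(state, "amynet_model"))
  if (inherits(vol, "gm_volume")) vol <- vol$data
  if (!all(dim(vol) == state$config$grid_extents))
    stopf("volume grid %s does not match configured grid %s",
          paste(dim(vol), collapse = "x"),
          paste(state$config$grid_extents, collapse = "x"))
  smri_fwd(state$par, state$config, vol)$latent
}

#' fMRI (FNC graph) branch forward pass
#' @param state an `amynet_model`.
#' @param g a [brain_graph()] with `n_fnc_nodes` nodes (signed weights kept).
#' @return numeric latent vector of length `latent_dim`.
#' @export
fmri_branch_forward <- function(state, g) {
  stopifnot(inherits(state, "amynet_model"), inherits(g, "brain_graph"))
  if (g$n_nodes != state$config$n_fnc_nodes)
    stopf("FNC graph has %d nodes; config expects %d", g$n_nodes, state$config$n_fnc_nodes)
  fmri_fwd(state$par, state$config, g$adjacency)$latent
}

#' dMRI (SC graph) branch forward pass
#' @param state an `amynet_model`.
#' @param g a [brain_graph()] with `n_sc_nodes` nodes and nonnegative weights.
#' @return numeric latent vector of length `latent_dim`.
#' @export
dmri_branch_forward <- function(state, g) {
  stopifnot(inherits(state, "amynet_model"), inherits(g, "brain_graph"))
  if (g$n_nodes != state$config$n_sc_nodes)
    stopf("SC graph has %d nodes; config expects %d", g$n_nodes, state$config$n_sc_nodes)
  if (min(g$adjacency) < 0) stopf("SC graph weights must be nonnegative")
  Tk <- cheb_polynomials(scaled_laplacian(g$adjacency, state$config$lambda_tol),
                         state$config$cheb_k)
  dmri_fwd(state$par, state$config, Tk)$latent
}

#' Fuse three branch latents and classify
#'
#' Concatenates the latents in fixed order (sMRI, fMRI, dMRI) into a
#' 300-feature vector and applies the three-layer MLP with softmax.
#' @param state an `amynet_model` (multimodal).
#' @param l_s,l_f,l_d latent vectors of length `latent_dim`.
#' @return list with `probs` (length-2, sums to 1), `logits`, `fused`.
#' @export
fuse_and_classify <- function(state, l_s, l_f, l_d) {
  stopifnot(inherits(state, "amynet_model"))
  ld <- state$config$latent_dim
  for (v in list(l_s, l_f, l_d))
    if (length(v) != ld) stopf("latent length %d != configured latent_dim %d", length(v), ld)
  fused <- c(l_s, l_f, l_d)
  out <- fusion_fwd(state$par, fused)
  list(probs = softmax(out$logits), logits = out$logits, fused = fused)
}
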