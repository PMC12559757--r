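# Compact 3D V-Net: residual stage blocks of volumetric convolutions, strided
# downsampling, nearest-neighbour upsampling with additive skip connections,
# sigmoid head; trained with soft-Dice (optionally + cross-entropy) loss and
# Adam. Fully convolutional, so inference runs on any patch whose dims are
# divisible by 2^(depth - 1). Conv kernels live in src/kernels.cpp.

conv3_fw <- function(x, w, b, stride = 1L, pad = 1L) {
  cpp_conv3d_fw(x, as.integer(dim(x)), w, as.integer(dim(w)), b,
                as.integer(stride), as.integer(pad))
}

conv3_bw <- function(x, w, gy, stride = 1L, pad = 1L) {
  cpp_conv3d_bw(x, as.integer(dim(x)), w, as.integer(dim(w)), gy,
                as.integer(stride), as.integer(pad))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# adjoint of nearest-neighbour x2 upsampling: sum gradients over each 2^3 cell
downsample_sum <- function(g) {
  d <- dim(g)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3] / 2, d[4]))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    out <- out + g[seq(1 + i, d[1], by = 2), seq(1 + j, d[2], by = 2),
                   seq(1 + k, d[3], by = 2), , drop = FALSE]
  }
  out
}

he_init <- function(kdim, gain = 2) {
  fan_in <- prod(kdim[1:4])
  array(rnorm(prod(kdim), sd = sqrt(gain / fan_in)), kdim)
}

#' Segmenter configuration
#'
#' Architecture and training hyper-parameters of the volumetric V-Net.
#'
#' @param base_channels feature channels at the top resolution (doubled per
#'   encoder stage).
#' @param depth number of encoder stages (>= 2).
#' @param loss `"dice"` (default, the architecture's native choice) or
#'   `"dice+ce"`.
#' @param lr Adam learning rate.
#' @param epochs passes over the training pairs (>= 1).
#' @param patch_size training patch dims; each must be divisible by
#'   `2^(depth - 1)`.
#' @param seed RNG seed for init, patch sampling and shuffling.
#' @return A `segmenter_config` list (architecture tag fixed at "vnet3d").
#' @export
segmenter_config <- function(base_channels = 4, depth = 2, loss = c("dice", "dice+ce"),
                             lr = 0.01, epochs = 10, patch_size = c(48, 48, 48),
                             seed = 1L) {
  loss <- match.arg(loss)
  if (depth < 2) abort("`depth` must be >= 2.")
  if (epochs < 1) abort("`epochs` must be >= 1.")
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  div <- 2^(depth - 1)
  if (any(patch_size %% div != 0)) {
    abort(sprintf("Each patch dimension must be divisible by %d for depth %d.",
                  div, depth))
  }
  structure(list(architecture = "vnet3d", base_channels = as.integer(base_channels),
                 depth = as.integer(depth), loss = loss, lr = lr,
                 epochs = as.integer(epochs), patch_size = patch_size,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

vnet_init_params <- function(cfg, in_ch = 1L) {
  D <- cfg$depth
  ch <- cfg$base_channels * 2^(seq_len(D) - 1)
  p <- list()
  cin <- in_ch
  for (s in seq_len(D)) {
    p[[paste0("enc_conv", s, "_w")]] <- he_init(c(3, 3, 3, cin, ch[s]))
    p[[paste0("enc_conv", s, "_b")]] <- numeric(ch[s])
    p[[paste0("enc_proj", s, "_w")]] <- he_init(c(1, 1, 1, cin, ch[s]), gain = 1)
    p[[paste0("enc_proj", s, "_b")]] <- numeric(ch[s])
    if (s < D) {
      p[[paste0("down", s, "_w")]] <- he_init(c(2, 2, 2, ch[s], ch[s + 1]))
      p[[paste0("down", s, "_b")]] <- numeric(ch[s + 1])
      cin <- ch[s + 1]
    }
  }
  for (s in rev(seq_len(D - 1))) {
    p[[paste0("up", s, "_w")]] <- he_init(c(3, 3, 3, ch[s + 1], ch[s]))
    p[[paste0("up", s, "_b")]] <- numeric(ch[s])
    p[[paste0("dec_conv", s, "_w")]] <- he_init(c(3, 3, 3, ch[s], ch[s]))
    p[[paste0("dec_conv", s, "_b")]] <- numeric(ch[s])
    p[[paste0("dec_proj", s, "_w")]] <- he_init(c(1, 1, 1, ch[s], ch[s]), gain = 1)
    p[[paste0("dec_proj", s, "_b")]] <- numeric(ch[s])
  }
  p[["head_w"]] <- he_init(c(1, 1, 1, cfg$base_channels, 1), gain = 1)
  p[["head_b"]] <- numeric(1)
  p
}

# residual stage block: relu(conv3x3) + 1x1 projection of the input
stage_fw <- function(x, p, tag) {
  a <- conv3_fw(x, p[[paste0(tag, "_w")]], p[[paste0(tag, "_b")]], 1L, 1L)
  proj_tag <- sub("conv", "proj", tag)
  pr <- conv3_fw(x, p[[paste0(proj_tag, "_w")]], p[[paste0(proj_tag, "_b")]], 1L, 0L)
  list(out = pmax(a, 0) + pr, x = x, a = a)
}

stage_bw <- function(g, cache, p, tag, grads) {
  proj_tag <- sub("conv", "proj", tag)
  gr <- g * (cache$a > 0)
  bw1 <- conv3_bw(cache$x, p[[paste0(tag, "_w")]], gr, 1L, 1L)
  bw2 <- conv3_bw(cache$x, p[[paste0(proj_tag, "_w")]], g, 1L, 0L)
  grads[[paste0(tag, "_w")]] <- grads[[paste0(tag, "_w")]] + bw1$gw
  grads[[paste0(tag, "_b")]] <- grads[[paste0(tag, "_b")]] + bw1$gb
  grads[[paste0(proj_tag, "_w")]] <- grads[[paste0(proj_tag, "_w")]] + bw2$gw
  grads[[paste0(proj_tag, "_b")]] <- grads[[paste0(proj_tag, "_b")]] + bw2$gb
  list(gx = bw1$gx + bw2$gx, grads = grads)
}

vnet_forward <- function(params, x, depth, cache = FALSE) {
  cc <- list(enc = vector("list", depth), down = vector("list", depth - 1),
             up = vector("list", depth - 1), dec = vector("list", depth - 1))
  cur <- x
  for (s in seq_len(depth)) {
    st <- stage_fw(cur, params, paste0("enc_conv", s))
    cc$enc[[s]] <- st
    cur <- st$out
    if (s < depth) {
      a <- conv3_fw(cur, params[[paste0("down", s, "_w")]],
                    params[[paste0("down", s, "_b")]], 2L, 0L)
      cc$down[[s]] <- list(x = cur, a = a)
      cur <- pmax(a, 0)
    }
  }
  for (s in rev(seq_len(depth - 1))) {
    u <- upsample2(cur)
    a <- conv3_fw(u, params[[paste0("up", s, "_w")]],
                  params[[paste0("up", s, "_b")]], 1L, 1L)
    r <- pmax(a, 0)
    merged <- r + cc$enc[[s]]$out
    cc$up[[s]] <- list(u = u, a = a)
    st <- stage_fw(merged, params, paste0("dec_conv", s))
    cc$dec[[s]] <- st
    cur <- st$out
  }
  logit <- conv3_fw(cur, params$head_w, params$head_b, 1L, 0L)
  prob <- 1 / (1 + exp(-logit))
  if (cache) list(prob = prob, logit = logit, top = cur, cache = cc)
  else prob
}

vnet_backward <- function(params, fwd, glogit, depth) {
  grads <- lapply(params, function(p) {
    g <- p; g[] <- 0; g
  })
  bwh <- conv3_bw(fwd$top, params$head_w, glogit, 1L, 0L)
  grads$head_w <- grads$head_w + bwh$gw
  grads$head_b <- grads$head_b + bwh$gb

  # decoder, outermost level first; g_enc accumulates the gradient reaching
  # each encoder stage's output (skip branch now, down-path branch later)
  g_enc <- vector("list", depth)
  g_cur <- bwh$gx
  for (s in seq_len(depth - 1)) {
    sb <- stage_bw(g_cur, fwd$cache$dec[[s]], params, paste0("dec_conv", s), grads)
    grads <- sb$grads
    g_merged <- sb$gx
    g_enc[[s]] <- g_merged                      # additive skip from enc level s
    gu_act <- g_merged * (fwd$cache$up[[s]]$a > 0)
    bwu <- conv3_bw(fwd$cache$up[[s]]$u, params[[paste0("up", s, "_w")]],
                    gu_act, 1L, 1L)
    grads[[paste0("up", s, "_w")]] <- grads[[paste0("up", s, "_w")]] + bwu$gw
    grads[[paste0("up", s, "_b")]] <- grads[[paste0("up", s, "_b")]] + bwu$gb
    g_cur <- downsample_sum(bwu$gx)             # into the next-deeper level
  }
  g_enc[[depth]] <- g_cur                       # bottom: decoder input is e_D

  # encoder, deepest stage first
  g_in <- NULL
  for (t in rev(seq_len(depth))) {
    g_out <- g_enc[[t]]
    if (!is.null(g_in)) {
      # g_in is the gradient at relu(down_t(e_t)); push through down conv
      ga <- g_in * (fwd$cache$down[[t]]$a > 0)
      bwd <- conv3_bw(fwd$cache$down[[t]]$x, params[[paste0("down", t, "_w")]],
                      ga, 2L, 0L)
      grads[[paste0("down", t, "_w")]] <- grads[[paste0("down", t, "_w")]] + bwd$gw
      grads[[paste0("down", t, "_b")]] <- grads[[paste0("down", t, "_b")]] + bwd$gb
      g_out <- g_out + bwd$gx
    }
    sbe <- stage_bw(g_out, fwd$cache$enc[[t]], params, paste0("enc_conv", t), grads)
    grads <- sbe$grads
    g_in <- sbe$gx
  }
  grads
}

# soft-Dice loss and its gradient w.r.t. the sigmoid logit
dice_loss_grad <- function(prob, target, with_ce = FALSE, eps = 1) {
  inter <- sum(prob * target)
  S <- sum(prob) + sum(target) + eps
  loss <- 1 - (2 * inter + eps) / S
  gp <- -(2 * target * S - (2 * inter + eps)) / S^2
  glogit <- gp * prob * (1 - prob)
  if (with_ce) {
    n <- length(prob)
    pc <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
    loss <- loss - mean(target * log(pc) + (1 - target) * log(1 - pc))
    glogit <- glogit + (prob - target) / n
  }
  list(loss = loss, glogit = glogit)
}

#' Train the volumetric segmenter
#'
#' Stochastic training of the compact 3D V-Net on (volume, mask) pairs with
#' soft-Dice loss and Adam. One iteration = one random patch from one
#' training pair; an epoch visits every pair once in shuffled order. Fully
#' seeded: a fixed config yields an identical loss trajectory (single
#' threaded, deterministic kernels).
#'
#' @param pairs list of `list(volume = , mask = )`: z-score normalized
#'   [volume_record()]s (or arrays) with logical ground-truth masks for the
#'   chosen target (breast or dense tissue).
#' @param cfg a [segmenter_config()].
#' @param target `"dense"` or `"breast"`; recorded on the model.
#' @return A `vnet_model`: parameters, config, target and the per-iteration
#'   loss `history`.
#' @export
train_segmenter <- function(pairs, cfg = segmenter_config(),
                            target = c("dense", "breast")) {
  target <- match.arg(target)
  stopifnot(inherits(cfg, "segmenter_config"))
  if (length(pairs) < 1) abort("Need at least one training pair.")
  vols <- lapply(pairs, function(p) as_volume_array(p$volume))
  masks <- lapply(pairs, function(p) array(as.numeric(p$mask), dim(p$mask)))
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]), dim(masks[[i]]))) {
      abort(sprintf("Training pair %d: volume and mask shapes differ.", i))
    }
    if (any(dim(vols[[i]]) < cfg$patch_size)) {
      abort(sprintf("Training pair %d is smaller than the training patch.", i))
    }
    if (abs(mean(vols[[i]])) > 0.1) {
      warn(sprintf("Training volume %d does not look z-score normalized (|mean| > 0.1).", i))
    }
  }
  ps <- cfg$patch_size
  with_seed(cfg$seed, {
    params <- vnet_init_params(cfg)
    m <- lapply(params, function(p) { z <- p; z[] <- 0; z })
    v <- m
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    it <- 0L
    history <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      for (i in sample(seq_along(vols))) {
        it <- it + 1L
        d <- dim(vols[[i]])
        s0 <- vapply(1:3, function(a) {
          if (d[a] == ps[a]) 0L else sample.int(d[a] - ps[a] + 1L, 1L) - 1L
        }, integer(1))
        ix <- (s0[1] + 1):(s0[1] + ps[1])
        iy <- (s0[2] + 1):(s0[2] + ps[2])
        iz <- (s0[3] + 1):(s0[3] + ps[3])
        x <- array(vols[[i]][ix, iy, iz], c(ps, 1L))
        t_ <- array(masks[[i]][ix, iy, iz], c(ps, 1L))
        fwd <- vnet_forward(params, x, cfg$depth, cache = TRUE)
        lg <- dice_loss_grad(fwd$prob, t_, with_ce = cfg$loss == "dice+ce")
        history[it] <- lg$loss
        grads <- vnet_backward(params, fwd, lg$glogit, cfg$depth)
        for (nm in names(params)) {
          g <- grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
          mhat <- m[[nm]] / (1 - b1^it)
          vhat <- v[[nm]] / (1 - b2^it)
          params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
    }
    structure(list(params = params, cfg = cfg, target = target,
                   history = history),
              class = "vnet_model")
  })
}

#' @export
print.vnet_model <- function(x, ...) {
  cat(sprintf("<vnet_model> target=%s, depth %d, base channels %d, %d iterations (final loss %.4f)\n",
              x$target, x$cfg$depth, x$cfg$base_channels, length(x$history),
              utils::tail(x$history, 1)))
  invisible(x)
}

#' @export
predict_patch.vnet_model <- function(model, patch, ...) {
  d <- dim(patch)
  div <- 2^(model$cfg$depth - 1)
  if (length(d) != 3 || any(d %% div != 0)) {
    abort(sprintf("Patch dims must be divisible by %d for this model.", div))
  }
  x <- array(patch, c(d, 1L))
  p <- vnet_forward(model$params, x, model$cfg$depth, cache = FALSE)
  array(p, d)
}

#' Save / load a trained segmenter
#'
#' Single-file checkpoint with the config embedded.
#' @param model a `vnet_model`.
#' @param path file path.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "vnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "vnet_model")) abort("Not a vnet_model checkpoint.")
  m
}
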