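# Hierarchical windowed-attention frame classifier (palpebral fissure
# existence vs disappearance). Four stages: patch partition + linear
# embedding, then window-restricted multi-head self-attention blocks with
# LayerNorm/MLP residuals, with 2x2 patch merging (4C -> 2C) between
# stages. Forward and backward passes are written out in base R matrix
# code; AdamW drives the updates. All tensors are token matrices (N x C).

#' Training configuration for the frame classifier
#'
#' The default stage layout is the standard "tiny" variant of the
#' architecture family (embedding 96; depths 2,2,6,2; window 7) at 224x224
#' input; the toy layout used in the examples and tests shrinks every
#' dimension for CPU-scale runs while keeping the same four-stage structure.
#'
#' @param input_size Square input side in pixels.
#' @param patch Patch side for the initial partition.
#' @param embed Embedding dimension of stage 1 (doubles at each merge).
#' @param depths,heads Integer vectors of length 4: blocks and attention
#'   heads per stage.
#' @param window Attention window side, in tokens (capped at the stage grid
#'   size).
#' @param mlp_ratio Hidden width of the block MLPs relative to the stage
#'   dimension.
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param batch_size,epochs Mini-batch size and training epochs.
#' @param split Train/validation/test proportions.
#' @param norm_mean,norm_sd Per-channel normalization constants applied
#'   after replicating the grayscale frame to 3 channels (defaults are the
#'   common natural-image pretraining constants).
#' @param crop_scale Range of the random-crop area fraction used as training
#'   augmentation; inference always uses a deterministic center crop.
#' @param seed Seed for split, init, shuffling and augmentation.
#' @return A list of class `"cls_config"`.
#' @export
cls_config <- function(input_size = 224L, patch = 4L, embed = 96L,
                       depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                       window = 7L, mlp_ratio = 4, lr = 1e-4,
                       weight_decay = 5e-2, batch_size = 8L, epochs = 10L,
                       split = c(8, 1, 1) / 10,
                       norm_mean = c(0.485, 0.456, 0.406),
                       norm_sd = c(0.229, 0.224, 0.225),
                       crop_scale = c(0.7, 1), seed = 1L) {
  if (input_size %% (patch * 8L) != 0)
    stopf("input_size must be divisible by patch * 8 (three 2x2 merges)")
  if (length(depths) != 4 || length(heads) != 4)
    stopf("depths and heads must have length 4")
  dims <- embed * c(1L, 2L, 4L, 8L)
  if (any(dims %% heads != 0))
    stopf("stage dimension must be divisible by its head count")
  structure(list(input_size = as.integer(input_size),
                 patch = as.integer(patch), embed = as.integer(embed),
                 depths = as.integer(depths), heads = as.integer(heads),
                 window = as.integer(window), mlp_ratio = mlp_ratio,
                 lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 crop_scale = crop_scale, seed = as.integer(seed)),
            class = "cls_config")
}

CLS_STATES <- c("existence", "disappearance")

# ---- geometry ------------------------------------------------------------

# token indices (column-major over the grid) of each attention window
window_index <- function(grid, win) {
  nwg <- grid %/% win
  idx <- vector("list", nwg * nwg)
  t <- 1L
  for (wc in seq_len(nwg))
    for (wr in seq_len(nwg)) {
      rows <- (wr - 1L) * win + seq_len(win)
      cols <- (wc - 1L) * win + seq_len(win)
      idx[[t]] <- as.integer(outer(rows, (cols - 1L) * grid, `+`))
      t <- t + 1L
    }
  idx
}

# index map for 2x2 patch merging: rows of the 4 quadrant token sets
merge_index <- function(grid) {
  g2 <- grid %/% 2L
  tok <- function(dr, dc) {
    r <- 2L * seq_len(g2) - 1L + dr
    c <- 2L * seq_len(g2) - 1L + dc
    as.integer(outer(r, (c - 1L) * grid, `+`))
  }
  list(tok(0L, 0L), tok(1L, 0L), tok(0L, 1L), tok(1L, 1L))
}

# linear indices extracting each patch (flattened, channel-last) from an
# S x S x 3 array; rows = tokens (column-major grid), cols = P*P*3 values
patch_index <- function(S, P) {
  g <- S %/% P
  npx <- P * P
  within_r <- rep(seq_len(P), P)
  within_c <- rep(seq_len(P), each = P)
  idx <- matrix(0L, g * g, npx * 3L)
  t <- 1L
  for (pc in seq_len(g))
    for (pr in seq_len(g)) {
      rr <- (pr - 1L) * P + within_r
      cc <- (pc - 1L) * P + within_c
      base <- rr + (cc - 1L) * S
      idx[t, ] <- c(base, base + S * S, base + 2L * S * S)
      t <- t + 1L
    }
  idx
}

swin_meta <- function(config) {
  g1 <- config$input_size %/% config$patch
  grids <- g1 %/% c(1L, 2L, 4L, 8L)
  dims <- config$embed * c(1L, 2L, 4L, 8L)
  wins <- pmin(config$window, grids)
  if (any(grids %% wins != 0))
    stopf("stage grid %s not divisible by window %s",
          paste(grids, collapse = ","), paste(wins, collapse = ","))
  list(grids = grids, dims = dims, wins = wins,
       widx = lapply(seq_len(4), function(s) window_index(grids[s], wins[s])),
       midx = lapply(2:4, function(s) merge_index(grids[s - 1])),
       pidx = patch_index(config$input_size, config$patch))
}

# ---- parameters ----------------------------------------------------------

swin_init <- function(config, meta) {
  p <- list()
  lin <- function(fin, fout) matrix(rnorm(fin * fout, 0, 0.02), fin, fout)
  p$embed_W <- lin(config$patch^2 * 3L, meta$dims[1])
  p$embed_b <- numeric(meta$dims[1])
  for (s in 1:4) {
    C <- meta$dims[s]
    if (s > 1) {
      p[[sprintf("s%d_mlng", s)]] <- rep(1, 4 * meta$dims[s - 1])
      p[[sprintf("s%d_mlnb", s)]] <- numeric(4 * meta$dims[s - 1])
      p[[sprintf("s%d_mW", s)]] <- lin(4 * meta$dims[s - 1], C)
      p[[sprintf("s%d_mb", s)]] <- numeric(C)
    }
    for (b in seq_len(config$depths[s])) {
      pre <- sprintf("s%db%d_", s, b)
      p[[paste0(pre, "ln1g")]] <- rep(1, C)
      p[[paste0(pre, "ln1b")]] <- numeric(C)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- lin(C, C)
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(C)
      p[[paste0(pre, "ln2g")]] <- rep(1, C)
      p[[paste0(pre, "ln2b")]] <- numeric(C)
      H <- round(config$mlp_ratio * C)
      p[[paste0(pre, "W1")]] <- lin(C, H)
      p[[paste0(pre, "b1")]] <- numeric(H)
      p[[paste0(pre, "W2")]] <- lin(H, C)
      p[[paste0(pre, "b2")]] <- numeric(C)
    }
  }
  p$head_lng <- rep(1, meta$dims[4])
  p$head_lnb <- numeric(meta$dims[4])
  p$head_W <- lin(meta$dims[4], 2L)
  p$head_b <- numeric(2L)
  p
}

# ---- primitives ----------------------------------------------------------

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dX = cache$inv * (dxhat - m1 - cache$xhat * m2),
       dg = colSums(dY * cache$xhat), db = colSums(dY))
}

gelu_fwd <- function(x) {
  c0 <- sqrt(2 / pi)
  t <- tanh(c0 * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + t), t = t)
}

gelu_bwd <- function(dy, x, t) {
  c0 <- sqrt(2 / pi)
  dy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2))
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# ---- forward / backward --------------------------------------------------

attn_fwd <- function(X, p, pre, widx, nh) {
  C <- ncol(X)
  dh <- C %/% nh
  scale <- 1 / sqrt(dh)
  out <- X * 0
  cache <- vector("list", length(widx))
  for (w in seq_along(widx)) {
    Xw <- X[widx[[w]], , drop = FALSE]
    Q <- Xw %*% p[[paste0(pre, "Wq")]] + rep(p[[paste0(pre, "bq")]], each = nrow(Xw))
    K <- Xw %*% p[[paste0(pre, "Wk")]] + rep(p[[paste0(pre, "bk")]], each = nrow(Xw))
    V <- Xw %*% p[[paste0(pre, "Wv")]] + rep(p[[paste0(pre, "bv")]], each = nrow(Xw))
    O <- Q * 0
    A <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A[[h]] <- softmax_rows(Q[, cols, drop = FALSE] %*%
                               t(K[, cols, drop = FALSE]) * scale)
      O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    out[widx[[w]], ] <- O %*% p[[paste0(pre, "Wo")]] +
      rep(p[[paste0(pre, "bo")]], each = nrow(Xw))
    cache[[w]] <- list(Xw = Xw, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(Y = out, cache = cache)
}

attn_bwd <- function(dY, X, p, g, pre, widx, nh, cache) {
  C <- ncol(X)
  dh <- C %/% nh
  scale <- 1 / sqrt(dh)
  dX <- X * 0
  for (w in seq_along(widx)) {
    cc <- cache[[w]]
    dOut <- dY[widx[[w]], , drop = FALSE]
    g[[paste0(pre, "Wo")]] <- g[[paste0(pre, "Wo")]] + t(cc$O) %*% dOut
    g[[paste0(pre, "bo")]] <- g[[paste0(pre, "bo")]] + colSums(dOut)
    dO <- dOut %*% t(p[[paste0(pre, "Wo")]])
    dQ <- dO * 0; dK <- dO * 0; dV <- dO * 0
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] * scale
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE] * scale
    }
    for (nm in list(c("Wq", "bq"), c("Wk", "bk"), c("Wv", "bv"))) {
      dM <- switch(nm[1], Wq = dQ, Wk = dK, Wv = dV)
      g[[paste0(pre, nm[1])]] <- g[[paste0(pre, nm[1])]] + t(cc$Xw) %*% dM
      g[[paste0(pre, nm[2])]] <- g[[paste0(pre, nm[2])]] + colSums(dM)
    }
    dXw <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) +
      dV %*% t(p[[paste0(pre, "Wv")]])
    dX[widx[[w]], ] <- dX[widx[[w]], , drop = FALSE] + dXw
  }
  list(dX = dX, g = g)
}

swin_forward <- function(p, meta, config, xp) {
  # xp: token matrix from the patch partition (g1^2 x P^2*3)
  cache <- list(stages = vector("list", 4))
  X <- xp %*% p$embed_W + rep(p$embed_b, each = nrow(xp))
  cache$xp <- xp
  for (s in 1:4) {
    sc <- list(blocks = vector("list", config$depths[s]))
    if (s > 1) {
      mi <- meta$midx[[s - 1]]
      Xm <- cbind(X[mi[[1]], , drop = FALSE], X[mi[[2]], , drop = FALSE],
                  X[mi[[3]], , drop = FALSE], X[mi[[4]], , drop = FALSE])
      ln <- ln_fwd(Xm, p[[sprintf("s%d_mlng", s)]], p[[sprintf("s%d_mlnb", s)]])
      sc$merge <- list(Xm = Xm, ln = ln)
      X <- ln$Y %*% p[[sprintf("s%d_mW", s)]] +
        rep(p[[sprintf("s%d_mb", s)]], each = nrow(ln$Y))
    }
    for (b in seq_len(config$depths[s])) {
      pre <- sprintf("s%db%d_", s, b)
      bc <- list(Xin = X)
      ln1 <- ln_fwd(X, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
      at <- attn_fwd(ln1$Y, p, pre, meta$widx[[s]], config$heads[s])
      X <- X + at$Y
      bc$ln1 <- ln1; bc$attn <- at$cache; bc$ln1Y <- ln1$Y; bc$Xmid <- X
      ln2 <- ln_fwd(X, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
      H1 <- ln2$Y %*% p[[paste0(pre, "W1")]] +
        rep(p[[paste0(pre, "b1")]], each = nrow(X))
      ge <- gelu_fwd(H1)
      M <- ge$y %*% p[[paste0(pre, "W2")]] +
        rep(p[[paste0(pre, "b2")]], each = nrow(X))
      X <- X + M
      bc$ln2 <- ln2; bc$ln2Y <- ln2$Y; bc$H1 <- H1; bc$gt <- ge$t
      bc$G <- ge$y
      sc$blocks[[b]] <- bc
    }
    cache$stages[[s]] <- sc
  }
  lnf <- ln_fwd(X, p$head_lng, p$head_lnb)
  pooled <- colMeans(lnf$Y)
  logits <- drop(pooled %*% p$head_W) + p$head_b
  cache$Xfinal <- X; cache$lnf <- lnf; cache$pooled <- pooled
  list(logits = logits, cache = cache)
}

swin_backward <- function(p, meta, config, cache, dlogits, g) {
  N4 <- nrow(cache$lnf$Y)
  g$head_W <- g$head_W + cache$pooled %o% dlogits
  g$head_b <- g$head_b + dlogits
  dpooled <- drop(p$head_W %*% dlogits)
  dlnfY <- matrix(dpooled / N4, N4, length(dpooled), byrow = TRUE)
  lb <- ln_bwd(dlnfY, cache$lnf, p$head_lng)
  g$head_lng <- g$head_lng + lb$dg
  g$head_lnb <- g$head_lnb + lb$db
  dX <- lb$dX
  for (s in 4:1) {
    sc <- cache$stages[[s]]
    for (b in rev(seq_len(config$depths[s]))) {
      pre <- sprintf("s%db%d_", s, b)
      bc <- sc$blocks[[b]]
      # MLP branch
      dM <- dX
      g[[paste0(pre, "W2")]] <- g[[paste0(pre, "W2")]] + t(bc$G) %*% dM
      g[[paste0(pre, "b2")]] <- g[[paste0(pre, "b2")]] + colSums(dM)
      dG <- dM %*% t(p[[paste0(pre, "W2")]])
      dH1 <- gelu_bwd(dG, bc$H1, bc$gt)
      g[[paste0(pre, "W1")]] <- g[[paste0(pre, "W1")]] + t(bc$ln2Y) %*% dH1
      g[[paste0(pre, "b1")]] <- g[[paste0(pre, "b1")]] + colSums(dH1)
      dln2Y <- dH1 %*% t(p[[paste0(pre, "W1")]])
      lb2 <- ln_bwd(dln2Y, bc$ln2, p[[paste0(pre, "ln2g")]])
      g[[paste0(pre, "ln2g")]] <- g[[paste0(pre, "ln2g")]] + lb2$dg
      g[[paste0(pre, "ln2b")]] <- g[[paste0(pre, "ln2b")]] + lb2$db
      dX <- dX + lb2$dX
      # attention branch
      ab <- attn_bwd(dX, bc$ln1Y, p, g, pre, meta$widx[[s]],
                     config$heads[s], bc$attn)
      g <- ab$g
      lb1 <- ln_bwd(ab$dX, bc$ln1, p[[paste0(pre, "ln1g")]])
      g[[paste0(pre, "ln1g")]] <- g[[paste0(pre, "ln1g")]] + lb1$dg
      g[[paste0(pre, "ln1b")]] <- g[[paste0(pre, "ln1b")]] + lb1$db
      dX <- dX + lb1$dX
    }
    if (s > 1) {
      mc <- sc$merge
      dlnY <- dX %*% t(p[[sprintf("s%d_mW", s)]])
      g[[sprintf("s%d_mW", s)]] <- g[[sprintf("s%d_mW", s)]] +
        t(mc$ln$Y) %*% dX
      g[[sprintf("s%d_mb", s)]] <- g[[sprintf("s%d_mb", s)]] + colSums(dX)
      lbm <- ln_bwd(dlnY, mc$ln, p[[sprintf("s%d_mlng", s)]])
      g[[sprintf("s%d_mlng", s)]] <- g[[sprintf("s%d_mlng", s)]] + lbm$dg
      g[[sprintf("s%d_mlnb", s)]] <- g[[sprintf("s%d_mlnb", s)]] + lbm$db
      Cprev <- meta$dims[s - 1]
      mi <- meta$midx[[s - 1]]
      dXprev <- matrix(0, meta$grids[s - 1]^2, Cprev)
      for (q in 1:4)
        dXprev[mi[[q]], ] <- lbm$dX[, (q - 1L) * Cprev + seq_len(Cprev),
                                    drop = FALSE]
      dX <- dXprev
    }
  }
  g$embed_W <- g$embed_W + t(cache$xp) %*% dX
  g$embed_b <- g$embed_b + colSums(dX)
  g
}

# ---- preprocessing -------------------------------------------------------

# grayscale frame -> normalized patch-token matrix
cls_preprocess <- function(image, config, meta, train = FALSE) {
  h <- nrow(image); w <- ncol(image)
  side <- min(h, w)
  if (train) {
    side <- max(8L, round(side * sqrt(runif(1, config$crop_scale[1],
                                            config$crop_scale[2]))))
    r0 <- sample.int(h - side + 1L, 1L)
    c0 <- sample.int(w - side + 1L, 1L)
  } else {
    r0 <- (h - side) %/% 2L + 1L
    c0 <- (w - side) %/% 2L + 1L
  }
  crop <- image[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
  if (train && runif(1) < 0.5) crop <- crop[, rev(seq_len(ncol(crop)))]
  S <- config$input_size
  m <- resize_nn(crop, S, S)
  x <- array(0, c(S, S, 3))
  for (ch in 1:3) x[, , ch] <- (m - config$norm_mean[ch]) / config$norm_sd[ch]
  matrix(x[meta$pidx], nrow(meta$pidx), ncol(meta$pidx))
}

# ---- training / inference ------------------------------------------------

#' Train the open/closed frame classifier
#'
#' Fits the four-stage windowed-attention classifier with cross-entropy loss
#' and AdamW, returning the checkpoint with the best validation accuracy.
#' Training frames are augmented with random crops and horizontal flips;
#' inference uses a deterministic center crop.
#'
#' @param frames List of grayscale matrices in `[0, 1]`.
#' @param states Character vector of per-frame states, `"existence"` or
#'   `"disappearance"`; both classes must be present in the training split.
#' @param config A [cls_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `"blink_swin"` with the best parameters, the
#'   config, the split, and `history` (epoch, train_loss, val_acc).
#' @export
train_classifier <- function(frames, states, config = cls_config(),
                             verbose = FALSE) {
  if (length(frames) == 0) stopf("empty training dataset")
  if (length(frames) != length(states))
    stopf("frames and states must be aligned")
  if (!all(states %in% CLS_STATES))
    stopf("states must be 'existence' or 'disappearance'")
  meta <- swin_meta(config)
  with_seed(config$seed, {
    n <- length(frames)
    sp <- split_indices(n, config$split)
    tr <- sp$train; va <- sp$val
    if (length(tr) == 0) tr <- seq_len(n)
    if (length(va) == 0) va <- tr
    if (length(unique(states[tr])) < 2)
      stopf("training split contains a single class; both states required")
    y <- as.integer(states == "disappearance") + 1L  # 1 = existence
    params <- swin_init(config, meta)
    mstate <- lapply(params, function(w) w * 0)
    vstate <- lapply(params, function(w) w * 0)
    step <- 0L
    best <- list(acc = -Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_acc = numeric(0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    decayed <- !grepl("(_b[12oqkv]?$|ln.?[gb]$|_mb$|_be$|head_b$)",
                      names(params))
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        g <- lapply(params, function(w) w * 0)
        bl <- 0
        for (i in idx) {
          xp <- cls_preprocess(frames[[i]], config, meta, train = TRUE)
          fw <- swin_forward(params, meta, config, xp)
          pr <- exp(fw$logits - max(fw$logits))
          pr <- pr / sum(pr)
          bl <- bl - log(pr[y[i]])
          dlog <- pr
          dlog[y[i]] <- dlog[y[i]] - 1
          g <- swin_backward(params, meta, config, fw$cache,
                             dlog / length(idx), g)
        }
        losses <- c(losses, bl / length(idx))
        step <- step + 1L
        for (l in seq_along(params)) {
          mstate[[l]] <- b1 * mstate[[l]] + (1 - b1) * g[[l]]
          vstate[[l]] <- b2 * vstate[[l]] + (1 - b2) * g[[l]]^2
          mh <- mstate[[l]] / (1 - b1^step)
          vh <- vstate[[l]] / (1 - b2^step)
          wd <- if (decayed[l]) config$weight_decay * params[[l]] else 0
          params[[l]] <- params[[l]] -
            config$lr * (mh / (sqrt(vh) + eps) + wd)
        }
      }
      val_pred <- vapply(va, function(i) {
        xp <- cls_preprocess(frames[[i]], config, meta, train = FALSE)
        which.max(swin_forward(params, meta, config, xp)$logits)
      }, integer(1))
      val_acc <- mean(val_pred == y[va])
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val acc %.4f", ep,
                        mean(losses), val_acc))
      if (val_acc > best$acc)
        best <- list(acc = val_acc, params = params, epoch = ep)
    }
    structure(list(params = best$params, best_val_acc = best$acc,
                   best_epoch = best$epoch, config = config, meta = meta,
                   split = sp, history = hist),
              class = "blink_swin")
  })
}

#' @export
print.blink_swin <- function(x, ...) {
  cat(sprintf(
    "Windowed-attention frame classifier: embed %d, depths %s, input %d\n",
    x$config$embed, paste(x$config$depths, collapse = ","),
    x$config$input_size))
  cat(sprintf("  trained %d epochs; best validation accuracy %.4f (epoch %d)\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' Classify one frame as open or closed
#'
#' @param model A `"blink_swin"` from [train_classifier()].
#' @param image Grayscale matrix in `[0, 1]`.
#' @return List of class `"frame_label"` with `state` (`"existence"` or
#'   `"disappearance"`) and `confidence` (the normalized score of the
#'   predicted state, in `[0.5, 1]` for two classes).
#' @export
classify_frame <- function(model, image) {
  if (!inherits(model, "blink_swin") || is.null(model$params))
    stopf("model is not a trained frame classifier")
  xp <- cls_preprocess(image, model$config, model$meta, train = FALSE)
  logits <- swin_forward(model$params, model$meta, model$config, xp)$logits
  pr <- exp(logits - max(logits))
  pr <- pr / sum(pr)
  structure(list(state = CLS_STATES[which.max(pr)], confidence = max(pr)),
            class = "frame_label")
}

#' @export
print.frame_label <- function(x, ...) {
  cat(sprintf("palpebral fissure %s (%.0f%% confidence)\n", x$state,
              100 * x$confidence))
  invisible(x)
}

#' @export
predict.blink_swin <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(classify_frame(object, newdata))
  lapply(newdata, classify_frame, model = object)
}

#' Correct the IPH with the frame classifier's verdict
#'
#' A frame classified as palpebral-fissure disappearance has its IPH set to
#' zero regardless of the segmentation output (spurious residual foreground
#' on closed eyes is the dominant segmentation failure mode); all other
#' frames are left unchanged. The operation is idempotent.
#'
#' @param label Per-frame state(s): a `"frame_label"`, or a character vector
#'   of `"existence"`/`"disappearance"`.
#' @param iph_px Non-negative IPH value(s) in pixels, recycled against
#'   `label`.
#' @return Corrected IPH value(s).
#' @examples
#' correct_iph("disappearance", 37) # 0
#' correct_iph("existence", 37)     # 37
#' @export
correct_iph <- function(label, iph_px) {
  if (inherits(label, "frame_label")) label <- label$state
  if (!all(label %in% CLS_STATES))
    stopf("label must be 'existence' or 'disappearance'")
  if (any(iph_px < 0)) stopf("iph_px must be >= 0")
  ifelse(label == "disappearance", 0, iph_px)
}

#' Frame-classification performance metrics
#'
#' Confusion-matrix metrics with palpebral-fissure \emph{disappearance} as
#' the positive class: accuracy, precision, sensitivity, specificity, and
#' F1 (the harmonic mean of precision and sensitivity).
#'
#' @param pred,truth Equal-length character vectors of
#'   `"existence"`/`"disappearance"` states.
#' @return List of class `"cls_metrics"` with `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1` and the 2x2 `counts`.
#' @examples
#' evaluate_frame_classification(
#'   rep(c("disappearance", "existence"), c(3, 7)),
#'   rep(c("disappearance", "existence"), c(4, 6)))
#' @export
evaluate_frame_classification <- function(pred, truth) {
  if (length(pred) == 0) stopf("empty input")
  if (length(pred) != length(truth)) stopf("pred and truth must be aligned")
  pos <- "disappearance"
  tp <- sum(pred == pos & truth == pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  structure(list(accuracy = (tp + tn) / length(pred), precision = prec,
                 sensitivity = sens, specificity = spec,
                 f1 = f1_score(prec, sens),
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "cls_metrics")
}

#' Harmonic mean of precision and sensitivity
#'
#' @param precision,sensitivity Values in `[0, 1]`.
#' @return The F1 score `2 * P * S / (P + S)`.
#' @examples
#' f1_score(0.9646, 0.9810) # 0.9727
#' @export
f1_score <- function(precision, sensitivity) {
  if (anyNA(c(precision, sensitivity))) return(NA_real_)
  if (precision + sensitivity == 0) return(0)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' @export
print.cls_metrics <- function(x, ...) {
  cat(sprintf(
    "Frame classification (positive = disappearance):\n  accuracy %.4f  precision %.4f  sensitivity %.4f  specificity %.4f  F1 %.4f\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}
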