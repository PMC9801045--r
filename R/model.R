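# The hybrid accessibility model: a densely connected convolutional branch
# over one-hot sequence, concatenated with the fused motif-by-expression TF
# vector, followed by a fully connected head.  Classification ends in a
# sigmoid with binary cross-entropy; regression ends in a linear output with
# mean squared error.

#' Configuration of the hybrid accessibility network
#'
#' The sequence branch starts with a transition module (a wide convolution of
#' `first_kernels` kernels spanning all four bases over `first_kernel_size`
#' positions, followed by max pooling), then `n_blocks` dense blocks of
#' `layers_per_block` convolutional layers each.  Within a dense block every
#' layer receives the channel-wise concatenation of the block input and all
#' preceding layer outputs; a layer is a 1x1 bottleneck convolution (to
#' `bottleneck_factor * growth_rate` channels) followed by a 3x1 convolution
#' emitting `growth_rate` channels.  Transition modules between blocks halve
#' the channels with a 1x1 convolution and max-pool positions.  ReLU follows
#' every convolution, with batch normalization and dropout after each ReLU.
#'
#' @param first_kernels Number of kernels in the first convolution (default
#'   160; each kernel spans 4 bases x `first_kernel_size` positions).
#' @param first_kernel_size Width in bp of the first-layer kernels (15).
#' @param n_blocks Number of dense blocks (3).
#' @param layers_per_block Convolutional layers per block (5).
#' @param growth_rate Channels added by each dense-block layer (16).
#' @param bottleneck_factor The 1x1 bottleneck reduces concatenated channels
#'   to `bottleneck_factor * growth_rate` (4).
#' @param pool_widths Max-pooling widths of the three transition modules.
#' @param dropout_rate Dropout probability after each ReLU (0.2).
#' @param hidden_units Width of the fully connected hidden layer (256).
#' @param seq_len Length in bp of the one-hot encoded input window (1000).
#' @param head How sequence-branch positions enter the fully connected
#'   head: `"flatten"` keeps channel x position features (position aware,
#'   the default), `"gap"` global-average-pools positions.
#' @param task `"classification"` (sigmoid output, cross-entropy loss) or
#'   `"regression"` (linear output, mean squared error).
#' @param ablation `"full"`, `"no_expression"` (expression replaced by ones,
#'   so the fused vector equals the motif scores), `"no_motif"` (motif scores
#'   replaced by ones), or `"resnet_backbone"` (residual instead of dense
#'   connectivity, same layer count).
#' @return A `chromdense_config` list.
#' @export
model_config <- function(first_kernels = 160L, first_kernel_size = 15L,
                         n_blocks = 3L, layers_per_block = 5L,
                         growth_rate = 16L, bottleneck_factor = 4L,
                         pool_widths = c(4L, 4L, 4L), dropout_rate = 0.2,
                         hidden_units = 256L, seq_len = 1000L,
                         head = c("flatten", "gap"),
                         task = c("classification", "regression"),
                         ablation = c("full", "no_expression", "no_motif",
                                      "resnet_backbone")) {
  task <- match.arg(task)
  head <- match.arg(head)
  ablation <- match.arg(ablation)
  stopifnot(n_blocks >= 1L, layers_per_block >= 1L, first_kernels >= 1L,
            first_kernel_size >= 1L, growth_rate >= 1L, seq_len >= 1L,
            hidden_units >= 1L, length(pool_widths) == n_blocks,
            all(pool_widths >= 1L), dropout_rate >= 0, dropout_rate < 1)
  structure(list(first_kernels = as.integer(first_kernels),
                 first_kernel_size = as.integer(first_kernel_size),
                 n_blocks = as.integer(n_blocks),
                 layers_per_block = as.integer(layers_per_block),
                 growth_rate = as.integer(growth_rate),
                 bottleneck_factor = as.integer(bottleneck_factor),
                 pool_widths = as.integer(pool_widths),
                 dropout_rate = dropout_rate,
                 hidden_units = as.integer(hidden_units),
                 seq_len = as.integer(seq_len),
                 head = head, task = task, ablation = ablation),
            class = "chromdense_config")
}

#' Build the hybrid network
#'
#' Initializes all trainable parameters for the given configuration.  Weight
#' initialization draws from the current R random stream, so seed with
#' [set.seed()] for reproducible models.
#'
#' @param config A [model_config()] object.
#' @param n_tfs Length of the fused TF feature vector.
#' @return A `chromdense_model` with untrained parameters.
#' @export
build_model <- function(config, n_tfs) {
  stopifnot(inherits(config, "chromdense_config"), n_tfs >= 1L)
  n_tfs <- as.integer(n_tfs)
  params <- list()
  buffers <- list()
  add_cu <- function(name, cin, cout, k) {
    params[[name]] <<- nn_init_conv(cin, cout, k)
    bn <- paste0(name, ".bn")
    params[[bn]] <<- nn_init_bn(cout)
    buffers[[bn]] <<- list(mean = rep(0, cout), var = rep(1, cout))
  }
  C <- config$first_kernels
  add_cu("conv0", 4L, C, config$first_kernel_size)
  P <- (config$seq_len - config$first_kernel_size + 1L) %/% config$pool_widths[1]
  if (P < 1L) stop("pooling leaves no spatial positions after first transition")
  g <- config$growth_rate
  m <- config$bottleneck_factor * g
  resnet <- config$ablation == "resnet_backbone"
  for (b in seq_len(config$n_blocks)) {
    for (j in seq_len(config$layers_per_block)) {
      if (resnet) {
        add_cu(sprintf("b%dl%d.bott", b, j), C, m, 1L)
        add_cu(sprintf("b%dl%d.conv", b, j), m, C, 3L)
      } else {
        add_cu(sprintf("b%dl%d.bott", b, j), C + (j - 1L) * g, m, 1L)
        add_cu(sprintf("b%dl%d.conv", b, j), m, g, 3L)
      }
    }
    if (!resnet) C <- C + config$layers_per_block * g
    if (b < config$n_blocks) {
      add_cu(sprintf("t%d", b), C, C %/% 2L, 1L)
      C <- C %/% 2L
      P <- P %/% config$pool_widths[b + 1L]
      if (P < 1L) stop("pooling leaves no spatial positions; reduce pool_widths")
    }
  }
  n_seq_feats <- if (config$head == "flatten") C * P else C
  params$fc1 <- nn_init_dense(n_seq_feats + n_tfs, config$hidden_units)
  params$fc2 <- nn_init_dense(config$hidden_units, 1L)
  structure(list(config = config, n_tfs = n_tfs, seq_channels = C,
                 params = params, buffers = buffers, history = NULL),
            class = "chromdense_model")
}

#' @export
print.chromdense_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, 0L))
  cat(sprintf(paste0("chromdense %s model (%s backbone): %d blocks x %d ",
                     "layers, growth %d,\n  first conv %d kernels of 4x%d, ",
                     "%d TFs, %d parameters\n"),
              cfg$task,
              if (cfg$ablation == "resnet_backbone") "residual" else "dense",
              cfg$n_blocks, cfg$layers_per_block, cfg$growth_rate,
              cfg$first_kernels, cfg$first_kernel_size, x$n_tfs, n_par))
  invisible(x)
}

## ---- composite conv unit: conv -> ReLU -> batch norm -> dropout ----------

post_fw <- function(model, name, y, mode) {
  bn <- paste0(name, ".bn")
  p <- model$params[[bn]]
  buf <- model$buffers[[bn]]
  r <- cpp_post_fw(y, p$gamma, p$beta, buf$mean, buf$var, 0.1, 1e-5,
                   mode == "train", model$config$dropout_rate)
  if (mode == "train") {
    model$buffers[[bn]] <- list(mean = as.numeric(r$rmean),
                                var = as.numeric(r$rvar))
  }
  list(out = r$out, model = model, cache = r$cache)
}

cu_fw <- function(model, name, x, k, pad, mode) {
  p <- model$params[[name]]
  y <- cpp_conv1d_fw(x, p$W, p$b, k, pad)
  pf <- post_fw(model, name, y, mode)
  list(out = pf$out, model = pf$model,
       cache = list(x = x, k = k, pad = pad, post = pf$cache))
}

acc_grads <- function(old, new) {
  if (is.null(old)) return(new)
  for (nm in names(new)) old[[nm]] <- old[[nm]] + new[[nm]]
  old
}

cu_bw <- function(model, name, cache, gout, grads) {
  bn <- paste0(name, ".bn")
  pb <- cpp_post_bw(gout, cache$post, model$params[[bn]]$gamma)
  grads[[bn]] <- acc_grads(grads[[bn]],
                           list(gamma = as.numeric(pb$ggamma),
                                beta = as.numeric(pb$gbeta)))
  gc <- cpp_conv1d_bw(cache$x, model$params[[name]]$W, pb$gin, cache$k,
                      cache$pad)
  grads[[name]] <- acc_grads(grads[[name]],
                             list(W = gc$gW, b = as.numeric(gc$gb)))
  list(gin = gc$gx, grads = grads)
}

## ---- dense / residual blocks --------------------------------------------

block_fw <- function(model, bi, x, mode) {
  L <- model$config$layers_per_block
  resnet <- model$config$ablation == "resnet_backbone"
  caches <- vector("list", L)
  if (resnet) {
    for (j in seq_len(L)) {
      u1 <- cu_fw(model, sprintf("b%dl%d.bott", bi, j), x, 1L, 0L, mode)
      model <- u1$model
      u2 <- cu_fw(model, sprintf("b%dl%d.conv", bi, j), u1$out, 3L, 1L, mode)
      model <- u2$model
      caches[[j]] <- list(bott = u1$cache, conv = u2$cache)
      x <- cpp_cube_add(x, u2$out)
    }
    return(list(out = x, model = model, caches = caches))
  }
  feats <- list(x)
  for (j in seq_len(L)) {
    xin <- if (j == 1L) x else cpp_cat_channels(feats)
    u1 <- cu_fw(model, sprintf("b%dl%d.bott", bi, j), xin, 1L, 0L, mode)
    model <- u1$model
    u2 <- cu_fw(model, sprintf("b%dl%d.conv", bi, j), u1$out, 3L, 1L, mode)
    model <- u2$model
    caches[[j]] <- list(bott = u1$cache, conv = u2$cache,
                        in_channels = vapply(feats, function(a)
                          cpp_cube_dims(a)[1], 0L))
    feats[[j + 1L]] <- u2$out
  }
  list(out = cpp_cat_channels(feats), model = model, caches = caches)
}

block_bw <- function(model, bi, caches, gout, grads) {
  L <- model$config$layers_per_block
  if (model$config$ablation == "resnet_backbone") {
    g <- gout
    for (j in rev(seq_len(L))) {
      r2 <- cu_bw(model, sprintf("b%dl%d.conv", bi, j), caches[[j]]$conv, g,
                  grads)
      grads <- r2$grads
      r1 <- cu_bw(model, sprintf("b%dl%d.bott", bi, j), caches[[j]]$bott,
                  r2$gin, grads)
      grads <- r1$grads
      g <- cpp_cube_add(g, r1$gin)  # skip connection
    }
    return(list(gin = g, grads = grads))
  }
  cs <- c(caches[[L]]$in_channels,
          cpp_cube_dims(gout)[1] - sum(caches[[L]]$in_channels))
  gfeats <- cpp_split_channels(gout, as.integer(cs))
  for (j in rev(seq_len(L))) {
    r2 <- cu_bw(model, sprintf("b%dl%d.conv", bi, j), caches[[j]]$conv,
                gfeats[[j + 1L]], grads)
    grads <- r2$grads
    r1 <- cu_bw(model, sprintf("b%dl%d.bott", bi, j), caches[[j]]$bott,
                r2$gin, grads)
    grads <- r1$grads
    if (j == 1L) {
      cpp_cube_add_inplace(gfeats[[1L]], r1$gin)
    } else {
      gi <- cpp_split_channels(r1$gin, as.integer(caches[[j]]$in_channels))
      for (i in seq_len(j)) cpp_cube_add_inplace(gfeats[[i]], gi[[i]])
    }
  }
  list(gin = gfeats[[1L]], grads = grads)
}

## ---- full network forward / backward ------------------------------------

# seqs: integer-coded batch x seq_len matrix; Fv: n_tfs x batch matrix.
net_forward <- function(model, seqs, Fv, mode = "eval") {
  cfg <- model$config
  cache <- list(mode = mode)
  p0 <- model$params$conv0
  y0 <- cpp_seqconv_fw(seqs, p0$W, p0$b, cfg$first_kernel_size)
  pf <- post_fw(model, "conv0", y0, mode)
  model <- pf$model
  cache$conv0 <- list(seqs = seqs, post = pf$cache)
  p <- cpp_maxpool_fw(pf$out, cfg$pool_widths[1])
  cache$pool0 <- list(idx = p$idx, in_len = p$in_len)
  x <- p$out
  cache$blocks <- vector("list", cfg$n_blocks)
  cache$trans <- vector("list", cfg$n_blocks - 1L)
  for (b in seq_len(cfg$n_blocks)) {
    bl <- block_fw(model, b, x, mode)
    model <- bl$model
    cache$blocks[[b]] <- bl$caches
    x <- bl$out
    if (b < cfg$n_blocks) {
      u <- cu_fw(model, sprintf("t%d", b), x, 1L, 0L, mode)
      model <- u$model
      pp <- cpp_maxpool_fw(u$out, cfg$pool_widths[b + 1L])
      cache$trans[[b]] <- list(cu = u$cache,
                               pool = list(idx = pp$idx,
                                           in_len = pp$in_len))
      x <- pp$out
    }
  }
  if (cfg$head == "flatten") {
    d <- cpp_cube_dims(x)
    gp <- matrix(cpp_cube_get(x), d[1] * d[2], d[3])
    cache$gap <- d
  } else {
    gp <- cpp_gap_fw(x)
    cache$gap <- cpp_cube_dims(x)[2]
  }
  h <- rbind(gp, Fv)
  cache$n_seq_feats <- nrow(gp)
  d1 <- dense_fw(model$params$fc1, h)
  cache$fc1 <- d1$cache
  r <- relu_fw(d1$out)
  cache$fc1relu <- r$cache
  dr <- dropout_fw(r$out, cfg$dropout_rate, mode)
  cache$fc1drop <- dr$cache
  d2 <- dense_fw(model$params$fc2, dr$out)
  cache$fc2 <- d2$cache
  list(z = as.numeric(d2$out), cache = cache, model = model)
}

# dz: gradient of the objective w.r.t. the linear output, one per example.
net_backward <- function(model, cache, dz) {
  cfg <- model$config
  grads <- list()
  g <- matrix(dz, nrow = 1L)
  r2 <- dense_bw(model$params$fc2, cache$fc2, g)
  grads$fc2 <- r2$grads
  g <- dropout_bw(cache$fc1drop, r2$gin)
  g <- relu_bw(cache$fc1relu, g)
  r1 <- dense_bw(model$params$fc1, cache$fc1, g)
  grads$fc1 <- r1$grads
  ns <- cache$n_seq_feats
  gseq <- r1$gin[seq_len(ns), , drop = FALSE]
  gfused <- r1$gin[-seq_len(ns), , drop = FALSE]
  g <- if (cfg$head == "flatten") {
    d <- cache$gap
    cpp_cube_create(array(gseq, c(d[1], d[2], d[3])))
  } else {
    cpp_gap_bw(gseq, cache$gap)
  }
  for (b in rev(seq_len(cfg$n_blocks))) {
    if (b < cfg$n_blocks) {
      g <- cpp_maxpool_bw(g, cache$trans[[b]]$pool$idx,
                          cache$trans[[b]]$pool$in_len)
      rt <- cu_bw(model, sprintf("t%d", b), cache$trans[[b]]$cu, g, grads)
      grads <- rt$grads
      g <- rt$gin
    }
    rb <- block_bw(model, b, cache$blocks[[b]], g, grads)
    grads <- rb$grads
    g <- rb$gin
  }
  g <- cpp_maxpool_bw(g, cache$pool0$idx, cache$pool0$in_len)
  pb <- cpp_post_bw(g, cache$conv0$post, model$params[["conv0.bn"]]$gamma)
  grads[["conv0.bn"]] <- acc_grads(grads[["conv0.bn"]],
                                   list(gamma = as.numeric(pb$ggamma),
                                        beta = as.numeric(pb$gbeta)))
  gc0 <- cpp_seqconv_bw(cache$conv0$seqs, pb$gin,
                        cfg$first_kernel_size)
  grads[["conv0"]] <- acc_grads(grads[["conv0"]],
                                list(W = gc0$gW, b = as.numeric(gc0$gb)))
  list(grads = grads, gfused = gfused)
}

## ---- loss ----------------------------------------------------------------

#' Training loss
#'
#' Mean binary cross-entropy for the classification task (predictions are
#' probabilities in `(0,1)`), mean squared error for regression.
#'
#' @param pred,target Numeric vectors of equal length.
#' @param task `"classification"` or `"regression"`.
#' @return A scalar loss.
#' @export
model_loss <- function(pred, target, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (length(pred) != length(target)) stop("pred and target lengths differ")
  if (anyNA(pred) || anyNA(target) || any(!is.finite(pred)) ||
      any(!is.finite(target))) {
    stop("non-finite values in loss inputs (training diagnostic)")
  }
  if (task == "regression") {
    mean((pred - target)^2)
  } else {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(target * log(p) + (1 - target) * log(1 - p))
  }
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- optimizer -----------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "replace")
}

adam_step <- function(params, grads, state, t, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      st <- state[[nm]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

## ---- training ------------------------------------------------------------

#' Train the hybrid network
#'
#' Each training example pairs one locus (integer-coded sequence) with one
#' cell type's fused TF vector and that cell type's target.  Optimization is
#' Adam on minibatches; the parameters with the best validation loss are
#' returned.  Fully deterministic given `seed`.
#'
#' @param model An untrained (or warm) [build_model()] object.
#' @param data List with `seq` (n x seq_len integer-coded matrix, 0=N,
#'   1..4=A,C,G,T), `fused` (n x n_tfs matrix), `target` (length-n vector).
#' @param epochs Number of passes over the training data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling shuffling, dropout and the
#'   validation split.
#' @param validation_frac Fraction of examples held out to select the best
#'   checkpoint; 0 selects by training loss.
#' @param pos_weight Weight on positive examples in the classification loss
#'   (1 = unweighted despite class imbalance).
#' @param verbose Print per-epoch losses.
#' @return The model with trained parameters and a `history` data frame.
#' @export
train_model <- function(model, data, epochs = 10L, batch_size = 64L,
                        lr = 1e-3, seed = 1L, validation_frac = 0.1,
                        pos_weight = 1, verbose = FALSE) {
  stopifnot(inherits(model, "chromdense_model"))
  n <- nrow(data$seq)
  if (is.null(n) || n == 0L) stop("empty training set")
  stopifnot(nrow(data$fused) == n, length(data$target) == n,
            ncol(data$fused) == model$n_tfs,
            ncol(data$seq) == model$config$seq_len)
  set.seed(seed)
  classification <- model$config$task == "classification"
  # condition the fused TF input: center per dimension, but scale by one
  # pooled standard deviation so gradients remain comparable across TFs
  # (training statistics are stored with the model and re-applied at
  # prediction time)
  if (is.null(model$fused_center)) {
    model$fused_center <- colMeans(data$fused)
    pooled <- sqrt(mean(apply(data$fused, 2, var)))
    model$fused_scale <- rep(max(pooled, 1e-6), ncol(data$fused))
  }
  data$fused <- scale_fused(model, data$fused)
  idx <- sample.int(n)
  n_val <- floor(validation_frac * n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- if (n_val > 0) idx[-seq_len(n_val)] else idx
  state <- adam_init(model$params)
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, buffers = model$buffers)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0
    n_seen <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
      B <- length(bidx)
      Xs <- data$seq[bidx, , drop = FALSE]
      Fv <- t(data$fused[bidx, , drop = FALSE])
      y <- data$target[bidx]
      fw <- net_forward(model, Xs, Fv, mode = "train")
      model <- fw$model
      z <- fw$z
      if (classification) {
        p <- sigmoid(z)
        w <- ifelse(y > 0, pos_weight, 1)
        bloss <- -mean(w * (y * log(pmax(p, 1e-12)) +
                            (1 - y) * log(pmax(1 - p, 1e-12))))
        dz <- w * (p - y) / B
      } else {
        bloss <- mean((z - y)^2)
        dz <- 2 * (z - y) / B
      }
      if (!is.finite(bloss)) stop("training diverged: non-finite loss")
      bw <- net_backward(model, fw$cache, dz)
      t_step <- t_step + 1L
      up <- adam_step(model$params, bw$grads, state, t_step, lr)
      model$params <- up$params
      state <- up$state
      ep_loss <- ep_loss + bloss * B
      n_seen <- n_seen + B
      cpp_pool_reset()
    }
    ep_loss <- ep_loss / n_seen
    vloss <- if (n_val > 0) {
      vp <- predict_model(model, data$seq[val_idx, , drop = FALSE],
                          data$fused[val_idx, , drop = FALSE],
                          batch_size = batch_size, .standardized = TRUE)
      model_loss(vp, data$target[val_idx], model$config$task)
    } else ep_loss
    if (vloss <= best$loss) {
      best <- list(loss = vloss, params = model$params,
                   buffers = model$buffers)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vloss))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss, vloss))
    }
  }
  model$params <- best$params
  model$buffers <- best$buffers
  model$history <- hist
  model
}

#' Predict accessibility for (sequence, fused vector) pairs
#'
#' Runs the network in evaluation mode (dropout off, batch normalization on
#' running statistics), so predictions are invariant to how examples are
#' batched.
#'
#' @param model Trained model.
#' @param seq n x seq_len integer-coded sequence matrix (see
#'   [encode_sequences()]).
#' @param fused n x n_tfs fused feature matrix.
#' @param batch_size Examples per forward pass.
#' @return Numeric vector of length n: probabilities for classification,
#'   unconstrained signals for regression.
#' @export
predict_model <- function(model, seq, fused, batch_size = 64L,
                          .standardized = FALSE) {
  stopifnot(inherits(model, "chromdense_model"))
  if (is.null(dim(seq))) seq <- matrix(seq, nrow = 1L)
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
  if (!.standardized) fused <- scale_fused(model, fused)
  n <- nrow(seq)
  stopifnot(nrow(fused) == n, ncol(fused) == model$n_tfs,
            ncol(seq) == model$config$seq_len)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    Fv <- t(fused[bidx, , drop = FALSE])
    out[bidx] <- net_forward(model, seq[bidx, , drop = FALSE], Fv,
                             mode = "eval")$z
    cpp_pool_reset()
  }
  if (model$config$task == "classification") sigmoid(out) else out
}

# Per-example gradient of the predicted accessibility w.r.t. the fused TF
# input, in evaluation mode.  Returns an n x n_tfs matrix.
fused_input_gradient <- function(model, seq, fused, batch_size = 64L) {
  if (is.null(dim(seq))) seq <- matrix(seq, nrow = 1L)
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
  fused <- scale_fused(model, fused)
  n <- nrow(seq)
  out <- matrix(0, n, model$n_tfs)
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    Fv <- t(fused[bidx, , drop = FALSE])
    fw <- net_forward(model, seq[bidx, , drop = FALSE], Fv, mode = "eval")
    up <- if (model$config$task == "classification") {
      p <- sigmoid(fw$z)
      p * (1 - p)  # d sigmoid(z) / dz
    } else rep(1, length(fw$z))
    bw <- net_backward(model, fw$cache, up)
    out[bidx, ] <- t(bw$gfused)
    cpp_pool_reset()
  }
  # chain through the stored standardization back to the raw fused input
  if (!is.null(model$fused_scale)) {
    out <- sweep(out, 2, model$fused_scale, `/`)
  }
  out
}

scale_fused <- function(model, fused) {
  if (is.null(model$fused_center)) return(fused)
  sweep(sweep(fused, 2, model$fused_center), 2, model$fused_scale, `/`)
}

#' First-layer convolution kernels
#'
#' @param model A model whose first convolution has kernels spanning all four
#'   bases.
#' @return Array of dimension `(4, kernel_width, n_kernels)`; rows are bases
#'   A, C, G, T.
#' @export
first_layer_kernels <- function(model) {
  W <- model$params$conv0$W
  k <- model$config$first_kernel_size
  n <- nrow(W)
  arr <- array(0, c(4L, k, n),
               dimnames = list(c("A", "C", "G", "T"), NULL, NULL))
  for (i in seq_len(n)) arr[, , i] <- matrix(W[i, ], nrow = 4L)
  arr
}
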