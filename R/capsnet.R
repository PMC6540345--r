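# Capsule-network classifier for 18x18 multiband feature matrices.
#
# Pure-R implementation: convolutions are im2col + BLAS matrix products,
# gradients are hand-derived. During backprop the routing coupling
# coefficients are treated as constants of the final iteration (the
# c-path of earlier iterations carries no gradient); with a single
# routing iteration this treatment is exact.

#' Capsule network configuration
#'
#' Defaults are the largest preset ("model A"): 3x3x256 conv front end,
#' primary capsules from a 3x3 stride-2 conv into 49 spatial capsules of
#' 256 dims, two 32-dim emotion capsules with 3 routing iterations, and a
#' 512/1024/324 reconstruction decoder.
#'
#' @param input_side Side length of the square input (18 for MFMs).
#' @param conv_kernel,conv_filters,conv_stride First convolution (no
#'   padding, ReLU).
#' @param primary_kernel,primary_stride,primary_channels Primary-capsule
#'   convolution (no padding, no activation before the squash).
#' @param primary_capsule_dim Dimension of one primary capsule; must
#'   divide `primary_channels`. Equal to `primary_channels` (default)
#'   gives one capsule per spatial position; smaller values give
#'   `primary_channels / primary_capsule_dim` capsule types per position.
#' @param emotion_capsule_dim,n_classes Output capsule geometry.
#' @param routing_iterations Dynamic-routing iterations (>= 1).
#' @param decoder_units Hidden layer sizes of the reconstruction decoder;
#'   its output layer is fixed at `input_side^2`.
#' @param m_plus,m_minus,lambda_down Margin-loss parameters.
#' @param recon_weight Weight of the reconstruction sum of squares in the
#'   total loss (per batch mean).
#' @param learning_rate Adam step size.
#' @param init_sd Standard deviation of the truncated-normal init of the
#'   capsule transformation matrices.
#' @param seed Seed for parameter initialization and batch shuffling.
#' @return A validated `capsnet_config`.
#' @export
capsnet_config <- function(input_side = 18, conv_kernel = 3,
                           conv_filters = 256, conv_stride = 1,
                           primary_kernel = 3, primary_stride = 2,
                           primary_channels = 256,
                           primary_capsule_dim = primary_channels,
                           emotion_capsule_dim = 32, n_classes = 2,
                           routing_iterations = 3,
                           decoder_units = c(512, 1024),
                           m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5,
                           recon_weight = 5e-4, learning_rate = 1e-3,
                           init_sd = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (m_minus >= m_plus) stop("m_minus must be below m_plus", call. = FALSE)
  if (routing_iterations < 1) stop("routing_iterations must be >= 1", call. = FALSE)
  if (primary_channels %% primary_capsule_dim != 0)
    stop("primary_capsule_dim must divide primary_channels", call. = FALSE)
  side1 <- (input_side - conv_kernel) %/% conv_stride + 1L
  if ((input_side - conv_kernel) %% conv_stride != 0)
    stop("conv geometry does not tile the input", call. = FALSE)
  side2 <- (side1 - primary_kernel) %/% primary_stride + 1L
  if (side2 < 1L) stop("primary conv output is empty", call. = FALSE)
  cfg$conv_side <- as.integer(side1)
  cfg$primary_side <- as.integer(side2)
  cfg$n_types <- as.integer(primary_channels / primary_capsule_dim)
  cfg$n_primary <- as.integer(side2^2 * cfg$n_types)
  cfg$decoder_out <- as.integer(input_side^2)
  structure(cfg, class = "capsnet_config")
}

#' Named configuration presets
#'
#' Presets mirror the model grid explored for MFM classification:
#' `model_1` ... `model_5` vary the conv/primary channel width (32, 128,
#' 256, 384, 512) with 2x16 emotion capsules; `model_A` ... `model_F`
#' vary kernel size, channel width, primary grouping and emotion capsule
#' dimension. `model_A` (3x3x256, (7x7)x256 primary, 2x32) is the
#' reference model.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [capsnet_config()].
#' @return A `capsnet_config`.
#' @export
capsnet_preset <- function(name = c("model_A", "model_B", "model_C",
                                    "model_D", "model_E", "model_F",
                                    "model_1", "model_2", "model_3",
                                    "model_4", "model_5"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    model_1 = list(conv_filters = 32, primary_channels = 32,
                   emotion_capsule_dim = 16),
    model_2 = list(conv_filters = 128, primary_channels = 128,
                   emotion_capsule_dim = 16),
    model_3 = list(conv_filters = 256, primary_channels = 256,
                   emotion_capsule_dim = 16),
    model_4 = list(conv_filters = 384, primary_channels = 384,
                   emotion_capsule_dim = 16),
    model_5 = list(conv_filters = 512, primary_channels = 512,
                   emotion_capsule_dim = 16),
    model_A = list(conv_filters = 256, primary_channels = 256,
                   emotion_capsule_dim = 32),
    model_B = list(conv_kernel = 5, conv_filters = 256,
                   primary_channels = 256, emotion_capsule_dim = 16),
    model_C = list(conv_kernel = 9, conv_filters = 256,
                   primary_channels = 256, primary_capsule_dim = 8,
                   emotion_capsule_dim = 32),
    model_D = list(conv_filters = 128, primary_channels = 128,
                   emotion_capsule_dim = 32),
    model_E = list(conv_kernel = 5, conv_filters = 128,
                   primary_channels = 128, emotion_capsule_dim = 16),
    model_F = list(conv_kernel = 9, conv_filters = 128,
                   primary_channels = 128, primary_capsule_dim = 8,
                   emotion_capsule_dim = 32))
  do.call(capsnet_config, utils::modifyList(args, list(...)))
}

#' Squash nonlinearity
#'
#' Rescales a vector to norm `||s||^2 / (1 + ||s||^2)` while preserving
#' its direction, so short vectors shrink toward 0 and long vectors
#' saturate just below 1. The zero vector maps to itself.
#'
#' @param s Numeric vector, or a matrix whose rows are squashed
#'   independently.
#' @return Object of the same shape.
#' @export
#' @examples
#' sqrt(sum(squash(c(1, 0))^2))  # 0.5
squash <- function(s) {
  if (!all(is.finite(s))) stop("non-finite input to squash", call. = FALSE)
  if (is.matrix(s)) row_squash(s) else as.vector(row_squash(matrix(s, 1L)))
}

row_squash <- function(m) {
  n2 <- rowSums(m^2)
  m * (sqrt(n2) / (1 + n2))
}

# grad wrt s of row_squash, given s and upstream grad g
row_squash_grad <- function(s, g) {
  n2 <- rowSums(s^2)
  n <- sqrt(n2)
  k <- n / (1 + n2)
  kp <- (1 - n2) / (1 + n2)^2
  dot <- rowSums(g * s)
  g * k + s * ifelse(n2 > 1e-24, dot * kp / n, 0)
}

# ---- routing ---------------------------------------------------------------

# Batched routing. uh: [B*n_i, n_j*d_e] with rows ordered sample-fastest,
# lower-capsule slower. Returns coupling c, outputs v (per sample), the
# pre-squash s, and the per-iteration coupling history.
route_batched <- function(uh, B, n_i, n_j, d_e, iterations) {
  grp <- rep_len(seq_len(B), B * n_i)
  jcols <- rep(seq_len(n_j), each = d_e)
  b_log <- matrix(0, B * n_i, n_j)
  c_hist <- vector("list", iterations)
  cc <- s <- v <- NULL
  for (it in seq_len(iterations)) {
    e <- exp(b_log - apply(b_log, 1L, max))
    cc <- e / rowSums(e)
    c_hist[[it]] <- cc
    s <- rowsum(uh * cc[, jcols, drop = FALSE], grp, reorder = FALSE)
    v <- s
    for (j in seq_len(n_j)) {
      cols <- (j - 1L) * d_e + seq_len(d_e)
      v[, cols] <- row_squash(s[, cols, drop = FALSE])
    }
    agree <- uh * v[grp, , drop = FALSE]
    for (j in seq_len(n_j))
      b_log[, j] <- b_log[, j] +
        rowSums(agree[, (j - 1L) * d_e + seq_len(d_e), drop = FALSE])
  }
  list(c = cc, v = v, s = s, c_history = c_hist)
}

#' Dynamic routing by agreement
#'
#' Iteratively assigns coupling coefficients between lower and higher
#' capsules: logits start at zero, each iteration softmaxes them over the
#' higher index, forms each higher capsule's input as the
#' coupling-weighted sum of prediction vectors, squashes it, and
#' increments the logits by the prediction-output dot products.
#'
#' @param u_hat Prediction vectors, array
#'   `[n_lower, n_higher, dim]`.
#' @param iterations Number of routing iterations (>= 1).
#' @return List with `c` (`[n_lower x n_higher]` coupling coefficients of
#'   the final iteration, rows summing to 1), `v` (`[n_higher x dim]`
#'   squashed outputs) and `c_history` (coupling matrices of every
#'   iteration).
#' @export
dynamic_routing <- function(u_hat, iterations = 3) {
  stopifnot(is.array(u_hat), length(dim(u_hat)) == 3L, iterations >= 1)
  n_i <- dim(u_hat)[1]; n_j <- dim(u_hat)[2]; d_e <- dim(u_hat)[3]
  # rows: sample-fastest with B = 1 -> row i, cols (j-1)*d_e + d
  uh <- matrix(aperm(u_hat, c(1L, 3L, 2L)), n_i, n_j * d_e)
  r <- route_batched(uh, 1L, n_i, n_j, d_e, iterations)
  list(c = r$c, v = matrix(as.vector(r$v), n_j, d_e, byrow = TRUE),
       c_history = r$c_history)
}

#' Margin loss on emotion-capsule norms
#'
#' Per class e: `T_e * max(0, m+ - ||v_e||)^2 + lambda * (1 - T_e) *
#' max(0, ||v_e|| - m-)^2`, summed over classes and averaged over the
#' batch.
#'
#' @param v Emotion-capsule outputs: `[B x n_classes]` matrix of norms, or
#'   `[B, n_classes, dim]` array of vectors (norms taken internally).
#' @param targets Integer class labels in `0:(n_classes - 1)`, length B.
#' @param cfg A [capsnet_config()] (supplies `m_plus`, `m_minus`,
#'   `lambda_down`).
#' @return List with `per_class` (`[B x n_classes]` loss terms) and
#'   `margin` (the scalar batch loss).
#' @export
margin_loss <- function(v, targets, cfg) {
  vn <- if (length(dim(v)) == 3L) sqrt(apply(v^2, c(1L, 2L), sum)) else v
  if (!is.matrix(vn)) vn <- matrix(vn, nrow = 1L)
  if (any(targets < 0 | targets >= ncol(vn)))
    stop("target outside the class set", call. = FALSE)
  Tm <- matrix(0, nrow(vn), ncol(vn))
  Tm[cbind(seq_len(nrow(vn)), targets + 1L)] <- 1
  per <- Tm * pmax(0, cfg$m_plus - vn)^2 +
    cfg$lambda_down * (1 - Tm) * pmax(0, vn - cfg$m_minus)^2
  list(per_class = per, margin = sum(per) / nrow(vn))
}

#' Combine margin and reconstruction losses
#'
#' @param loss_terms List with `margin` (scalar) and `reconstruction`
#'   (batch-mean reconstruction sum of squares).
#' @param cfg A [capsnet_config()] (supplies `recon_weight`).
#' @return Scalar total loss.
#' @export
total_loss <- function(loss_terms, cfg) {
  loss_terms$margin + cfg$recon_weight * loss_terms$reconstruction
}

# ---- parameters ------------------------------------------------------------

trunc_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# im2col gather index: for an n x n input (row-major flat), k x k kernel,
# given stride; rows = output positions (row-major), cols = taps.
im2col_index <- function(n, k, stride) {
  n_out <- (n - k) %/% stride + 1L
  idx <- matrix(0L, n_out^2, k^2)
  p <- 0L
  for (r in seq_len(n_out)) for (cc in seq_len(n_out)) {
    p <- p + 1L
    t0 <- 0L
    for (kr in seq_len(k)) for (kc in seq_len(k)) {
      t0 <- t0 + 1L
      idx[p, t0] <- (stride * (r - 1L) + kr - 1L) * n +
        stride * (cc - 1L) + kc
    }
  }
  idx
}

#' Initialize a capsule network model
#'
#' @param cfg A [capsnet_config()].
#' @return A `capsnet` model object holding the config, parameters and an
#'   empty optimizer state.
#' @export
capsnet_init <- function(cfg) {
  stopifnot(inherits(cfg, "capsnet_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(cfg$seed)
  Fd <- cfg$conv_filters
  k1 <- cfg$conv_kernel^2
  k2 <- cfg$primary_kernel^2 * Fd
  dio <- cfg$n_classes * cfg$emotion_capsule_dim
  W <- array(trunc_normal(cfg$primary_capsule_dim * dio * cfg$n_primary,
                          cfg$init_sd),
             c(cfg$primary_capsule_dim, dio, cfg$n_primary))
  du <- cfg$decoder_units
  params <- list(
    K1 = he_init(k1, Fd), b1 = numeric(Fd),
    K2 = he_init(k2, cfg$primary_channels), b2 = numeric(cfg$primary_channels),
    W = W,
    Wd1 = he_init(dio, du[1]), bd1 = numeric(du[1]),
    Wd2 = he_init(du[1], du[2]), bd2 = numeric(du[2]),
    Wd3 = he_init(du[2], cfg$decoder_out, fan_in = du[2]) / sqrt(2),
    bd3 = numeric(cfg$decoder_out))
  structure(list(cfg = cfg, params = params, opt = NULL, log = NULL,
                 idx1 = im2col_index(cfg$input_side, cfg$conv_kernel,
                                     cfg$conv_stride),
                 idx2 = im2col_index(cfg$conv_side, cfg$primary_kernel,
                                     cfg$primary_stride)),
            class = "capsnet")
}

#' @export
print.capsnet <- function(x, ...) {
  cfg <- x$cfg
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<capsnet> %dx%d -> conv %dx%dx%d -> %d primary capsules ",
                     "(%dD) -> %d emotion capsules (%dD), %d routing iter, ",
                     "%s parameters\n"),
              cfg$input_side, cfg$input_side, cfg$conv_side, cfg$conv_side,
              cfg$conv_filters, cfg$n_primary, cfg$primary_capsule_dim,
              cfg$n_classes, cfg$emotion_capsule_dim, cfg$routing_iterations,
              format(np, big.mark = ",")))
  invisible(x)
}

# Flatten MFM input to [B, side^2] row-major.
as_input_matrix <- function(x, side) {
  if (is.list(x) && !is.null(x$mfm)) x <- x$mfm
  if (is.matrix(x) && all(dim(x) == side)) x <- array(x, c(1L, side, side))
  if (is.matrix(x) && ncol(x) == side^2) return(x)
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == side, dim(x)[3] == side)
  matrix(aperm(x, c(1L, 3L, 2L)), dim(x)[1], side^2)
}

# ---- forward / backward ----------------------------------------------------

#' Forward pass of the capsule network
#'
#' @param model A [capsnet_init()] model.
#' @param x Input MFMs: `[B, side, side]` array, a single `side x side`
#'   matrix, an `mfm_set`, or a pre-flattened `[B, side^2]` matrix
#'   (row-major).
#' @param targets Optional integer labels (`0`-based) used to mask the
#'   decoder input during training; when absent the predicted class masks
#'   it.
#' @param keep_cache Keep intermediate activations (used by the training
#'   loop).
#' @return List with `v_norm` (`[B x n_classes]` capsule norms, the class
#'   scores), `v` (`[B, n_classes, dim]` emotion capsules), `coupling`
#'   (final routing coefficients), `recon` (`[B x side^2]`
#'   reconstruction), `shapes` (conv map, primary and emotion capsule
#'   geometry) and, if requested, `cache`.
#' @export
capsnet_forward <- function(model, x, targets = NULL, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  X <- as_input_matrix(x, cfg$input_side)
  B <- nrow(X)
  np1 <- cfg$conv_side^2
  # conv + ReLU
  A <- X[, as.vector(model$idx1), drop = FALSE]
  Xc <- matrix(array(A, c(B, np1, ncol(model$idx1))),
               B * np1, ncol(model$idx1))
  Z1 <- sweep(Xc %*% p$K1, 2L, p$b1, "+")
  A1 <- pmax(Z1, 0)
  # primary conv -> capsules
  nq <- cfg$primary_side^2
  kt <- ncol(model$idx2)
  Fd <- cfg$conv_filters
  Pcol <- matrix(0, B * nq, kt * Fd)
  rows_k <- vector("list", kt)
  for (k in seq_len(kt)) {
    rows_k[[k]] <- rep((model$idx2[, k] - 1L) * B, each = B) +
      rep(seq_len(B), nq)
    Pcol[, (k - 1L) * Fd + seq_len(Fd)] <- A1[rows_k[[k]], , drop = FALSE]
  }
  Z2 <- sweep(Pcol %*% p$K2, 2L, p$b2, "+")
  d_p <- cfg$primary_capsule_dim
  Tt <- cfg$n_types
  u_pre <- if (Tt == 1L) Z2 else
    matrix(aperm(array(Z2, c(B * nq, d_p, Tt)), c(1L, 3L, 2L)),
           B * nq * Tt, d_p)
  u <- row_squash(u_pre)
  # predictions per lower capsule
  d_e <- cfg$emotion_capsule_dim
  n_j <- cfg$n_classes
  n_i <- cfg$n_primary
  UH <- matrix(0, B * n_i, n_j * d_e)
  for (i in seq_len(n_i)) {
    ri <- (i - 1L) * B + seq_len(B)
    UH[ri, ] <- u[ri, , drop = FALSE] %*% p$W[, , i]
  }
  rt <- route_batched(UH, B, n_i, n_j, d_e, cfg$routing_iterations)
  v <- rt$v
  vn <- matrix(0, B, n_j)
  for (j in seq_len(n_j))
    vn[, j] <- sqrt(rowSums(v[, (j - 1L) * d_e + seq_len(d_e),
                              drop = FALSE]^2))
  # decoder, masked by target (training) or prediction (inference)
  msk_class <- if (is.null(targets)) max.col(vn, ties.method = "first") - 1L
               else as.integer(targets)
  msk <- matrix(0, B, n_j)
  msk[cbind(seq_len(B), msk_class + 1L)] <- 1
  dec_in <- v * msk[, rep(seq_len(n_j), each = d_e), drop = FALSE]
  H1 <- pmax(sweep(dec_in %*% p$Wd1, 2L, p$bd1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% p$Wd2, 2L, p$bd2, "+"), 0)
  Y <- 1 / (1 + exp(-sweep(H2 %*% p$Wd3, 2L, p$bd3, "+")))
  out <- list(
    v_norm = vn,
    v = aperm(array(v, c(B, d_e, n_j)), c(1L, 3L, 2L)),
    coupling = rt$c,
    recon = Y,
    shapes = list(conv = c(cfg$conv_side, cfg$conv_side, cfg$conv_filters),
                  primary = c(n_i, d_p),
                  emotion = c(n_j, d_e),
                  decoder_out = cfg$decoder_out))
  if (keep_cache)
    out$cache <- list(X = X, Xc = Xc, Z1 = Z1, A1 = A1, Pcol = Pcol,
                      rows_k = rows_k, Z2 = Z2, u_pre = u_pre, u = u,
                      UH = UH, s = rt$s, v_flat = v, vn = vn, c = rt$c,
                      msk = msk, dec_in = dec_in, H1 = H1, H2 = H2, Y = Y,
                      B = B)
  out
}

# Loss + gradients for one batch; targets 0-based.
capsnet_grad <- function(model, x, targets) {
  cfg <- model$cfg
  p <- model$params
  fw <- capsnet_forward(model, x, targets = targets, keep_cache = TRUE)
  ca <- fw$cache
  B <- ca$B
  n_j <- cfg$n_classes
  d_e <- cfg$emotion_capsule_dim
  n_i <- cfg$n_primary
  ml <- margin_loss(ca$vn, targets, cfg)
  rec_sse <- sum((ca$Y - ca$X)^2) / B
  loss <- total_loss(list(margin = ml$margin, reconstruction = rec_sse), cfg)

  Tm <- matrix(0, B, n_j)
  Tm[cbind(seq_len(B), as.integer(targets) + 1L)] <- 1
  dvn <- (-2 * Tm * pmax(0, cfg$m_plus - ca$vn) +
          2 * cfg$lambda_down * (1 - Tm) * pmax(0, ca$vn - cfg$m_minus)) / B
  dv <- matrix(0, B, n_j * d_e)
  for (j in seq_len(n_j)) {
    cols <- (j - 1L) * d_e + seq_len(d_e)
    vnj <- ca$vn[, j]
    dv[, cols] <- ca$v_flat[, cols] *
      ifelse(vnj > 1e-12, dvn[, j] / vnj, 0)
  }
  # decoder backward
  dY <- (2 * cfg$recon_weight / B) * (ca$Y - ca$X)
  dZ3 <- dY * ca$Y * (1 - ca$Y)
  gWd3 <- crossprod(ca$H2, dZ3); gbd3 <- colSums(dZ3)
  dH2 <- tcrossprod(dZ3, p$Wd3) * (ca$H2 > 0)
  gWd2 <- crossprod(ca$H1, dH2); gbd2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, p$Wd2) * (ca$H1 > 0)
  gWd1 <- crossprod(ca$dec_in, dH1); gbd1 <- colSums(dH1)
  ddec <- tcrossprod(dH1, p$Wd1) * ca$msk[, rep(seq_len(n_j), each = d_e)]
  dv <- dv + ddec
  # through emotion squash (per class block)
  ds <- dv
  for (j in seq_len(n_j)) {
    cols <- (j - 1L) * d_e + seq_len(d_e)
    ds[, cols] <- row_squash_grad(ca$s[, cols, drop = FALSE],
                                  dv[, cols, drop = FALSE])
  }
  # s = sum_i c_ij uh ; c constant
  grp <- rep_len(seq_len(B), B * n_i)
  dUH <- ds[grp, , drop = FALSE] *
    ca$c[, rep(seq_len(n_j), each = d_e), drop = FALSE]
  gW <- array(0, dim(p$W))
  du <- matrix(0, nrow(ca$u), ncol(ca$u))
  for (i in seq_len(n_i)) {
    ri <- (i - 1L) * B + seq_len(B)
    gW[, , i] <- crossprod(ca$u[ri, , drop = FALSE], dUH[ri, , drop = FALSE])
    du[ri, ] <- tcrossprod(dUH[ri, , drop = FALSE], p$W[, , i])
  }
  du_pre <- row_squash_grad(ca$u_pre, du)
  # capsule grouping back to conv channels
  d_p <- cfg$primary_capsule_dim
  Tt <- cfg$n_types
  nq <- cfg$primary_side^2
  dZ2 <- if (Tt == 1L) du_pre else
    matrix(aperm(array(du_pre, c(B * nq, Tt, d_p)), c(1L, 3L, 2L)),
           B * nq, d_p * Tt)
  gK2 <- crossprod(ca$Pcol, dZ2); gb2 <- colSums(dZ2)
  dPcol <- tcrossprod(dZ2, p$K2)
  Fd <- cfg$conv_filters
  dA1 <- matrix(0, nrow(ca$A1), Fd)
  for (k in seq_along(ca$rows_k)) {
    rk <- ca$rows_k[[k]]
    dA1[rk, ] <- dA1[rk, , drop = FALSE] +
      dPcol[, (k - 1L) * Fd + seq_len(Fd), drop = FALSE]
  }
  dZ1 <- dA1 * (ca$Z1 > 0)
  gK1 <- crossprod(ca$Xc, dZ1); gb1 <- colSums(dZ1)
  list(loss = loss, margin = ml$margin, reconstruction = rec_sse,
       v_norm = ca$vn,
       grads = list(K1 = gK1, b1 = gb1, K2 = gK2, b2 = gb2, W = gW,
                    Wd1 = gWd1, bd1 = gbd1, Wd2 = gWd2, bd2 = gbd2,
                    Wd3 = gWd3, bd3 = gbd3))
}

adam_step <- function(model, grads) {
  cfg <- model$cfg
  if (is.null(model$opt))
    model$opt <- list(t = 0L,
                      m = lapply(model$params, function(p) p * 0),
                      v = lapply(model$params, function(p) p * 0))
  o <- model$opt
  o$t <- o$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- cfg$learning_rate * sqrt(1 - b2^o$t) / (1 - b1^o$t)
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    o$m[[nm]] <- b1 * o$m[[nm]] + (1 - b1) * g
    o$v[[nm]] <- b2 * o$v[[nm]] + (1 - b2) * g^2
    model$params[[nm]] <- model$params[[nm]] -
      lr_t * o$m[[nm]] / (sqrt(o$v[[nm]]) + eps)
  }
  model$opt <- o
  model
}

#' Train a capsule network
#'
#' Mini-batch Adam on the margin + weighted reconstruction loss. Batch
#' order is reshuffled every epoch from the model's seed stream.
#'
#' @param model A [capsnet_init()] model.
#' @param x Training MFMs (see [capsnet_forward()] for accepted forms).
#' @param y Integer labels, `0`-based, length = number of samples.
#' @param epochs,batch_size Training schedule (protocol defaults are 400
#'   epochs, batch 40; tests and examples use far less).
#' @param validation Optional `list(x = , y = )` scored after each epoch.
#' @param verbose Print an epoch summary line.
#' @return The trained model; `model$log` holds the per-epoch margin,
#'   reconstruction and (if given) validation accuracy.
#' @export
capsnet_train <- function(model, x, y, epochs = 400, batch_size = 40,
                          validation = NULL, verbose = FALSE) {
  cfg <- model$cfg
  X <- as_input_matrix(x, cfg$input_side)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y >= 0 & y < cfg$n_classes))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(cfg$seed + 104729L)
  n <- nrow(X)
  log_df <- data.frame(epoch = integer(), margin = numeric(),
                       reconstruction = numeric(), val_accuracy = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    m_sum <- r_sum <- 0; nb <- 0L
    for (s0 in seq.int(1L, n, by = batch_size)) {
      bi <- ord[s0:min(s0 + batch_size - 1L, n)]
      gr <- capsnet_grad(model, X[bi, , drop = FALSE], y[bi])
      model <- adam_step(model, gr$grads)
      m_sum <- m_sum + gr$margin; r_sum <- r_sum + gr$reconstruction
      nb <- nb + 1L
    }
    va <- NA_real_
    if (!is.null(validation))
      va <- mean(predict(model, validation$x) == validation$y)
    log_df[ep, ] <- list(ep, m_sum / nb, r_sum / nb, va)
    if (verbose)
      message(sprintf("epoch %d: margin %.4f recon %.2f%s", ep, m_sum / nb,
                      r_sum / nb,
                      if (is.na(va)) "" else sprintf(" val_acc %.3f", va)))
  }
  model$log <- log_df
  model
}

#' Predict classes or capsule norms for MFMs
#'
#' @param object A trained `capsnet`.
#' @param x MFMs (see [capsnet_forward()]).
#' @param type `"class"` for 0-based labels (argmax of emotion-capsule
#'   norms), `"norm"` for the `[B x n_classes]` norm matrix.
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return Integer vector or numeric matrix.
#' @export
predict.capsnet <- function(object, x, type = c("class", "norm"),
                            batch_size = 256, ...) {
  type <- match.arg(type)
  X <- as_input_matrix(x, object$cfg$input_side)
  out <- matrix(0, nrow(X), object$cfg$n_classes)
  for (s0 in seq.int(1L, nrow(X), by = batch_size)) {
    bi <- s0:min(s0 + batch_size - 1L, nrow(X))
    out[bi, ] <- capsnet_forward(object, X[bi, , drop = FALSE])$v_norm
  }
  if (type == "norm") out else max.col(out, ties.method = "first") - 1L
}
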