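# Binary-weight 1D convolutional network for heartbeat-template
# identification, written in plain R on top of BLAS matrix products.
#
# Architecture: conv(16 filters, width 7, full precision) -> ReLU -> pool 2
#            -> conv(32, width 5, binarized weights) -> ReLU -> pool 2
#            -> dense(64, binarized) -> ReLU -> dense(C, full precision)
#            -> softmax.
# Hidden weights are binarized in the forward pass as sign(W) scaled by the
# mean absolute latent weight per output unit; gradients pass straight
# through where |W| <= 1 and latent weights are clipped to [-1, 1] — keeping
# the first and last layers full precision is standard binary-network
# practice. Training is minibatch Adam on the softmax cross-entropy.

binarize <- function(W) {
  s <- sign(W); s[s == 0] <- 1
  alpha <- colMeans(abs(W))
  sweep(s, 2, alpha, "*")
}

# im2col: (N, L, C) array -> (N*L_out) x (k*C) matrix, rows ordered with the
# batch index fastest so array(Y, c(N, L_out, F)) restores the layout.
im2col <- function(X, k) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  L_out <- L - k + 1L
  M <- matrix(0, N * L_out, k * C)
  for (c in seq_len(C)) for (j in seq_len(k))
    M[, (c - 1L) * k + j] <- as.vector(X[, j:(j + L_out - 1L), c])
  M
}

col2im <- function(dM, N, L, C, k) {
  L_out <- L - k + 1L
  dX <- array(0, c(N, L, C))
  for (c in seq_len(C)) for (j in seq_len(k))
    dX[, j:(j + L_out - 1L), c] <- dX[, j:(j + L_out - 1L), c] +
      matrix(dM[, (c - 1L) * k + j], N, L_out)
  dX
}

pool2_forward <- function(X) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  P <- L %/% 2L
  a <- X[, seq_len(P) * 2L - 1L, , drop = FALSE]
  b <- X[, seq_len(P) * 2L, , drop = FALSE]
  list(out = pmax(a, b), take_first = a >= b)
}

pool2_backward <- function(dY, take_first, L) {
  N <- dim(dY)[1]; P <- dim(dY)[2]; C <- dim(dY)[3]
  dX <- array(0, c(N, L, C))
  dX[, seq_len(P) * 2L - 1L, ] <- dY * take_first
  dX[, seq_len(P) * 2L, ] <- dY * !take_first
  dX
}

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^t)
  vh <- state$v / (1 - beta2^t)
  state$delta <- lr * mh / (sqrt(vh) + eps)
  state
}

bcnn_forward <- function(net, X, keep = FALSE) {
  N <- nrow(X)
  A0 <- array(X, c(N, ncol(X), 1L))
  M1 <- im2col(A0, net$k1)
  Z1 <- sweep(M1 %*% net$W1, 2, net$b1, "+")
  A1 <- array(pmax(Z1, 0), c(N, net$L1, net$f1))
  P1 <- pool2_forward(A1)
  W2b <- binarize(net$W2)
  M2 <- im2col(P1$out, net$k2)
  Z2 <- sweep(M2 %*% W2b, 2, net$b2, "+")
  A2 <- array(pmax(Z2, 0), c(N, net$L2, net$f2))
  P2 <- pool2_forward(A2)
  Fl <- matrix(P2$out, N, net$P2 * net$f2)
  Wdb <- binarize(net$Wd)
  Zd <- sweep(Fl %*% Wdb, 2, net$bd, "+")
  Ad <- pmax(Zd, 0)
  Zo <- sweep(Ad %*% net$Wo, 2, net$bo, "+")
  Zo <- Zo - apply(Zo, 1, max)
  P <- exp(Zo) / rowSums(exp(Zo))
  if (!keep) return(list(prob = P))
  list(prob = P, A0 = A0, M1 = M1, Z1 = Z1, P1 = P1, W2b = W2b, M2 = M2,
       Z2 = Z2, P2 = P2, Fl = Fl, Wdb = Wdb, Zd = Zd, Ad = Ad)
}

#' Train the binary-weight 1D CNN
#'
#' @param x Standardized template matrix (one template per row); templates
#'   are expected to have been quantized to 8-bit before standardization.
#' @param y Factor of subject labels.
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @param epochs Training epochs (default 30).
#' @param lr Adam learning rate.
#' @param batch Minibatch size.
#' @param f1,k1,f2,k2,hidden Architecture: filters/width of the two
#'   convolution layers and the binarized dense width.
#' @return A fitted network usable with [bcnn_predict()].
#' @export
bcnn_train <- function(x, y, seed = 1, epochs = 30, lr = 0.01, batch = 32,
                       f1 = 16, k1 = 7, f2 = 32, k2 = 5, hidden = 64) {
  y <- droplevels(as.factor(y))
  C <- nlevels(y)
  L <- ncol(x)
  N <- nrow(x)
  L1 <- L - k1 + 1L; P1 <- L1 %/% 2L
  L2 <- P1 - k2 + 1L; P2 <- L2 %/% 2L
  if (P2 < 1) stop("templates too short for the network architecture")
  with_seed(seed, {
    init <- function(nr, nc) matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
    net <- list(k1 = k1, f1 = f1, k2 = k2, f2 = f2, L1 = L1, L2 = L2,
                P1 = P1, P2 = P2, levels = levels(y),
                W1 = init(k1, f1), b1 = numeric(f1),
                W2 = init(k2 * f1, f2), b2 = numeric(f2),
                Wd = init(P2 * f2, hidden), bd = numeric(hidden),
                Wo = init(hidden, C), bo = numeric(C))
    Y <- diag(C)[as.integer(y), , drop = FALSE]
    opt <- lapply(c("W1", "b1", "W2", "b2", "Wd", "bd", "Wo", "bo"),
                  function(p) list(m = net[[p]] * 0, v = net[[p]] * 0))
    names(opt) <- c("W1", "b1", "W2", "b2", "Wd", "bd", "Wo", "bo")
    t_step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (s in seq(1, N, by = batch)) {
        idx <- ord[s:min(N, s + batch - 1L)]
        if (length(idx) < 2) next
        fw <- bcnn_forward(net, x[idx, , drop = FALSE], keep = TRUE)
        nb <- length(idx)
        dZo <- (fw$prob - Y[idx, , drop = FALSE]) / nb
        g <- list()
        g$Wo <- t(fw$Ad) %*% dZo
        g$bo <- colSums(dZo)
        dAd <- dZo %*% t(net$Wo)
        dZd <- dAd * (fw$Zd > 0)
        g$Wd <- (t(fw$Fl) %*% dZd) * (abs(net$Wd) <= 1)   # STE
        g$bd <- colSums(dZd)
        dFl <- dZd %*% t(fw$Wdb)
        dP2 <- array(dFl, c(nb, net$P2, net$f2))
        dA2 <- pool2_backward(dP2, fw$P2$take_first, net$L2)
        dZ2 <- matrix(dA2, nb * net$L2, net$f2) * (fw$Z2 > 0)
        g$W2 <- (t(fw$M2) %*% dZ2) * (abs(net$W2) <= 1)   # STE
        g$b2 <- colSums(dZ2)
        dM2 <- dZ2 %*% t(fw$W2b)
        dP1 <- col2im(dM2, nb, net$P1, net$f1, net$k2)
        dA1 <- pool2_backward(dP1, fw$P1$take_first, net$L1)
        dZ1 <- matrix(dA1, nb * net$L1, net$f1) * (fw$Z1 > 0)
        g$W1 <- t(fw$M1) %*% dZ1
        g$b1 <- colSums(dZ1)
        t_step <- t_step + 1
        for (p in names(g)) {
          opt[[p]] <- adam_step(opt[[p]], g[[p]], lr, t_step)
          net[[p]] <- net[[p]] - opt[[p]]$delta
        }
        net$W2 <- pmin(pmax(net$W2, -1), 1)
        net$Wd <- pmin(pmax(net$Wd, -1), 1)
      }
    }
    class(net) <- "bcnn"
    net
  })
}

#' Predict with a fitted binary-weight CNN
#'
#' @param net Network from [bcnn_train()].
#' @param x Standardized template matrix.
#' @return Factor of predicted labels.
#' @export
bcnn_predict <- function(net, x) {
  P <- bcnn_forward(net, as.matrix(x))$prob
  factor(net$levels[max.col(P, ties.method = "first")], levels = net$levels)
}
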