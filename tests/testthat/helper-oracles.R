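# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops, not the package's vectorized code.

oracle_loss_inb <- function(M, A) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      if (A[i, j] > 0) {
        s <- s + (A[i, j] - M[i, j])^2
        n <- n + 1
      }
    }
  }
  if (n == 0) 0 else s / n
}

oracle_loss_oob <- function(M, A) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      if (A[i, j] == 0) {
        s <- s + M[i, j]^2
        n <- n + 1
      }
    }
  }
  if (n == 0) 0 else s / n
}

oracle_cross_entropy <- function(y, label) {
  y <- min(max(y, 1e-7), 1 - 1e-7)
  -(label * log(y) + (1 - label) * log(1 - y))
}

oracle_total <- function(y, label, M, A, alpha, beta, gamma) {
  alpha * oracle_cross_entropy(y, label) +
    beta * oracle_loss_inb(M, A) + gamma * oracle_loss_oob(M, A)
}

oracle_iou3 <- function(P, A) {
  i <- 0; np <- 0; na <- 0; nu <- 0
  for (k in seq_along(P)) {
    p <- P[k] > 0; a <- A[k] > 0
    if (p && a) i <- i + 1
    if (p) np <- np + 1
    if (a) na <- na + 1
    if (p || a) nu <- nu + 1
  }
  c(iop = if (np == 0) as.numeric(na == 0) else i / np,
    ioa = if (na == 0) as.numeric(np == 0) else i / na,
    iou = if (nu == 0) 1 else i / nu)
}

oracle_confused <- function(M, eps) {
  n <- 0
  for (v in M) if (v >= 0.5 - eps && v <= 0.5 + eps) n <- n + 1
  n
}

# ROC-AUC by explicit pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# Non-interpolated AP by enumerating every distinct confidence cut-point.
oracle_ap <- function(scores, labels) {
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  npos <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (cut in unique(scores)) {
    sel <- scores >= cut
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# All-points interpolated detection AP from per-detection (confidence,
# is-true-positive) pairs plus the number of positives, by enumerating
# recall levels and taking the max precision at recall >= r.
oracle_det_ap <- function(conf, is_tp, n_pos, ids = seq_along(conf)) {
  ord <- order(-conf, ids)
  is_tp <- is_tp[ord]
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  prec <- tp / (tp + fp); rec <- tp / n_pos
  ap <- 0; prev <- 0
  for (k in which(is_tp)) {
    p_int <- max(prec[rec >= rec[k]])
    ap <- ap + (rec[k] - prev) * p_int
    prev <- rec[k]
  }
  ap
}

oracle_rpn_targets <- function(ann, grid, frac = 0.1) {
  cell <- nrow(ann) / grid
  out <- matrix(0L, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      cnt <- 0
      for (r in seq_len(cell)) {
        for (cc in seq_len(cell)) {
          if (ann[(i - 1) * cell + r, (j - 1) * cell + cc] > 0) cnt <- cnt + 1
        }
      }
      out[i, j] <- as.integer(cnt / cell^2 >= frac)
    }
  }
  out
}

# Brute-force point-in-disc raster.
oracle_disc_count <- function(n, center, radius) {
  cnt <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) cnt <- cnt + 1
    }
  }
  cnt
}

random_mask <- function(n, p = 0.3) matrix(rbinom(n * n, 1, p), n, n)
random_prob <- function(n) matrix(runif(n * n), n, n)
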