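## Small in-code fixtures shared across the suite.

## tiny abundance matrix with QC rows and controllable values
tiny_matrix <- function(values, n_qc = 3, qc_values = NULL) {
  p <- ncol(values)
  n <- nrow(values)
  if (is.null(qc_values)) {
    qc_values <- matrix(rep(colMeans(values, na.rm = TRUE), each = n_qc), n_qc, p)
  }
  vals <- rbind(values, qc_values)
  colnames(vals) <- colnames(values) %||% paste0("m", seq_len(p))
  if (any(vals < 0, na.rm = TRUE)) attr(vals, "transformed") <- TRUE
  meta <- data.frame(
    sample_id = c(sprintf("S%02d", seq_len(n)), sprintf("QC%02d", seq_len(n_qc))),
    batch_id = "B1",
    is_qc = c(rep(FALSE, n), rep(TRUE, n_qc)),
    label = c(rep_len(c(1L, 0L), n), rep(NA_integer_, n_qc)))
  abundance_matrix(vals, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standardized two-class feature matrix with `n_signal` shifted features
signal_matrix <- function(n1 = 50, n0 = 50, p = 20, n_signal = 4,
                          shift = 1, seed = 1) {
  set.seed(seed)
  y <- c(rep(1L, n1), rep(0L, n0))
  X <- matrix(rnorm((n1 + n0) * p), n1 + n0, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  if (n_signal > 0) X[y == 1L, seq_len(n_signal)] <-
      X[y == 1L, seq_len(n_signal)] + shift
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  list(X = X, y = y, signal = colnames(X)[seq_len(n_signal)])
}

## brute-force BH step-up adjustment (independent oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

## brute-force AUC by pairwise comparison with ties counted half
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

## factorial-enumeration hypergeometric upper tail (independent oracle)
hyper_oracle <- function(k, K, n, N) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
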