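# Independent oracles used to freeze expected values; each is a direct,
# deliberately naive transcription of the defining computation and never
# shares code with the package.

# Upper-tail overlap probability by exhaustive enumeration of all C(N, n2)
# draws of set2, with set1 fixed as the first n1 universe elements.
enum_overlap_p <- function(k, n1, n2, N) {
  if (n2 == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n2)
  hits <- colSums(draws <= n1)
  mean(hits >= k)
}

# Literal Benjamini-Hochberg step-up adjustment: q_(i) = min_{j >= i} m p_(j)/j.
bh_step_up_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Literal two-stage Benjamini-Krieger-Yekutieli rejection, loop form.
bky_literal <- function(p, fdr) {
  m <- length(p)
  qp <- fdr / (1 + fdr)
  bh_at <- function(alpha) {
    o <- order(p)
    k <- 0L
    for (i in seq_len(m)) if (p[o][i] <= i * alpha / m) k <- i
    rej <- rep(FALSE, m)
    if (k > 0L) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  s1 <- bh_at(qp)
  r1 <- sum(s1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_at(qp * m / (m - r1))
}

# Welch t statistic, Welch-Satterthwaite df and two-sided p, by hand.
welch_hand <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Mixture p-value vectors for FDR property tests.
random_p_vector <- function(m, signal_fraction = 0.2) {
  n_sig <- rbinom(1, m, signal_fraction)
  p <- c(rbeta(n_sig, 0.15, 1), runif(m - n_sig))
  sample(p)
}

sim_fixture_cfg <- function(...) {
  sim_config(n_genes = 400, n_nodes = 6, n_driver_nodes = 1,
             targets_per_node = 25, n_prone_genes = 30,
             n_resistant_genes = 15, background_rate = 0.4, ...)
}
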