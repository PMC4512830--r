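# shared in-code fixtures; everything is generated, nothing is stored

make_labels <- function(n_tumor, n_normal) {
  tibble::tibble(
    sample = c(sprintf("t%02d", seq_len(n_tumor)),
               sprintf("n%02d", seq_len(n_normal))),
    class = rep(c("tumor", "normal"), c(n_tumor, n_normal))
  )
}

# counts with equal library sizes so exact-test oracles are exact
make_balanced_counts <- function(rows, labels) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- labels$sample
  m
}

# brute-force one-sided hypergeometric upper tail from binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  j <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  sum(pmf[j >= k])
}

# brute-force BH step-up: q_i = min over j >= rank(i) of m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# small pathway_activity object built directly from M and S matrices
make_activity <- function(M, S) {
  structure(list(M = M, S = S,
                 pathways = setNames(vector("list", ncol(M)), colnames(M))),
            class = "pathway_activity")
}
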