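# Independent oracles and small fixture builders shared across tests.
# Each oracle is deliberately naive (loops, exhaustive enumeration, direct
# dense linear algebra) so it shares no code path with the implementation.

# Jaccard by element-wise counting over an explicit universe
jaccard_oracle <- function(a, b, universe) {
  n_int <- 0L; n_uni <- 0L
  for (g in universe) {
    ina <- g %in% a; inb <- g %in% b
    if (ina && inb) n_int <- n_int + 1L
    if (ina || inb) n_uni <- n_uni + 1L
  }
  n_int / n_uni
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n2)
# draws; exact because every count is a small integer
hyper_oracle <- function(k, n1, n2, N) {
  if (n2 == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n2)
  overlaps <- colSums(draws <= n1)  # fixed first set = {1..n1}
  mean(overlaps >= k)
}

# regularized discriminant direction by direct dense p x p inversion
chdir_oracle <- function(values, classes, gamma) {
  ctl <- values[, classes == "control", drop = FALSE]
  trt <- values[, classes == "treatment", drop = FALSE]
  d <- rowMeans(trt) - rowMeans(ctl)
  R <- cbind(ctl - rowMeans(ctl), trt - rowMeans(trt))
  S <- R %*% t(R) / (ncol(values) - 2)
  nu <- sum(diag(S)) / nrow(values)
  b <- solve((1 - gamma) * S + gamma * nu * diag(nrow(values)), d)
  if (sum(b * d) < 0) b <- -b
  b / sqrt(sum(b^2))
}

make_experiment <- function(p = 6, n_ctl = 3, n_trt = 3, shift_genes = NULL,
                            shift = 0, sd = 1) {
  genes <- sprintf("g%02d", seq_len(p))
  samples <- c(paste0("c", seq_len(n_ctl)), paste0("t", seq_len(n_trt)))
  m <- matrix(rnorm(p * (n_ctl + n_trt), sd = sd), p,
              dimnames = list(genes, samples))
  cls <- c(rep("control", n_ctl), rep("treatment", n_trt))
  if (!is.null(shift_genes))
    m[shift_genes, cls == "treatment"] <-
      m[shift_genes, cls == "treatment"] + shift
  expression_experiment(m, cls)
}

small_config <- function(seed, ...) {
  synthetic_config(n_genes = 200, n_drugs = 30, conditions_per_drug = 2,
                   n_planted_reversers = 3, planted_moa_size = 6,
                   n_moa_terms = 5, n_bbb_high = 6, seed = seed, ...)
}
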