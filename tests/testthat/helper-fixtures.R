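# Shared fixtures built in code.

# A sharply peaked PFM around a consensus, JASPAR-like 97:1:1:1 columns.
toy_pfm <- function(consensus, id = "TOY", strong = 97, weak = 1) {
  ch <- strsplit(consensus, "")[[1]]
  counts <- matrix(weak, 4L, length(ch),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) counts[ch[j], j] <- strong
  structure(list(id = id, name = id, counts = counts), class = "pfm")
}

# Independent brute-force split-enumeration p-value (plain-probability
# arithmetic, no shared code with nb_test beyond stats::dnbinom).
bruteforce_split_p <- function(counts_a, counts_b, sf_a, sf_b, var_fun) {
  ka <- sum(counts_a); kb <- sum(counts_b); K <- ka + kb
  if (K == 0) return(1)
  q0 <- K / (sum(sf_a) + sum(sf_b))
  v0 <- var_fun(q0)
  extra <- max(v0 - q0, 0)
  dens <- function(x, mu, extra_var, sf) {
    v <- mu + extra_var * sum(sf^2)
    if (v <= mu) dpois(x, mu) else dnbinom(x, mu = mu, size = mu^2 / (v - mu))
  }
  mu_a <- q0 * sum(sf_a); mu_b <- q0 * sum(sf_b)
  probs <- numeric(K + 1)
  for (a in 0:K) {
    probs[a + 1] <- dens(a, mu_a, extra, sf_a) * dens(K - a, mu_b, extra, sf_b)
  }
  pobs <- probs[ka + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)]) / sum(probs)
}

# SSE of an assignment with centroids recomputed from it.
partition_sse <- function(x, assign) {
  sum(vapply(unique(assign), function(cl) {
    sub <- x[assign == cl, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2, ctr)^2)
  }, numeric(1)))
}
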