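# Independent reference implementations ("oracles") used only by tests.
# Each is a deliberately naive, straight-line computation kept free of the
# package's code paths.

# all-pairs SNP x gene scan: a gene is supported by a SNP iff same
# chromosome and pos in [start - window, end + window]
oracle_map_genes <- function(snps, genes, window) {
  hits <- list()
  for (g in seq_len(nrow(genes))) {
    for (s in seq_len(nrow(snps))) {
      if (snps$chrom[s] != genes$chrom[g]) next
      if (snps$pos[s] >= genes$start[g] - window &&
          snps$pos[s] <= genes$end[g] + window) {
        rel <- if (snps$pos[s] >= genes$start[g] &&
                   snps$pos[s] <= genes$end[g]) "in_gene" else
                     "within_window"
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], snp_id = snps$snp_id[s], rel = rel)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(gene_id = character(0), snp_id = character(0),
                      rel = character(0)))
  }
  do.call(rbind, hits)
}

# exhaustive enumeration of all 2x2 tables with fixed margins;
# P(overlap >= x) for X ~ Hypergeometric(universe, candidates, network)
oracle_fisher_right <- function(x, network, candidates, universe) {
  lo <- max(0L, network + candidates - universe)
  hi <- min(network, candidates)
  total <- choose(universe, network)
  p <- 0
  for (k in lo:hi) {
    if (k >= x) {
      p <- p + choose(candidates, k) *
        choose(universe - candidates, network - k) / total
    }
  }
  p
}

# log-space cumulative hypergeometric upper tail via logsumexp of exact
# log point masses (stable for large margins)
oracle_fisher_right_log <- function(x, network, candidates, universe) {
  hi <- min(network, candidates)
  if (x > hi) return(0)
  k <- x:hi
  lp <- dhyper(k, m = candidates, n = universe - candidates, k = network,
               log = TRUE)
  mx <- max(lp)
  exp(mx + log(sum(exp(lp - mx))))
}

# straight-line greedy clumping on a dense r2 matrix
oracle_clump <- function(snp_id, pos, p, r2, window_bp, r2_cut,
                         chrom = NULL) {
  chrom <- chrom %||% rep("1", length(p))
  n <- length(p)
  state <- rep("free", n)
  ord <- order(p, pos, snp_id)
  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    for (j in seq_len(n)) {
      if (state[j] != "free") next
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          r2[i, j] >= r2_cut) {
        state[j] <- "removed"
      }
    }
  }
  idx <- which(state == "index")
  snp_id[idx[order(p[idx], pos[idx], snp_id[idx])]]
}

# textbook iteratively-reweighted least squares for logistic regression
oracle_irls_logistic <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(as.vector(beta_new))
    }
    beta <- as.vector(beta_new)
  }
  beta
}

# dense loop computation of mean beta x dosage scores
oracle_scores <- function(betas, dosages) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(m)) acc <- acc + betas[j] * dosages[i, j]
    out[i] <- acc / m
  }
  out
}

# sorted-loop step-up q-values with a pi0 factor and uncorrected-p floor
oracle_qvalues <- function(p, pi0 = 1) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, pi0 * m * ps[i] / i, 1)
    q[i] <- max(running, ps[i])
  }
  out <- numeric(m)
  out[ord] <- q
  out
}
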