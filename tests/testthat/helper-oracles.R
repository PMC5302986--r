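# Independent brute-force oracles used to cross-check package statistics.

# Two-sided rank-sum p by full enumeration of all C(n1+n2, n1) group
# assignments (tie-free data), with tail doubling.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-up BH by direct definition: adj_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank_j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(o == i)  # rank of p[i]
    r[i] <- min(1, min(m * p[o][k:m] / (k:m)))
  }
  r
}

# AUC as the tie-corrected Mann-Whitney U statistic / (n1 * n0).
oracle_auc_u <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (s in pos) u <- u + sum(s > neg) + 0.5 * sum(s == neg)
  u / (length(pos) * length(neg))
}

# Two-sided Fisher p by hypergeometric tail doubling, direct summation.
oracle_fisher_doubling <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(supp, c1, n - c1, r1)
  min(1, 2 * min(sum(dens[supp <= a]), sum(dens[supp >= a])))
}

# Small deterministic Cp/condition fixture: f features, one reference and
# k resistant conditions with r replicates.
toy_condition_map <- function(conditions = c("parental", "res1", "res2", "res3"),
                              replicates = 3) {
  samples <- as.vector(vapply(conditions, function(cn)
    paste0(cn, "_", seq_len(replicates)), character(replicates)))
  stats::setNames(rep(conditions, each = replicates), samples)
}
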