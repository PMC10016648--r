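# Independent oracles used across the suite. These deliberately avoid the
# code paths (and, where possible, the algorithms) of the implementation.

# Kruskal-Wallis H from the rank-variance definition:
# H = (N-1) * sum_i n_i (rbar_i - rbar)^2 / sum_ij (r_ij - rbar)^2
# (equals the usual tie-corrected H without writing the correction factor)
kw_oracle_h <- function(values, groups) {
  r <- rank(values)
  rbar <- mean(r)
  num <- sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - rbar)^2))
  den <- sum((r - rbar)^2)
  (length(values) - 1) * num / den
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the first group (no ties assumed)
mw_oracle_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  r <- rank(pooled)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Joint-ML ancestral states under Brownian motion via the weighted graph
# Laplacian: minimize sum_e (x_child - x_parent)^2 / len_e over internal
# states with tips fixed. Solves the full linear system explicitly --
# no re-rooting, no GLS mean.
asr_laplacian_oracle <- function(tree, tips) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  x_tip <- as.numeric(tips[tree$tip.label])
  W <- matrix(0, N, N)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    w <- 1 / tree$edge.length[e]
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  L <- diag(rowSums(W)) - W
  int <- (n + 1):N
  a <- solve(L[int, int, drop = FALSE],
             -L[int, seq_len(n), drop = FALSE] %*% x_tip)
  as.numeric(a)
}

# worked sex-difference fixture: published female species means paired with
# the male 1C values printed alongside them in the same survey
printed_sex_fixture <- function() {
  data.frame(
    species = c("Gomphocerippus rufus", "Chorthippus vagans",
                "Pseudochorthippus parallelus", "Schistocerca gregaria",
                "Chorthippus dorsatus", "Myrmeleotettix maculatus"),
    mean_1C_female_pg = c(13.18, 11.11, 13.14, 10.68, 12.59, 11.83),
    mean_1C_male_pg = c(10.66, 8.68, 10.89, 8.55, 12.80, 12.14),
    stringsAsFactors = FALSE)
}
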