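# Independent brute-force oracles and small fixtures shared across tests.
# The oracles enumerate ordered population allele draws directly and never
# reuse the package's likelihood code paths.

# P(unordered genotype g) by double enumeration of ordered draws.
oracle_genotype_prob <- function(g, m) {
  p <- m$freqs
  s <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (identical(sort(c(m$alleles[i], m$alleles[j])), sort(g))) {
      s <- s + p[i] * p[j]
    }
  }
  s
}

# P(G1, G2 | exactly one shared IBD allele): one common draw u plus
# independent draws v (completing G1) and w (completing G2).
oracle_joint_one_ibd <- function(g1, g2, m) {
  p <- m$freqs
  s <- 0
  for (u in seq_along(p)) for (v in seq_along(p)) for (w in seq_along(p)) {
    if (identical(sort(c(m$alleles[u], m$alleles[v])), sort(g1)) &&
        identical(sort(c(m$alleles[u], m$alleles[w])), sort(g2))) {
      s <- s + p[u] * p[v] * p[w]
    }
  }
  s
}

# Pairwise LR via the IBD-state mixture, assembled only from the
# enumeration primitives above.
oracle_pairwise_lr <- function(g1, g2, k, m) {
  p1 <- oracle_genotype_prob(g1, m)
  p2 <- oracle_genotype_prob(g2, m)
  joint <- k[1] * p1 * p2 +
    k[2] * oracle_joint_one_ibd(g1, g2, m) +
    k[3] * p1 * identical(sort(g1), sort(g2))
  joint / (p1 * p2)
}

# All unordered genotypes of a marker, as a list of sorted label pairs.
all_genotypes <- function(m) {
  a <- m$alleles
  out <- list()
  for (i in seq_along(a)) for (j in i:length(a)) {
    out[[length(out) + 1L]] <- sort(c(a[i], a[j]))
  }
  out
}

# Tiny fixed panels used by several tests.
toy_marker2 <- function(p = c(0.5, 0.5)) {
  marker_frequencies("L1", c("8", "9"), p)
}

toy_panel1 <- function(p = c(0.5, 0.5)) {
  frequency_set(str_panel("toy1", "L1"), list(L1 = toy_marker2(p)))
}

toy_panel2 <- function() {
  frequency_set(str_panel("toy2", c("L1", "L2")), list(
    L1 = marker_frequencies("L1", c("8", "9"), c(0.6, 0.4)),
    L2 = marker_frequencies("L2", c("10", "11", "12"), c(0.5, 0.3, 0.2))
  ))
}
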