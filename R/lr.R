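#' @name kinship_lr
#' @title Kinship likelihood ratios
#'
#' @description
#' A kinship likelihood ratio compares the probability of the observed
#' genotypes under the alleged relationship to their probability under
#' unrelatedness. For a pairwise hypothesis with IBD coefficients
#' `(k0, k1, k2)` the per-locus LR is
#' `k0 + k1 * P(G2 | G1, 1 IBD) / P(G2) + k2 * [G1 = G2] / P(G2)`,
#' conditioning on which of the first genotype's alleles is shared
#' identically by descent. For a trio the per-locus LR is the paternity
#' index `P(Gc | Gm, Gaf is father) / P(Gc | Gm, random man is father)`,
#' obtained by enumerating the maternal/paternal assignments of the child's
#' alleles that are consistent with the mother. Loci are treated as
#' unlinked, so the combined LR is the product over loci (accumulated in
#' log10 space).
NULL

# ---- vectorized internals on allele indices -------------------------------
# All .lr_* functions take integer allele-index vectors (parallel over
# cases) plus the marker's frequency vector p, and return per-case LRs.

# HWE genotype probability for index pairs.
.lr_pgeno <- function(y1, y2, p) {
  ifelse(y1 == y2, p[y1]^2, 2 * p[y1] * p[y2])
}

# P(G2 | G1, exactly one allele IBD): the IBD allele is one of G1's two
# alleles with probability 1/2 each; the other allele of G2 is a population
# draw.
.lr_pcond1 <- function(x1, x2, y1, y2, p) {
  f <- function(a) {
    ifelse(y1 == y2,
           (a == y1) * p[y1],
           (a == y1) * p[y2] + (a == y2) * p[y1])
  }
  0.5 * f(x1) + 0.5 * f(x2)
}

# Pairwise LR = k0 + k1*L1 + k2*L2 on canonical (sorted) index pairs.
.lr_pairwise <- function(x1, x2, y1, y2, p, k, mut) {
  sx1 <- pmin(x1, x2); sx2 <- pmax(x1, x2)
  sy1 <- pmin(y1, y2); sy2 <- pmax(y1, y2)
  pg2 <- .lr_pgeno(sy1, sy2, p)
  lr <- k[1] +
    k[2] * .lr_pcond1(sx1, sx2, sy1, sy2, p) / pg2 +
    k[3] * (sx1 == sy1 & sx2 == sy2) / pg2
  if (mut$mode == "rate_floor" && k[2] > 0) {
    z <- lr == 0
    if (any(z)) lr[z] <- k[2] * mut$mu / pg2[z]
  }
  lr
}

# Fraction of a genotype's alleles equal to `a` (Mendelian transmission
# probability 0, 1/2 or 1).
.lr_trans <- function(g1, g2, a) ((g1 == a) + (g2 == a)) / 2

# Trio paternity index.  Maternal incompatibility at a locus falls back to
# the motherless parent-child LR of (child, alleged father).
.lr_trio <- function(m1, m2, c1, c2, f1, f2, p, mut) {
  hom <- c1 == c2
  tm1 <- .lr_trans(m1, m2, c1); tm2 <- .lr_trans(m1, m2, c2)
  tf1 <- .lr_trans(f1, f2, c1); tf2 <- .lr_trans(f1, f2, c2)
  num <- ifelse(hom, tm1 * tf1, tm1 * tf2 + tm2 * tf1)
  den <- ifelse(hom, tm1 * p[c1], tm1 * p[c2] + tm2 * p[c1])
  lr <- num / den
  if (mut$mode == "rate_floor") {
    # paternal exclusion: replace zero paternal transmissions by mu
    z <- which(num == 0 & den > 0)
    if (length(z)) {
      gf1 <- ifelse(tf1[z] > 0, tf1[z], mut$mu)
      gf2 <- ifelse(tf2[z] > 0, tf2[z], mut$mu)
      lr[z] <- ifelse(hom[z], tm1[z] * gf1,
                      tm1[z] * gf2 + tm2[z] * gf1) / den[z]
    }
  }
  bad <- which(den == 0)
  if (length(bad)) {
    lr[bad] <- .lr_pairwise(f1[bad], f2[bad], c1[bad], c2[bad], p,
                            c(0, 1, 0), mut)
  }
  lr
}

# ---- public per-locus API --------------------------------------------------

# Canonicalize a two-allele genotype given as a character vector of labels.
.as_genotype <- function(g) {
  g <- as.character(g)
  if (length(g) != 2L) stop("a genotype is two allele labels", call. = FALSE)
  sort(g)
}

#' Hardy-Weinberg genotype probability
#'
#' `p^2` for a homozygote, `2*p*q` for a heterozygote.
#'
#' @param g genotype: character vector of two allele labels.
#' @param m a [marker_frequencies].
#' @return A probability.
#' @examples
#' m <- marker_frequencies("L", c("a", "b", "c"), c(0.2, 0.3, 0.5))
#' genotype_prob(c("a", "a"), m) # 0.04
#' genotype_prob(c("a", "b"), m) # 0.12
#' @export
genotype_prob <- function(g, m) {
  stopifnot(inherits(m, "marker_frequencies"))
  i <- allele_index(.as_genotype(g), m)
  .lr_pgeno(i[1], i[2], m$freqs)
}

#' Per-locus pairwise likelihood ratio
#'
#' @param g1,g2 genotypes (character vectors of two allele labels) of the
#'   two tested individuals.
#' @param hyp a pairwise [kinship_hypothesis].
#' @param m a [marker_frequencies].
#' @param mut a [mutation_policy].
#' @return The per-locus LR (non-negative).
#' @examples
#' m <- marker_frequencies("L", c("a", "b"), c(0.5, 0.5))
#' pairwise_lr_locus(c("a", "a"), c("a", "a"),
#'                   kinship_hypothesis("full_sib"), m) # 2.25
#' @export
pairwise_lr_locus <- function(g1, g2, hyp, m, mut = mutation_policy()) {
  stopifnot(inherits(hyp, "relationship_hypothesis"),
            inherits(m, "marker_frequencies"),
            inherits(mut, "mutation_policy"))
  if (hyp$kind != "pairwise") {
    stop("pairwise_lr_locus needs a pairwise hypothesis", call. = FALSE)
  }
  i <- allele_index(.as_genotype(g1), m)
  j <- allele_index(.as_genotype(g2), m)
  .lr_pairwise(i[1], i[2], j[1], j[2], m$freqs, hyp$k, mut)
}

#' Per-locus trio paternity index
#'
#' @param gm,gc,gaf genotypes of mother, child, and alleged father.
#' @param m a [marker_frequencies].
#' @param mut a [mutation_policy].
#' @return The per-locus paternity index.
#' @examples
#' m <- marker_frequencies("L", c("a", "b"), c(0.9, 0.1))
#' trio_lr_locus(c("a", "a"), c("a", "b"), c("b", "b"), m) # 1/0.1 = 10
#' @export
trio_lr_locus <- function(gm, gc, gaf, m, mut = mutation_policy()) {
  stopifnot(inherits(m, "marker_frequencies"),
            inherits(mut, "mutation_policy"))
  im <- allele_index(.as_genotype(gm), m)
  ic <- allele_index(.as_genotype(gc), m)
  jf <- allele_index(.as_genotype(gaf), m)
  .lr_trio(im[1], im[2], ic[1], ic[2], jf[1], jf[2], m$freqs, mut)
}

#' Combined multilocus likelihood ratio
#'
#' Multiplies per-locus LRs across the panel, accumulating in log10 space;
#' the combined LR is 0 exactly when some locus LR is 0.
#'
#' @param case a [simulate_case] result.
#' @param hyp a [kinship_hypothesis]; a trio hypothesis requires a trio
#'   case, a pairwise hypothesis a two-person case.
#' @param freqs a [frequency_set].
#' @param mut a [mutation_policy].
#' @return An object of class `lr_result`: list with `per_locus` (named
#'   numeric), `combined`, and `log10_combined` (`-Inf` when combined is 0).
#' @export
combined_lr <- function(case, hyp, freqs, mut = mutation_policy()) {
  stopifnot(inherits(case, "simulated_case"),
            inherits(hyp, "relationship_hypothesis"),
            inherits(freqs, "frequency_set"))
  gt <- case$genotypes
  trio_case <- all(c("mother", "child", "alleged_father") %in% names(gt))
  if (hyp$kind == "trio_paternity" && !trio_case) {
    stop("trio hypothesis requires a trio case", call. = FALSE)
  }
  if (hyp$kind == "pairwise" && trio_case) {
    stop("pairwise hypothesis requires a two-person case", call. = FALSE)
  }
  markers <- freqs$panel$markers
  per_locus <- vapply(markers, function(mk) {
    m <- freqs$per_marker[[mk]]
    if (hyp$kind == "trio_paternity") {
      trio_lr_locus(gt$mother[[mk]], gt$child[[mk]],
                    gt$alleged_father[[mk]], m, mut)
    } else {
      pairwise_lr_locus(gt$person1[[mk]], gt$person2[[mk]], hyp, m, mut)
    }
  }, 0)
  log10_combined <- sum(log10(per_locus))
  structure(list(per_locus = per_locus,
                 combined = if (is.infinite(log10_combined) &&
                                log10_combined < 0) 0
                            else 10^log10_combined,
                 log10_combined = log10_combined),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("Combined LR over %d loci: %.6g (log10 = %.4f)\n",
              length(x$per_locus), x$combined, x$log10_combined))
  invisible(x)
}
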