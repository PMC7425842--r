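# Independent trio oracle: paternity index by direct enumeration of ordered
# maternal/paternal transmissions (numerator) and maternal transmission plus
# a population draw (denominator).
oracle_trio_pi <- function(gm, gc, gaf, m) {
  p <- m$freqs
  num <- 0
  for (ma in gm) for (pa in gaf) {
    if (identical(sort(c(ma, pa)), sort(gc))) num <- num + 0.25
  }
  den <- 0
  for (ma in gm) for (w in seq_along(p)) {
    if (identical(sort(c(ma, m$alleles[w])), sort(gc))) {
      den <- den + 0.5 * p[w]
    }
  }
  c(num = num, den = den)
}

m3 <- marker_frequencies("L", c("a", "b", "c"), c(0.2, 0.3, 0.5))
m4 <- marker_frequencies("L", c("a", "b", "c", "d"),
                         c(0.1, 0.2, 0.3, 0.4))

test_that("genotype probabilities are Hardy-Weinberg", {
  expect_equal(genotype_prob(c("a", "a"), m3), 0.04)
  expect_equal(genotype_prob(c("a", "b"), m3), 0.12)
  expect_equal(genotype_prob(c("b", "a"), m3), 0.12)  # order-free
  total <- sum(vapply(all_genotypes(m3), genotype_prob, 0, m = m3))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(genotype_prob(c("a", "z"), m3), "unknown allele")
})

test_that("worked pairwise examples match hand calculations", {
  m <- toy_marker2()  # two alleles at 0.5/0.5
  fs_hyp <- kinship_hypothesis("full_sib")
  expect_equal(pairwise_lr_locus(c("8", "8"), c("8", "8"), fs_hyp, m),
               2.25)  # 0.25 + 0.5/p + 0.25/p^2
  expect_equal(pairwise_lr_locus(c("a", "a"), c("b", "c"),
                                 kinship_hypothesis("parent_child"), m3),
               0)    # Mendelian exclusion
  expect_equal(pairwise_lr_locus(c("a", "a"), c("b", "c"),
                                 kinship_hypothesis("first_cousin"), m3),
               0.75) # wholly mismatched pair collapses to k0
})

test_that("the unrelated hypothesis always gives LR 1", {
  unrel <- kinship_hypothesis("unrelated")
  for (g1 in all_genotypes(m4)) for (g2 in all_genotypes(m4)) {
    expect_identical(pairwise_lr_locus(g1, g2, unrel, m4), 1)
  }
})

test_that("pairwise LR matches the enumeration oracle on all pairs", {
  presets <- c("parent_child", "full_sib", "half_sib", "first_cousin",
               "unrelated")
  gts <- all_genotypes(m4)
  for (rel in presets) {
    hyp <- kinship_hypothesis(rel)
    for (g1 in gts) for (g2 in gts) {
      expect_equal(pairwise_lr_locus(g1, g2, hyp, m4),
                   oracle_pairwise_lr(g1, g2, hyp$k, m4),
                   tolerance = 1e-12)
    }
  }
})

test_that("pairwise LR is symmetric in the two genotypes", {
  gts <- all_genotypes(m3)
  for (rel in c("parent_child", "full_sib", "half_sib", "first_cousin")) {
    hyp <- kinship_hypothesis(rel)
    for (g1 in gts) for (g2 in gts) {
      expect_equal(pairwise_lr_locus(g1, g2, hyp, m3),
                   pairwise_lr_locus(g2, g1, hyp, m3), tolerance = 1e-12)
    }
  }
})

test_that("custom k vectors are validated", {
  expect_s3_class(kinship_hypothesis(k = c(0.5, 0.25, 0.25)),
                  "relationship_hypothesis")
  expect_error(kinship_hypothesis(k = c(0.5, 0.6, 0.1)), "sum")
  expect_error(kinship_hypothesis(k = c(-0.1, 1, 0.1)), "non-negative")
})

test_that("trio paternity index matches its worked example and oracle", {
  m <- marker_frequencies("L", c("a", "b"), c(0.9, 0.1))
  expect_equal(trio_lr_locus(c("a", "a"), c("a", "b"), c("b", "b"), m), 10)
  expect_equal(trio_lr_locus(c("a", "a"), c("a", "b"), c("c", "c"), m3), 0)

  # every (mother, child, father) combination with a maternally consistent
  # child agrees with direct transmission enumeration
  gts <- all_genotypes(m3)
  for (gm in gts) for (gc in gts) for (gaf in gts) {
    o <- oracle_trio_pi(gm, gc, gaf, m3)
    if (o["den"] > 0) {
      expect_equal(trio_lr_locus(gm, gc, gaf, m3),
                   unname(o["num"] / o["den"]), tolerance = 1e-12)
    }
  }
})

test_that("the paternity index averages to 1 over random alleged fathers", {
  # the denominator is the random-man likelihood, so the HWE-weighted mean
  # of PI over alleged fathers is exactly 1 for any consistent mother/child
  gts <- all_genotypes(m4)
  for (gm in gts) for (gc in gts) {
    o <- oracle_trio_pi(gm, gc, gts[[1]], m4)
    if (o["den"] == 0) next
    e_pi <- sum(vapply(gts, function(gaf) {
      genotype_prob(gaf, m4) * trio_lr_locus(gm, gc, gaf, m4)
    }, 0))
    expect_equal(e_pi, 1, tolerance = 1e-12)
  }
})

test_that("maternal incompatibility falls back to the motherless duo LR", {
  pc <- kinship_hypothesis("parent_child")
  # mother cc cannot have produced child ab: locus treated as a duo
  expect_equal(trio_lr_locus(c("c", "c"), c("a", "b"), c("a", "a"), m3),
               pairwise_lr_locus(c("a", "a"), c("a", "b"), pc, m3),
               tolerance = 1e-12)
})

test_that("the rate floor replaces exclusions with a mu-scaled likelihood", {
  pc <- kinship_hypothesis("parent_child")
  floor_mut <- mutation_policy("rate_floor", mu = 0.002)
  # pairwise exclusion: aa vs bc
  expect_equal(pairwise_lr_locus(c("a", "a"), c("b", "c"), pc, m3,
                                 floor_mut),
               0.002 / (2 * 0.3 * 0.5), tolerance = 1e-12)
  # trio paternal exclusion: father cc cannot give b
  strict <- trio_lr_locus(c("a", "a"), c("a", "b"), c("c", "c"), m3)
  floored <- trio_lr_locus(c("a", "a"), c("a", "b"), c("c", "c"), m3,
                           floor_mut)
  expect_identical(strict, 0)
  expect_equal(floored, 0.002 / 0.3, tolerance = 1e-12)
  expect_error(mutation_policy("rate_floor", mu = 0.02), "0.01")
})

test_that("combined LR obeys the product law", {
  markers <- sprintf("L%02d", 1:15)
  fs <- frequency_set(str_panel("p15", markers), setNames(lapply(
    markers, function(mk) marker_frequencies(mk, c("8", "9"), c(0.5, 0.5))),
    markers))
  gt <- setNames(rep(list(c("8", "8")), 15), markers)
  case <- structure(list(relationship = "parent_child", truth = "related",
                         genotypes = list(person1 = gt, person2 = gt)),
                    class = "simulated_case")
  pc <- kinship_hypothesis("parent_child")
  res <- combined_lr(case, pc, fs)
  expect_equal(unname(res$per_locus), rep(2, 15))   # each locus LR = 1/p = 2
  expect_equal(res$combined, 2^15, tolerance = 1e-9)
  expect_equal(res$log10_combined, 15 * log10(2), tolerance = 1e-12)

  # unrelated hypothesis: all per-locus LRs 1, combined 1
  res1 <- combined_lr(case, kinship_hypothesis("unrelated"), fs)
  expect_equal(res1$combined, 1)

  # one excluding locus annihilates the product
  gt2 <- gt; gt2$L08 <- c("9", "9")
  case2 <- case; case2$genotypes$person2 <- gt2
  res0 <- combined_lr(case2, pc, fs)
  expect_identical(res0$combined, 0)
  expect_identical(res0$log10_combined, -Inf)
})

test_that("combined LR rejects mismatched case/hypothesis structure", {
  fs <- toy_panel2()
  set.seed(120)
  trio <- simulate_case("trio", "related", fs)
  duo <- simulate_case("parent_child", "related", fs)
  expect_error(combined_lr(trio, kinship_hypothesis("parent_child"), fs),
               "two-person")
  expect_error(combined_lr(duo, kinship_hypothesis("trio"), fs), "trio")
})
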