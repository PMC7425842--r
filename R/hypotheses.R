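#' Relationship hypotheses
#'
#' A tested relationship hypothesis is either the trio paternity hypothesis
#' (biological mother, child, alleged father; evaluated with the paternity
#' index) or a pairwise hypothesis summarized by the IBD-sharing
#' probabilities `k = (k0, k1, k2)`: the probabilities that the pair shares
#' 0, 1 or 2 alleles identical by descent at an autosomal locus.
#'
#' Presets: `parent_child` (0,1,0), `full_sib` (1/4,1/2,1/4), `half_sib`
#' (1/2,1/2,0), `first_cousin` (3/4,1/4,0), `unrelated` (1,0,0), and
#' `trio` for the trio paternity hypothesis.
#'
#' @param relationship one of `"trio"`, `"parent_child"`, `"full_sib"`,
#'   `"half_sib"`, `"first_cousin"`, `"unrelated"`.
#' @param k optional numeric `(k0, k1, k2)` for a custom pairwise
#'   hypothesis; must be non-negative and sum to 1.
#' @return An object of class `relationship_hypothesis` with fields `kind`
#'   (`"trio_paternity"` or `"pairwise"`), `relationship`, and `k`
#'   (pairwise only).
#' @examples
#' kinship_hypothesis("full_sib")$k # 0.25 0.50 0.25
#' @export
kinship_hypothesis <- function(relationship = c("trio", "parent_child",
                                                "full_sib", "half_sib",
                                                "first_cousin", "unrelated"),
                               k = NULL) {
  if (!is.null(k)) {
    k <- as.numeric(k)
    if (length(k) != 3L || any(!is.finite(k)) || any(k < 0) ||
        abs(sum(k) - 1) > 1e-9) {
      stop("k must be three non-negative probabilities summing to 1",
           call. = FALSE)
    }
    return(structure(list(kind = "pairwise", relationship = "custom", k = k),
                     class = "relationship_hypothesis"))
  }
  relationship <- match.arg(relationship)
  if (relationship == "trio") {
    return(structure(list(kind = "trio_paternity", relationship = "trio"),
                     class = "relationship_hypothesis"))
  }
  k <- switch(relationship,
    parent_child = c(0, 1, 0),
    full_sib     = c(0.25, 0.5, 0.25),
    half_sib     = c(0.5, 0.5, 0),
    first_cousin = c(0.75, 0.25, 0),
    unrelated    = c(1, 0, 0)
  )
  structure(list(kind = "pairwise", relationship = relationship, k = k),
            class = "relationship_hypothesis")
}

#' @export
print.relationship_hypothesis <- function(x, ...) {
  if (x$kind == "trio_paternity") {
    cat("Trio paternity hypothesis (paternity index)\n")
  } else {
    cat(sprintf("Pairwise hypothesis '%s': k = (%g, %g, %g)\n",
                x$relationship, x$k[1], x$k[2], x$k[3]))
  }
  invisible(x)
}

#' Mutation policy
#'
#' Controls how mutations are handled, both in the likelihood ratio and
#' (optionally) in the simulation itself.
#'
#' * `strict_zero` (default): a Mendelian incompatibility gives the locus a
#'   likelihood ratio of 0, so a single incompatible locus excludes.
#' * `rate_floor`: a zero Mendelian transmission probability is replaced by
#'   the aggregate per-meiosis mutation rate `mu`, so incompatible loci
#'   yield a small positive likelihood instead of annihilating the product.
#'
#' When `simulate = TRUE`, gene dropping also mutates each transmitted
#' allele with probability `mu`, moving it one step up or down the marker's
#' numeric allele ladder (equal probability each direction, reflecting at
#' the ladder ends); allele labels must then parse as repeat counts.
#'
#' @param mode `"strict_zero"` or `"rate_floor"`.
#' @param mu per-meiosis mutation rate, in (0, 0.01); used by `rate_floor`
#'   and by simulation-side mutation.
#' @param simulate logical; apply stepwise mutations during gene dropping.
#' @return An object of class `mutation_policy`.
#' @export
mutation_policy <- function(mode = c("strict_zero", "rate_floor"),
                            mu = 0.002, simulate = FALSE) {
  mode <- match.arg(mode)
  mu <- as.numeric(mu)
  if (!is.finite(mu) || mu <= 0 || mu >= 0.01) {
    stop("mu must lie in (0, 0.01)", call. = FALSE)
  }
  structure(list(mode = mode, mu = mu, simulate = isTRUE(simulate)),
            class = "mutation_policy")
}
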