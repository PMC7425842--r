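# Internal helpers.

# Run `expr` under a given seed, then restore the caller's RNG state so
# seeded generators behave as pure functions.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Map allele labels to indices of a marker's allele vector, erroring on
# unknown labels.
allele_index <- function(labels, m) {
  idx <- match(labels, m$alleles)
  if (anyNA(idx)) {
    stop("unknown allele(s) at marker '", m$marker, "': ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

# Neighbor tables for the stepwise mutation ladder: for each allele index,
# the index one repeat step up and one step down in numeric label order,
# reflecting at the ladder ends.  Errors if labels are not numeric.
mutation_ladder <- function(m) {
  vals <- suppressWarnings(as.numeric(m$alleles))
  if (anyNA(vals)) {
    stop("stepwise mutation requires numeric allele labels; marker '",
         m$marker, "' has non-numeric label(s): ",
         paste(m$alleles[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  ord <- order(vals)              # rank[i]: position of allele i on ladder
  rank <- match(seq_along(vals), ord)
  n <- length(vals)
  up <- ord[pmin(rank + 1L, n)]
  down <- ord[pmax(rank - 1L, 1L)]
  # reflect at the ends: a +1 step from the top goes down, and vice versa
  up[rank == n] <- ord[n - 1L]
  down[rank == 1L] <- ord[2L]
  list(up = up, down = down)
}
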