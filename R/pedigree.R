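#' @name pedigree_sim
#' @title Pedigree genotype simulation
#'
#' @description
#' Genotypes are simulated by Mendelian gene dropping: founders are drawn
#' under Hardy-Weinberg equilibrium from the population allele frequencies,
#' children receive one allele from each parent with probability 1/2 per
#' parental allele, and loci are treated as unlinked and independent.
#' Hidden individuals (e.g. the untyped co-parent of a duo, the shared
#' grandparents of cousins) are simulated and discarded; only the tested
#' individuals are returned.
NULL

.relationships <- c("trio", "parent_child", "full_sib", "half_sib",
                    "first_cousin", "unrelated")

# ---- vectorized engine -----------------------------------------------------

# n HWE allele draws at one marker.
.drop_draw <- function(n, p) sample.int(length(p), n, replace = TRUE, prob = p)

# Transmit one allele from each of n parents (index pairs a1, a2), with
# optional stepwise mutation on the marker's allele ladder.
.drop_transmit <- function(a1, a2, mut, ladder = NULL) {
  n <- length(a1)
  al <- ifelse(stats::runif(n) < 0.5, a1, a2)
  if (mut$simulate) {
    hit <- stats::runif(n) < mut$mu
    if (any(hit)) {
      upwards <- stats::runif(n) < 0.5
      al[hit & upwards] <- ladder$up[al[hit & upwards]]
      al[hit & !upwards] <- ladder$down[al[hit & !upwards]]
    }
  }
  al
}

# Simulate the tested individuals of n independent cases at one marker.
# Returns a named list of individuals, each a list(a1, a2) of allele index
# vectors.  `truth` is "related" (the alleged relationship holds) or
# "unrelated" (the tested individuals are unrelated; for a trio, the
# mother-child link is real and only the alleged father is unrelated).
.drop_marker <- function(relationship, truth, p, n, mut) {
  ladder <- NULL
  if (mut$simulate) {
    ladder <- attr(p, "ladder")
  }
  founder <- function() list(a1 = .drop_draw(n, p), a2 = .drop_draw(n, p))
  child_of <- function(x, y) {
    list(a1 = .drop_transmit(x$a1, x$a2, mut, ladder),
         a2 = .drop_transmit(y$a1, y$a2, mut, ladder))
  }
  related <- truth == "related"
  switch(relationship,
    trio = {
      mo <- founder(); fa <- founder()
      ch <- child_of(mo, fa)
      af <- if (related) fa else founder()
      list(mother = mo, child = ch, alleged_father = af)
    },
    parent_child = {
      if (related) {
        pa <- founder(); co <- founder()
        list(person1 = pa, person2 = child_of(pa, co))
      } else {
        list(person1 = founder(), person2 = founder())
      }
    },
    full_sib = {
      if (related) {
        pa <- founder(); ma <- founder()
        list(person1 = child_of(pa, ma), person2 = child_of(pa, ma))
      } else {
        list(person1 = founder(), person2 = founder())
      }
    },
    half_sib = {
      if (related) {
        shared <- founder(); o1 <- founder(); o2 <- founder()
        list(person1 = child_of(shared, o1), person2 = child_of(shared, o2))
      } else {
        list(person1 = founder(), person2 = founder())
      }
    },
    first_cousin = {
      if (related) {
        gp1 <- founder(); gp2 <- founder()
        sib1 <- child_of(gp1, gp2); sib2 <- child_of(gp1, gp2)
        list(person1 = child_of(sib1, founder()),
             person2 = child_of(sib2, founder()))
      } else {
        list(person1 = founder(), person2 = founder())
      }
    },
    unrelated = list(person1 = founder(), person2 = founder()),
    stop("unknown relationship: ", relationship, call. = FALSE)
  )
}

# Frequency vector of a marker with the mutation ladder pre-attached.
.drop_freqvec <- function(m, mut) {
  p <- m$freqs
  if (mut$simulate) attr(p, "ladder") <- mutation_ladder(m)
  p
}

# log10 combined LR for n simulated cases of one (relationship, truth) arm,
# tested under `hyp`.  Consumes the current RNG stream.
.sim_log10_lr <- function(relationship, truth, hyp, freqs, n, mut) {
  acc <- numeric(n)
  for (mk in freqs$panel$markers) {
    m <- freqs$per_marker[[mk]]
    p <- .drop_freqvec(m, mut)
    ind <- .drop_marker(relationship, truth, p, n, mut)
    lr <- if (hyp$kind == "trio_paternity") {
      .lr_trio(ind$mother$a1, ind$mother$a2,
               ind$child$a1, ind$child$a2,
               ind$alleged_father$a1, ind$alleged_father$a2, p, mut)
    } else {
      .lr_pairwise(ind$person1$a1, ind$person1$a2,
                   ind$person2$a1, ind$person2$a2, p, hyp$k, mut)
    }
    acc <- acc + log10(lr)
  }
  acc
}

# ---- scalar / per-case API -------------------------------------------------

#' Draw one founder genotype under Hardy-Weinberg equilibrium
#'
#' Two alleles are drawn independently from each marker's frequency
#' distribution; markers are independent. Consumes the global RNG stream
#' (use `set.seed()` for reproducibility).
#'
#' @param freqs a [frequency_set].
#' @return A multilocus genotype: named list, one sorted two-allele
#'   character vector per panel marker.
#' @export
sample_founder <- function(freqs) {
  stopifnot(inherits(freqs, "frequency_set"))
  out <- lapply(freqs$per_marker, function(m) {
    sort(m$alleles[.drop_draw(2L, m$freqs)])
  })
  names(out) <- freqs$panel$markers
  out
}

#' Transmit one allele from a parent genotype
#'
#' Returns one of the parent's two alleles with probability 1/2 each. With
#' simulation-side mutation enabled, the transmitted allele is shifted one
#' step up or down the marker's numeric allele ladder with probability
#' `mut$mu` (reflecting at the ladder ends).
#'
#' @param parent genotype: character vector of two allele labels.
#' @param m a [marker_frequencies] (supplies the allele ladder).
#' @param mut a [mutation_policy].
#' @return A single allele label.
#' @export
transmit <- function(parent, m, mut = mutation_policy()) {
  stopifnot(inherits(m, "marker_frequencies"),
            inherits(mut, "mutation_policy"))
  i <- allele_index(.as_genotype(parent), m)
  p <- .drop_freqvec(m, mut)
  m$alleles[.drop_transmit(i[1], i[2], mut, attr(p, "ladder"))]
}

#' Simulate one relationship-testing case
#'
#' Gene-drops the pedigree of the given scenario and returns the genotypes
#' of the tested individuals only. A trio case carries `mother`, `child`,
#' `alleged_father`; every pairwise case carries `person1`, `person2`.
#' Under `truth = "unrelated"` the tested individuals are unrelated
#' founders, except for the trio where the real mother-child pair is kept
#' and only the alleged father is an unrelated founder.
#'
#' Consumes the global RNG stream; see [estimate_rates()] for seeded bulk
#' simulation.
#'
#' @param relationship one of `"trio"`, `"parent_child"`, `"full_sib"`,
#'   `"half_sib"`, `"first_cousin"`, `"unrelated"`.
#' @param truth `"related"` or `"unrelated"` (`"unrelated"` forced for the
#'   `unrelated` scenario).
#' @param freqs a [frequency_set].
#' @param mut a [mutation_policy].
#' @return An object of class `simulated_case`: list with `relationship`,
#'   `truth`, and `genotypes` (named list of multilocus genotypes).
#' @examples
#' fs <- generate_frequency_set(builtin_panel("identifiler15"), seed = 1)
#' set.seed(42)
#' case <- simulate_case("trio", "related", fs)
#' names(case$genotypes)
#' @export
simulate_case <- function(relationship, truth = c("related", "unrelated"),
                          freqs, mut = mutation_policy()) {
  relationship <- match.arg(relationship, .relationships)
  truth <- match.arg(truth)
  if (relationship == "unrelated") truth <- "unrelated"
  stopifnot(inherits(freqs, "frequency_set"),
            inherits(mut, "mutation_policy"))
  markers <- freqs$panel$markers
  per_marker <- lapply(markers, function(mk) {
    m <- freqs$per_marker[[mk]]
    p <- .drop_freqvec(m, mut)
    ind <- .drop_marker(relationship, truth, p, 1L, mut)
    lapply(ind, function(g) sort(m$alleles[c(g$a1, g$a2)]))
  })
  who <- names(per_marker[[1]])
  genotypes <- lapply(who, function(w) {
    g <- lapply(per_marker, `[[`, w)
    names(g) <- markers
    g
  })
  names(genotypes) <- who
  structure(list(relationship = relationship, truth = truth,
                 genotypes = genotypes),
            class = "simulated_case")
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("Simulated %s case (%s truth): %s over %d markers\n",
              x$relationship, x$truth,
              paste(names(x$genotypes), collapse = ", "),
              length(x$genotypes[[1]])))
  invisible(x)
}

#' Export simulated genotypes to CSV
#'
#' Long format: `case_id,individual,marker,allele1,allele2`.
#'
#' @param cases list of [simulate_case] results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(cases, path) {
  rows <- do.call(rbind, lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    do.call(rbind, lapply(names(case$genotypes), function(w) {
      g <- case$genotypes[[w]]
      data.frame(case_id = i, individual = w, marker = names(g),
                 allele1 = vapply(g, `[`, "", 1L),
                 allele2 = vapply(g, `[`, "", 2L))
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
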