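#' Per-marker allele frequencies
#'
#' `marker_frequencies` holds the population allele frequency distribution of
#' one STR marker: allele labels (typically repeat counts, possibly
#' intermediate such as `"9.3"`) and their frequencies. Frequencies must be
#' strictly positive and are renormalized to sum to 1; at least two alleles
#' are required.
#'
#' @param marker marker name.
#' @param alleles character vector of allele labels.
#' @param freqs numeric vector of frequencies, same length as `alleles`.
#' @return An object of class `marker_frequencies`.
#' @examples
#' marker_frequencies("TH01", c("6", "7", "9.3"), c(0.23, 0.19, 0.58))
#' @export
marker_frequencies <- function(marker, alleles, freqs) {
  alleles <- as.character(alleles)
  freqs <- as.numeric(freqs)
  if (length(alleles) != length(freqs)) {
    stop("alleles and freqs must have the same length", call. = FALSE)
  }
  if (length(alleles) < 2L) {
    stop("marker '", marker, "' needs at least 2 alleles", call. = FALSE)
  }
  if (anyDuplicated(alleles)) {
    stop("duplicated allele labels at marker '", marker, "'", call. = FALSE)
  }
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("all frequencies at marker '", marker,
         "' must be finite and > 0", call. = FALSE)
  }
  structure(list(marker = as.character(marker)[1],
                 alleles = alleles,
                 freqs = freqs / sum(freqs)),
            class = "marker_frequencies")
}

#' Expected heterozygosity of a marker
#'
#' `1 - sum(p^2)`, the probability that a random Hardy-Weinberg genotype is
#' heterozygous.
#'
#' @param m a [marker_frequencies].
#' @return A number in `[0, 1)`.
#' @export
expected_heterozygosity <- function(m) {
  stopifnot(inherits(m, "marker_frequencies"))
  1 - sum(m$freqs^2)
}

#' Population frequency set for a panel
#'
#' A `frequency_set` binds one [marker_frequencies] to every marker of an
#' [str_panel]; it is the population model every simulation and likelihood
#' computation runs against.
#'
#' @param panel an [str_panel].
#' @param per_marker named list of [marker_frequencies], one per panel
#'   marker. Entries for markers not in the panel are dropped.
#' @param population text label for the population the frequencies describe.
#' @return An object of class `frequency_set`.
#' @export
frequency_set <- function(panel, per_marker, population = "synthetic") {
  stopifnot(inherits(panel, "str_panel"))
  if (is.null(names(per_marker))) {
    names(per_marker) <- vapply(per_marker, `[[`, "", "marker")
  }
  missing <- setdiff(panel$markers, names(per_marker))
  if (length(missing)) {
    stop("missing frequencies for panel marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_marker <- per_marker[panel$markers]
  ok <- vapply(per_marker, inherits, TRUE, "marker_frequencies")
  if (!all(ok)) stop("per_marker entries must be marker_frequencies objects",
                     call. = FALSE)
  structure(list(population = as.character(population)[1],
                 panel = panel, per_marker = per_marker),
            class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  het <- vapply(x$per_marker, expected_heterozygosity, 0)
  na <- vapply(x$per_marker, function(m) length(m$alleles), 0L)
  cat("Frequency set '", x$population, "' on panel '", x$panel$name, "' (",
      length(x$per_marker), " markers)\n", sep = "")
  cat(sprintf("  alleles/marker: %d-%d, mean expected heterozygosity %.3f\n",
              min(na), max(na), mean(het)))
  invisible(x)
}

#' Generate a synthetic frequency set
#'
#' Draws, for each panel marker, an allele count uniformly from
#' `alleles_per_marker` and allele frequencies from a symmetric Dirichlet
#' distribution with the given concentration. Allele labels are consecutive
#' integer repeat counts starting at a random offset, so the stepwise
#' mutation model can parse them as an allele ladder. The defaults (5-15
#' alleles, concentration 1) give expected heterozygosities in the 0.6-0.95
#' band typical of forensic STR markers.
#'
#' The function is pure: given the same `(panel, alleles_per_marker,
#' concentration, seed)` it returns the identical set, and it leaves the
#' caller's RNG state untouched.
#'
#' @param panel an [str_panel].
#' @param alleles_per_marker integer range `c(lo, hi)` within `[2, 30]`.
#' @param concentration positive Dirichlet concentration parameter; large
#'   values give near-uniform frequencies, small values skewed ones.
#' @param seed integer seed.
#' @param population label for the generated set.
#' @return A [frequency_set].
#' @examples
#' fs <- generate_frequency_set(builtin_panel("identifiler15"), seed = 7)
#' mean(vapply(fs$per_marker, expected_heterozygosity, 0))
#' @export
generate_frequency_set <- function(panel,
                                   alleles_per_marker = c(5L, 15L),
                                   concentration = 1,
                                   seed = 1L,
                                   population = "synthetic") {
  stopifnot(inherits(panel, "str_panel"))
  r <- as.integer(round(alleles_per_marker))
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] ||
      r[1] < 2L || r[2] > 30L) {
    stop("alleles_per_marker must be an integer range within [2, 30]",
         call. = FALSE)
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop("concentration must be > 0", call. = FALSE)
  }
  with_preserved_rng(seed, {
    per_marker <- lapply(panel$markers, function(mk) {
      a <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
      # symmetric Dirichlet via normalized gammas
      g <- stats::rgamma(a, shape = concentration, rate = 1)
      while (any(g == 0)) g <- stats::rgamma(a, shape = concentration, 1)
      start <- sample(5:(31L - a), 1L)
      marker_frequencies(mk, as.character(seq(start, length.out = a)),
                         g / sum(g))
    })
    names(per_marker) <- panel$markers
    frequency_set(panel, per_marker, population = population)
  })
}

#' Read / write allele frequency tables
#'
#' The file format is CSV with header `marker,allele,frequency`, one row per
#' (marker, allele), UTF-8, dot decimal separator. On read, rows for markers
#' outside the panel are ignored; per-marker frequency sums within
#' `[0.99, 1.01]` (published forensic tables are rounded to 3-4 decimals)
#' are renormalized to 1, sums outside that band are an error. Write
#' followed by read reproduces frequencies to better than 1e-12.
#'
#' @param path CSV file path.
#' @param panel an [str_panel]; every panel marker must be present in the
#'   file.
#' @param population label attached to the returned set.
#' @return `read_frequencies()` returns a [frequency_set];
#'   `write_frequencies()` returns `path` invisibly.
#' @export
read_frequencies <- function(path, panel, population = "file") {
  stopifnot(inherits(panel, "str_panel"))
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  need <- c("marker", "allele", "frequency")
  if (!all(need %in% names(df))) {
    stop("frequency CSV must have columns marker, allele, frequency: ",
         path, call. = FALSE)
  }
  df <- df[df$marker %in% panel$markers, , drop = FALSE]
  missing <- setdiff(panel$markers, unique(df$marker))
  if (length(missing)) {
    stop("frequency file '", path, "' is missing panel marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("marker", "allele")])) {
    d <- df[duplicated(df[c("marker", "allele")]), ]
    stop("duplicate (marker, allele) rows, e.g. ",
         d$marker[1], "/", d$allele[1], call. = FALSE)
  }
  if (any(df$frequency <= 0) || any(!is.finite(df$frequency))) {
    stop("all frequencies must be finite and > 0", call. = FALSE)
  }
  per_marker <- lapply(split(df, df$marker), function(part) {
    s <- sum(part$frequency)
    if (s < 0.99 || s > 1.01) {
      stop("frequencies at marker '", part$marker[1], "' sum to ",
           format(s), ", outside [0.99, 1.01]", call. = FALSE)
    }
    marker_frequencies(part$marker[1], part$allele, part$frequency / s)
  })
  frequency_set(panel, per_marker, population = population)
}

#' @rdname read_frequencies
#' @param fs a [frequency_set].
#' @export
write_frequencies <- function(fs, path) {
  stopifnot(inherits(fs, "frequency_set"))
  rows <- do.call(rbind, lapply(fs$per_marker, function(m) {
    data.frame(marker = m$marker, allele = m$alleles,
               frequency = sprintf("%.17g", m$freqs))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
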