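#' Decision policy
#'
#' Laboratories render a conclusion by thresholding the combined likelihood
#' ratio. A *binary* policy declares inclusion at `LR >= t_incl` and
#' exclusion otherwise. A *ternary* policy adds an inconclusive range:
#' inclusion at `LR >= t_incl`, exclusion at `LR <= t_excl`, inconclusive
#' in between (the open interval `t_excl < LR < t_incl`, e.g.
#' `0.01 < LR < 100`). Boundary values are decisions, not inconclusive.
#'
#' @param mode `"binary"` or `"ternary"`.
#' @param t_incl inclusion threshold on LR, must exceed 1 (common survey
#'   values: 100 and 1000).
#' @param t_excl exclusion threshold on LR, in (0, 1); ternary only.
#' @return An object of class `decision_policy`.
#' @export
decision_policy <- function(mode = c("binary", "ternary"),
                            t_incl = 100, t_excl = 0.01) {
  mode <- match.arg(mode)
  if (!is.finite(t_incl) || t_incl <= 1) {
    stop("t_incl must be > 1", call. = FALSE)
  }
  if (mode == "ternary" && (!is.finite(t_excl) || t_excl <= 0 ||
                            t_excl >= 1)) {
    stop("ternary policy needs 0 < t_excl < 1", call. = FALSE)
  }
  structure(list(mode = mode, t_incl = t_incl,
                 t_excl = if (mode == "ternary") t_excl else NA_real_),
            class = "decision_policy")
}

#' Classify likelihood ratios under a decision policy
#'
#' @param lr numeric vector of non-negative LR values (`0` classifies as
#'   exclusion under either mode).
#' @param policy a [decision_policy].
#' @return Character vector in `{"inclusion", "exclusion",
#'   "inconclusive"}`.
#' @examples
#' p <- decision_policy("ternary", 100, 0.01)
#' classify(c(100, 50, 0.01, 0), p)
#' @export
classify <- function(lr, policy) {
  stopifnot(inherits(policy, "decision_policy"))
  if (any(lr < 0, na.rm = TRUE)) stop("LR values must be >= 0",
                                      call. = FALSE)
  out <- rep("exclusion", length(lr))
  out[lr >= policy$t_incl] <- "inclusion"
  if (policy$mode == "ternary") {
    out[lr > policy$t_excl & lr < policy$t_incl] <- "inconclusive"
  }
  out
}

# classify on log10(LR) (-Inf = LR 0); returns integer counts
# c(inclusion, exclusion, inconclusive).
.classify_counts_log10 <- function(l10, policy) {
  li <- log10(policy$t_incl)
  incl <- l10 >= li
  if (policy$mode == "ternary") {
    excl <- l10 <= log10(policy$t_excl)
    c(sum(incl), sum(excl), sum(!incl & !excl))
  } else {
    c(sum(incl), sum(!incl), 0L)
  }
}

# ---- LR histograms ---------------------------------------------------------

# Decade bins on log10(LR): a dedicated LR = 0 bin, an open lower tail
# (-Inf, -10], interior decades, and an open upper tail (10, Inf).
.hist_edges <- -10:10

.hist_template <- function() {
  e <- .hist_edges
  data.frame(
    bin = c("LR=0", sprintf("(%s,%s]", c("-Inf", e[-length(e)]), e),
            sprintf("(%d,Inf)", e[length(e)])),
    bin_low_log10 = c(NA, -Inf, e[-length(e)], e[length(e)]),
    bin_high_log10 = c(NA, e, Inf),
    count = 0
  )
}

# counts vector aligned with .hist_template() rows, from log10 LRs
.hist_counts <- function(l10) {
  zero <- sum(is.infinite(l10) & l10 < 0)
  fin <- l10[is.finite(l10)]
  k <- findInterval(fin, .hist_edges, left.open = TRUE) + 1L
  c(zero, tabulate(k, nbins = length(.hist_edges) + 1L))
}

# ---- Monte-Carlo estimation ------------------------------------------------

# independent, reproducible RNG streams for the two arms
.arm_seed <- function(seed, arm) (as.integer(seed) %% 1073741823L) * 2L + arm

#' Simulate a sample of combined log10 likelihood ratios
#'
#' Simulates `n` independent cases of one `(relationship, truth)` arm and
#' returns their combined log10 LRs under the relationship's own hypothesis
#' (paternity index for trios, IBD-coefficient LR otherwise). This is the
#' raw material of the false-rate tables and LR-count histograms; retain it
#' when several threshold policies must be compared on the same sample.
#'
#' @param relationship alleged relationship: `"trio"`, `"parent_child"`,
#'   `"full_sib"`, `"half_sib"`, or `"first_cousin"`.
#' @param truth `"related"` (simulate the alleged relationship) or
#'   `"unrelated"` (simulate unrelated individuals, tested under the
#'   alleged relationship).
#' @param freqs a [frequency_set].
#' @param n number of simulated cases.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param mut a [mutation_policy].
#' @return Numeric vector of length `n` of log10 combined LRs (`-Inf` for
#'   excluded cases with a zero-LR locus).
#' @export
simulate_lr_sample <- function(relationship, truth, freqs, n, seed = 1L,
                               mut = mutation_policy()) {
  relationship <- match.arg(relationship,
                            setdiff(.relationships, "unrelated"))
  truth <- match.arg(truth, c("related", "unrelated"))
  stopifnot(inherits(freqs, "frequency_set"),
            inherits(mut, "mutation_policy"), n >= 1)
  hyp <- kinship_hypothesis(relationship)
  with_preserved_rng(seed,
    .sim_log10_lr(relationship, truth, hyp, freqs, as.integer(n), mut))
}

#' Tally false rates from simulated LR samples
#'
#' Classifies the two arms' log10 LR samples under a policy and assembles
#' the one-row rate table: the false negative rate is the fraction of
#' truly related cases not called inclusion (binary) or called exclusion
#' (ternary); the false positive rate is the fraction of unrelated cases
#' called inclusion; inconclusive fractions are reported for ternary
#' policies. Binomial standard errors accompany both false rates.
#'
#' @param l10_related,l10_unrelated numeric vectors of log10 combined LRs
#'   for the related and unrelated arm (e.g. from [simulate_lr_sample()]).
#' @param policy a [decision_policy].
#' @param relationship,panel labels recorded in the output row.
#' @return A one-row `data.frame` with columns `relationship, panel, mode,
#'   t_incl, t_excl, n_sims, fn_rate, fp_rate, inconclusive_related,
#'   inconclusive_unrelated, fn_se, fp_se`.
#' @export
tally_rates <- function(l10_related, l10_unrelated, policy,
                        relationship = NA_character_,
                        panel = NA_character_) {
  stopifnot(inherits(policy, "decision_policy"))
  n <- length(l10_related)
  stopifnot(n >= 1, length(l10_unrelated) == n)
  cr <- .classify_counts_log10(l10_related, policy)
  cu <- .classify_counts_log10(l10_unrelated, policy)
  fn <- if (policy$mode == "binary") (cr[2] + cr[3]) / n else cr[2] / n
  fp <- cu[1] / n
  data.frame(
    relationship = relationship, panel = panel, mode = policy$mode,
    t_incl = policy$t_incl, t_excl = policy$t_excl, n_sims = n,
    fn_rate = fn, fp_rate = fp,
    inconclusive_related = if (policy$mode == "ternary") cr[3] / n
                           else NA_real_,
    inconclusive_unrelated = if (policy$mode == "ternary") cu[3] / n
                             else NA_real_,
    fn_se = sqrt(fn * (1 - fn) / n), fp_se = sqrt(fp * (1 - fp) / n),
    row.names = NULL
  )
}

#' Monte-Carlo false-rate estimation
#'
#' Simulates `n_sims` truly related and `n_sims` unrelated cases of the
#' alleged relationship, computes each case's combined LR, classifies under
#' the policy, and tallies false negative / false positive / inconclusive
#' rates with binomial standard errors, plus decade-binned log10(LR)
#' histograms for both arms. Simulation streams in fixed-size chunks, so
#' memory use is independent of `n_sims`; the related and unrelated arms
#' use independent seeded RNG streams derived from `seed`.
#'
#' @inheritParams simulate_lr_sample
#' @param policy a [decision_policy].
#' @param n_sims replicates per arm.
#' @return An object of class `rate_estimate`: list with `rates` (the
#'   [tally_rates()] row), `hist_related`, and `hist_unrelated`
#'   (data.frames of binned LR counts; counts sum to `n_sims`).
#' @examples
#' fs <- generate_frequency_set(builtin_panel("identifiler15"), seed = 1)
#' est <- estimate_rates("trio", fs, decision_policy("binary", 100),
#'                       n_sims = 1000, seed = 7)
#' est$rates$fn_rate
#' @export
estimate_rates <- function(relationship, freqs, policy, n_sims = 1e5,
                           seed = 1L, mut = mutation_policy()) {
  relationship <- match.arg(relationship,
                            setdiff(.relationships, "unrelated"))
  stopifnot(inherits(freqs, "frequency_set"),
            inherits(policy, "decision_policy"),
            inherits(mut, "mutation_policy"), n_sims >= 1)
  n_sims <- as.integer(n_sims)
  hyp <- kinship_hypothesis(relationship)
  chunk <- 100000L

  run_arm <- function(truth, arm) {
    with_preserved_rng(.arm_seed(seed, arm), {
      dec <- c(0L, 0L, 0L)
      hc <- numeric(length(.hist_edges) + 2L)
      done <- 0L
      while (done < n_sims) {
        m <- min(chunk, n_sims - done)
        l10 <- .sim_log10_lr(relationship, truth, hyp, freqs, m, mut)
        dec <- dec + .classify_counts_log10(l10, policy)
        hc <- hc + .hist_counts(l10)
        done <- done + m
      }
      list(dec = dec, hist = hc)
    })
  }
  rel <- run_arm("related", 0L)
  unrel <- run_arm("unrelated", 1L)

  n <- n_sims
  fn <- if (policy$mode == "binary") (rel$dec[2] + rel$dec[3]) / n
        else rel$dec[2] / n
  fp <- unrel$dec[1] / n
  rates <- data.frame(
    relationship = relationship, panel = freqs$panel$name,
    mode = policy$mode, t_incl = policy$t_incl, t_excl = policy$t_excl,
    n_sims = n, fn_rate = fn, fp_rate = fp,
    inconclusive_related = if (policy$mode == "ternary") rel$dec[3] / n
                           else NA_real_,
    inconclusive_unrelated = if (policy$mode == "ternary") unrel$dec[3] / n
                             else NA_real_,
    fn_se = sqrt(fn * (1 - fn) / n), fp_se = sqrt(fp * (1 - fp) / n),
    row.names = NULL
  )
  mk_hist <- function(arm, counts) {
    h <- .hist_template()
    h$count <- counts
    cbind(relationship = relationship, arm = arm, h)
  }
  structure(list(rates = rates,
                 hist_related = mk_hist("related", rel$hist),
                 hist_unrelated = mk_hist("unrelated", unrel$hist)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  r <- x$rates
  cat(sprintf(
    "%s on %s, %s policy (t_incl = %g%s), n = %d per arm\n",
    r$relationship, r$panel, r$mode, r$t_incl,
    if (r$mode == "ternary") sprintf(", t_excl = %g", r$t_excl) else "",
    r$n_sims))
  cat(sprintf("  FN %.5g (SE %.2g)   FP %.5g (SE %.2g)\n",
              r$fn_rate, r$fn_se, r$fp_rate, r$fp_se))
  if (r$mode == "ternary") {
    cat(sprintf("  inconclusive: related %.4g, unrelated %.4g\n",
                r$inconclusive_related, r$inconclusive_unrelated))
  }
  invisible(x)
}

# ---- exact enumeration oracle ---------------------------------------------

#' Exact false rates by exhaustive enumeration
#'
#' For pairwise relationships on small panels, enumerates every joint
#' genotype configuration of the two individuals with its exact probability
#' under the true relationship (via the IBD-coefficient mixture) and under
#' unrelatedness, computes each configuration's combined LR and decision,
#' and returns exact rates. Serves as an oracle for [estimate_rates()].
#'
#' The joint state space (product over markers of the squared per-marker
#' genotype count) must not exceed 1e7; larger panels are rejected with a
#' pointer to Monte-Carlo estimation. The trio scenario and simulation-side
#' mutation are not supported.
#'
#' @inheritParams estimate_rates
#' @return A one-row rate table as in [tally_rates()], with `n_sims = NA`
#'   and zero standard errors.
#' @examples
#' toy <- str_panel("toy", "L1")
#' fs <- frequency_set(toy, list(
#'   L1 = marker_frequencies("L1", c("a", "b"), c(0.5, 0.5))))
#' exact_rates_bruteforce("parent_child", fs,
#'                        decision_policy("binary", 1.5))$fn_rate # 0.75
#' @export
exact_rates_bruteforce <- function(relationship, freqs, policy,
                                   mut = mutation_policy()) {
  relationship <- match.arg(relationship,
                            c("parent_child", "full_sib", "half_sib",
                              "first_cousin", "unrelated"))
  stopifnot(inherits(freqs, "frequency_set"),
            inherits(policy, "decision_policy"),
            inherits(mut, "mutation_policy"))
  if (mut$simulate) {
    stop("exact enumeration does not model simulation-side mutation",
         call. = FALSE)
  }
  k <- kinship_hypothesis(relationship)$k

  # per-marker table of all ordered (G1, G2) unordered-genotype pairs
  locus_tables <- lapply(freqs$per_marker, function(m) {
    p <- m$freqs
    a <- length(p)
    gi <- which(upper.tri(matrix(0, a, a), diag = TRUE), arr.ind = TRUE)
    x1 <- gi[, 1]; x2 <- gi[, 2]        # x1 <= x2
    g <- length(x1)
    i1 <- rep(seq_len(g), times = g); i2 <- rep(seq_len(g), each = g)
    pg1 <- .lr_pgeno(x1[i1], x2[i1], p)
    pg2 <- .lr_pgeno(x1[i2], x2[i2], p)
    pc1 <- .lr_pcond1(x1[i1], x2[i1], x1[i2], x2[i2], p)
    same <- x1[i1] == x1[i2] & x2[i1] == x2[i2]
    list(lr = .lr_pairwise(x1[i1], x2[i1], x1[i2], x2[i2], p, k, mut),
         p_rel = pg1 * (k[1] * pg2 + k[2] * pc1 + k[3] * same),
         p_unrel = pg1 * pg2)
  })

  size <- prod(vapply(locus_tables, function(t) length(t$lr), 0))
  if (size > 1e7) {
    stop("joint state space has ", format(size),
         " configurations (> 1e7); use Monte-Carlo estimate_rates()",
         call. = FALSE)
  }

  state <- list(llr = 0, p_rel = 1, p_unrel = 1)
  for (t in locus_tables) {
    ns <- length(state$llr); nm <- length(t$lr)
    is_ <- rep(seq_len(ns), times = nm); im <- rep(seq_len(nm), each = ns)
    state <- list(llr = state$llr[is_] + log10(t$lr[im]),
                  p_rel = state$p_rel[is_] * t$p_rel[im],
                  p_unrel = state$p_unrel[is_] * t$p_unrel[im])
  }

  li <- log10(policy$t_incl)
  incl <- state$llr >= li
  excl <- if (policy$mode == "ternary") {
    state$llr <= log10(policy$t_excl)
  } else !incl
  inc <- !incl & !excl
  fn <- if (policy$mode == "binary") sum(state$p_rel[!incl])
        else sum(state$p_rel[excl])
  data.frame(
    relationship = relationship, panel = freqs$panel$name,
    mode = policy$mode, t_incl = policy$t_incl, t_excl = policy$t_excl,
    n_sims = NA_integer_, fn_rate = fn, fp_rate = sum(state$p_unrel[incl]),
    inconclusive_related = if (policy$mode == "ternary")
      sum(state$p_rel[inc]) else NA_real_,
    inconclusive_unrelated = if (policy$mode == "ternary")
      sum(state$p_unrel[inc]) else NA_real_,
    fn_se = 0, fp_se = 0, row.names = NULL
  )
}

# ---- CSV output ------------------------------------------------------------

#' Write rate tables and LR histograms to CSV
#'
#' @param rates data.frame of [tally_rates()] /
#'   [exact_rates_bruteforce()] rows (rbind several to one file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @param hists list of histogram data.frames from [estimate_rates()].
#' @export
write_histograms <- function(hists, path) {
  utils::write.csv(do.call(rbind, hists), path, row.names = FALSE)
  invisible(path)
}
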