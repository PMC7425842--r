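#' Global caseload model
#'
#' Projects how many relationship-testing cases worldwide may have been
#' falsely interpreted. The model multiplies, for each combination of case
#' type, arm (truly related vs truly unrelated) and laboratory LR
#' threshold:
#'
#' `cases of that type` x `arm fraction` x `fraction of labs using that
#' threshold` x `false rate at that threshold`
#'
#' where the related arm uses false negative rates (truly related excluded)
#' and the unrelated arm uses false positive rates (truly unrelated
#' included). The arm split is applied uniformly across case types. Case
#' types without a threshold in the lab mix (laboratories reporting only
#' the LR) contribute no decisions and no rows.
#'
#' @param total_cases total number of cases tested.
#' @param related_fraction fraction of cases in which the alleged
#'   relationship is true (the complement is the exclusion fraction).
#' @param casetype_mix named numeric vector of case-type proportions
#'   (names from `"trio"`, `"parent_child"`, `"full_sib"`, `"half_sib"`,
#'   `"first_cousin"`); must sum to 1.
#' @param lab_threshold_mix named list, one named numeric vector per case
#'   type mapping LR threshold (as name) to the proportion of laboratories
#'   using it; each vector may sum to at most 1.
#' @param rates `data.frame` with columns `case_type`, `threshold`,
#'   `fn_rate`, `fp_rate`, covering every (case type, threshold) pair in
#'   the lab mix. May be omitted and supplied later via
#'   [project_from_simulation()].
#' @return An object of class `caseload_model`.
#' @seealso [caseload_preset()] for the published Identifiler-era model.
#' @export
caseload_model <- function(total_cases, related_fraction, casetype_mix,
                           lab_threshold_mix, rates = NULL) {
  if (!is.finite(total_cases) || total_cases < 0) {
    stop("total_cases must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(related_fraction) || related_fraction < 0 ||
      related_fraction > 1) {
    stop("related_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(casetype_mix) &&
      abs(sum(casetype_mix) - 1) > 1e-9) {
    stop("casetype_mix must sum to 1", call. = FALSE)
  }
  unknown <- setdiff(names(casetype_mix),
                     setdiff(.relationships, "unrelated"))
  if (length(unknown)) {
    stop("unknown case type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (ct in names(lab_threshold_mix)) {
    mix <- lab_threshold_mix[[ct]]
    if (sum(mix) > 1 + 1e-9) {
      stop("lab threshold mix for '", ct, "' sums to more than 1",
           call. = FALSE)
    }
  }
  if (!is.null(rates)) {
    need <- c("case_type", "threshold", "fn_rate", "fp_rate")
    if (!all(need %in% names(rates))) {
      stop("rates needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(total_cases = total_cases,
                 related_fraction = related_fraction,
                 casetype_mix = casetype_mix,
                 lab_threshold_mix = lab_threshold_mix,
                 rates = rates),
            class = "caseload_model")
}

#' Published caseload model presets
#'
#' `"table1_identifiler"` encodes the published global model for
#' second-generation 15-marker kits: 10 million cases, 72% truly related,
#' case mix 75% trio / 20% parent-child / 5% full-sibling, AABB-survey lab
#' threshold mixes (trio 65% at LR 100 and 35% at LR 1000; parent-child
#' 75%/25%; full-sibling 20% at LR 100, the remaining labs reporting LR
#' only), and the published false rates per (case type, threshold).
#'
#' @param name preset name.
#' @return A complete [caseload_model].
#' @examples
#' project(caseload_preset("table1_identifiler"))
#' @export
caseload_preset <- function(name = "table1_identifiler") {
  name <- match.arg(name)
  rates <- data.frame(
    case_type = rep(c("trio", "parent_child", "full_sib"), c(2, 2, 1)),
    threshold = c(100, 1000, 100, 1000, 100),
    fn_rate = c(0.00058, 0.00284, 0.0114, 0.0767, 0.2082),
    fp_rate = c(0.000007, 0.000002, 0.00015, 0.000055, 0.00032)
  )
  caseload_model(
    total_cases = 1e7,
    related_fraction = 0.72,
    casetype_mix = c(trio = 0.75, parent_child = 0.20, full_sib = 0.05),
    lab_threshold_mix = list(
      trio = c("100" = 0.65, "1000" = 0.35),
      parent_child = c("100" = 0.75, "1000" = 0.25),
      full_sib = c("100" = 0.20)
    ),
    rates = rates
  )
}

#' Expected number of false interpretations in one model cell
#'
#' @param n_type number of cases of the case type.
#' @param arm_fraction fraction of those cases in the arm (related or
#'   unrelated).
#' @param lab_fraction fraction of laboratories using the threshold.
#' @param false_rate false negative (related arm) or false positive
#'   (unrelated arm) rate at that threshold.
#' @return List with `unrounded` (the product) and `count` (rounded to the
#'   nearest integer, halves away from zero).
#' @examples
#' expected_false_count(7.5e6, 0.72, 0.65, 0.00058)$count # 2036
#' @export
expected_false_count <- function(n_type, arm_fraction, lab_fraction,
                                 false_rate) {
  v <- c(n_type, arm_fraction, lab_fraction, false_rate)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all factors must be finite and non-negative", call. = FALSE)
  }
  if (arm_fraction > 1 || lab_fraction > 1) {
    stop("fractions must not exceed 1", call. = FALSE)
  }
  u <- n_type * arm_fraction * lab_fraction * false_rate
  list(unrounded = u, count = round_half_away(u))
}

#' Project expected numbers of falsely interpreted cases
#'
#' Expands the model into one row per (case type, arm, threshold) with a
#' laboratory fraction, applies [expected_false_count()] to each, and
#' totals the projection. Related rows (false negatives) come first, then
#' unrelated rows (false positives), each in case-mix order by increasing
#' threshold.
#'
#' @param model a complete [caseload_model] (with `rates`).
#' @return An object of class `false_count_table`: a `data.frame` with
#'   columns `case_type, arm, threshold, lab_fraction, false_rate,
#'   unrounded, expected_count` and attributes `total_rounded_rows` (sum of
#'   the rounded counts), `total_unrounded`, and `grand_total` (the
#'   unrounded sum, rounded).
#' @export
project <- function(model) {
  stopifnot(inherits(model, "caseload_model"))
  if (is.null(model$rates)) {
    stop("model has no rates; supply them or use project_from_simulation()",
         call. = FALSE)
  }
  rows <- list()
  for (arm in c("related", "unrelated")) {
    arm_fraction <- if (arm == "related") model$related_fraction
                    else 1 - model$related_fraction
    for (ct in names(model$casetype_mix)) {
      mix <- model$lab_threshold_mix[[ct]]
      if (is.null(mix)) next
      n_type <- model$total_cases * model$casetype_mix[[ct]]
      for (th in as.numeric(names(mix))) {
        r <- model$rates[model$rates$case_type == ct &
                         model$rates$threshold == th, , drop = FALSE]
        if (nrow(r) != 1L) {
          stop("missing false rates for case type '", ct,
               "' at threshold ", th, call. = FALSE)
        }
        rate <- if (arm == "related") r$fn_rate else r$fp_rate
        cell <- expected_false_count(n_type, arm_fraction,
                                     mix[[as.character(th)]], rate)
        rows[[length(rows) + 1L]] <- data.frame(
          case_type = ct, arm = arm, threshold = th,
          lab_fraction = mix[[as.character(th)]], false_rate = rate,
          unrounded = cell$unrounded, expected_count = cell$count
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    case_type = character(), arm = character(), threshold = numeric(),
    lab_fraction = numeric(), false_rate = numeric(),
    unrounded = numeric(), expected_count = numeric()
  )
  rownames(out) <- NULL
  attr(out, "total_rounded_rows") <- sum(out$expected_count)
  attr(out, "total_unrounded") <- sum(out$unrounded)
  attr(out, "grand_total") <- round_half_away(sum(out$unrounded))
  class(out) <- c("false_count_table", "data.frame")
  out
}

#' @export
print.false_count_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf(
    "Grand total: %d (sum of unrounded values %.3f; rounded rows sum to %d)\n",
    as.integer(attr(x, "grand_total")), attr(x, "total_unrounded"),
    as.integer(attr(x, "total_rounded_rows"))))
  invisible(x)
}

#' Project from simulated or enumerated rate tables
#'
#' Wires [estimate_rates()] / [exact_rates_bruteforce()] output into the
#' caseload projection: rate-table rows (columns `relationship`, `t_incl`,
#' `fn_rate`, `fp_rate`) supply the false rates for every (case type,
#' threshold) pair in the model's lab mix.
#'
#' @param model a [caseload_model], with or without rates (any existing
#'   rates are replaced).
#' @param rate_tables `data.frame` of rate rows, e.g. `rbind` of
#'   `estimate_rates(...)$rates` across relationships and thresholds.
#' @return A `false_count_table`, identical to [project()] with the same
#'   rates entered manually.
#' @export
project_from_simulation <- function(model, rate_tables) {
  stopifnot(inherits(model, "caseload_model"))
  need <- c("relationship", "t_incl", "fn_rate", "fp_rate")
  if (!all(need %in% names(rate_tables))) {
    stop("rate_tables needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (ct in names(model$lab_threshold_mix)) {
    for (th in as.numeric(names(model$lab_threshold_mix[[ct]]))) {
      hit <- rate_tables$relationship == ct & rate_tables$t_incl == th
      if (!any(hit)) {
        stop("rate_tables does not cover case type '", ct,
             "' at threshold ", th, call. = FALSE)
      }
    }
  }
  model$rates <- data.frame(case_type = rate_tables$relationship,
                            threshold = rate_tables$t_incl,
                            fn_rate = rate_tables$fn_rate,
                            fp_rate = rate_tables$fp_rate)
  project(model)
}

#' Read / write a caseload model configuration
#'
#' JSON or YAML (by file extension) mirroring the [caseload_model] fields.
#'
#' @param path file path.
#' @return `read_caseload_model()` returns a [caseload_model];
#'   `write_caseload_model()` returns `path` invisibly.
#' @export
read_caseload_model <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  rates <- if (!is.null(obj$rates)) as.data.frame(obj$rates) else NULL
  caseload_model(obj$total_cases, obj$related_fraction,
                 unlist(obj$casetype_mix),
                 lapply(obj$lab_threshold_mix, unlist),
                 rates)
}

#' @rdname read_caseload_model
#' @param model a [caseload_model].
#' @export
write_caseload_model <- function(model, path) {
  stopifnot(inherits(model, "caseload_model"))
  obj <- list(total_cases = model$total_cases,
              related_fraction = model$related_fraction,
              casetype_mix = as.list(model$casetype_mix),
              lab_threshold_mix = lapply(model$lab_threshold_mix, as.list),
              rates = model$rates)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a false-count projection to CSV
#'
#' Columns: `case_type,arm,threshold,lab_fraction,false_rate,expected_count`
#' (plus the unrounded value).
#'
#' @param x a `false_count_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_false_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
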