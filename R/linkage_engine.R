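.norm_fields <- c("record_id", "name_joined", "mother_joined", "first_name",
                  "second_name", "last_name", "first_mother_name",
                  "second_mother_name", "name_no_last", "mother_no_last",
                  "birth_day", "birth_month", "birth_year", "dob_digits",
                  "slk_full", "slk_mother_trimmed")

.check_normalized <- function(x, what) {
  miss <- setdiff(.norm_fields, names(x))
  if (length(miss)) {
    stop_config(what, " is not a normalized registry (missing: ",
                paste(miss, collapse = ", "), "); run normalize_registry() first")
  }
}

.key_present <- function(v) {
  if (is.character(v)) !is.na(v) & nzchar(v) else !is.na(v)
}

#' Generate candidate pairs by blocking
#'
#' Returns every (left, right) pair that agrees exactly on all blocking keys.
#' Records missing any key value produce no candidates. An empty key list
#' yields the full cross product.
#'
#' @param left,right normalized registries ([normalize_registry()]).
#' @param keys character vector of normalized field names.
#' @return `data.table` with columns `li`, `ri` (row indices into `left` and
#'   `right`) and `left_id`, `right_id`.
#' @export
block_candidates <- function(left, right, keys) {
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  bad <- setdiff(keys, names(left))
  if (length(bad)) stop_config("unknown blocking key(s): ", paste(bad, collapse = ", "))
  if (!length(keys)) {
    pairs <- data.table::CJ(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
  } else {
    lt <- left[, c(keys), with = FALSE][, li := .I]
    rt <- right[, c(keys), with = FALSE][, ri := .I]
    for (k in keys) {
      lt <- lt[.key_present(lt[[k]])]
      rt <- rt[.key_present(rt[[k]])]
    }
    if (nrow(lt) == 0 || nrow(rt) == 0) {
      pairs <- data.table::data.table(li = integer(0), ri = integer(0))
    } else {
      pairs <- merge(lt, rt, by = keys, allow.cartesian = TRUE)[, .(li, ri)]
    }
  }
  pairs[, left_id := left$record_id[li]]
  pairs[, right_id := right$record_id[ri]]
  data.table::setorder(pairs, li, ri)[]
}

#' Composite similarity score of record pairs
#'
#' The weighted sum of the step's per-field similarities divided by the
#' step's divisor. A component where either side is missing or empty
#' contributes zero (its weight still counts in the divisor), so incomplete
#' records are penalized rather than silently skipped.
#'
#' @param left,right normalized registries with the same number of rows;
#'   row i of `left` is scored against row i of `right`.
#' @param step a probabilistic [linkage_step()].
#' @param params [similarity_params()].
#' @return numeric vector of scores in \[0, 1\].
#' @export
composite_score <- function(left, right, step, params = similarity_params()) {
  if (step$method != "probabilistic") stop_config("composite_score needs a probabilistic step")
  if (nrow(left) != nrow(right)) stop_config("left and right must pair rowwise")
  metric <- switch(step$metric,
                   jaro = function(a, b) jaro(a, b),
                   jaro_winkler = function(a, b) jaro_winkler(a, b, params))
  total <- numeric(nrow(left))
  for (f in names(step$components)) {
    a <- as.character(left[[f]])
    b <- as.character(right[[f]])
    ok <- .key_present(a) & .key_present(b)
    s <- numeric(length(a))
    if (any(ok)) s[ok] <- metric(a[ok], b[ok])
    total <- total + step$components[[f]] * s
  }
  total / step$divisor
}

#' Resolve scored pairs to a one-to-one matching
#'
#' Greedy selection by descending score with ties broken by `(left_id,
#' right_id)` lexicographic order; each id on either side is used at most
#' once. Deterministic for a given input set.
#'
#' @param scored `data.table` with columns `left_id`, `right_id`, `score`.
#' @return `data.table` subset of `scored`, one row per accepted link.
#' @export
resolve_one_to_one <- function(scored) {
  scored <- data.table::as.data.table(scored)[, .(left_id, right_id, score)]
  if (nrow(scored) == 0) return(scored)
  dt <- data.table::setorder(data.table::copy(scored), -score, left_id, right_id)
  acc <- vector("list", 0)
  # rows that are the best remaining for both their ids are exactly the ones
  # sequential greedy accepts; iterate until no conflicts remain
  while (nrow(dt) > 0) {
    take <- !duplicated(dt$left_id) & !duplicated(dt$right_id)
    chosen <- dt[take]
    acc[[length(acc) + 1L]] <- chosen
    dt <- dt[!take][!(left_id %in% chosen$left_id) & !(right_id %in% chosen$right_id)]
  }
  out <- data.table::rbindlist(acc)
  data.table::setorder(out, -score, left_id, right_id)[]
}

#' Execute a single linkage step
#'
#' Deterministic steps join on the step's statistical linkage key variant;
#' probabilistic steps block, score, keep pairs strictly above the threshold
#' and resolve to one-to-one. Deterministic links carry score 1.
#'
#' @param left,right normalized registries (unmatched records only).
#' @param step a [linkage_step()].
#' @param params [similarity_params()].
#' @return `data.table` with columns `left_id`, `right_id`, `step`, `score`.
#' @export
run_step <- function(left, right, step, params = similarity_params()) {
  .check_normalized(left, "left"); .check_normalized(right, "right")
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  if (step$method == "deterministic") {
    key <- if (step$slk_variant == "full") "slk_full" else "slk_mother_trimmed"
    lt <- data.table::data.table(left_id = left$record_id, k = left[[key]])[!is.na(k)]
    rt <- data.table::data.table(right_id = right$record_id, k = right[[key]])[!is.na(k)]
    pairs <- merge(lt, rt, by = "k", allow.cartesian = TRUE)[, .(left_id, right_id)]
    pairs[, score := 1.0]
  } else {
    cand <- block_candidates(left, right, step$blocking)
    if (nrow(cand) == 0) {
      pairs <- data.table::data.table(left_id = character(0),
                                      right_id = character(0), score = numeric(0))
    } else {
      sc <- composite_score(left[cand$li], right[cand$ri], step, params)
      pairs <- cand[, .(left_id, right_id)][, score := sc][score > step$threshold]
    }
  }
  out <- resolve_one_to_one(pairs)
  out[, step := step$index]
  data.table::setcolorder(out, c("left_id", "right_id", "step", "score"))[]
}

#' Brute-force reference for a single step
#'
#' Scores the full cross product of records, ignoring blocking during
#' scoring, then applies the same blocking-key equality filter before
#' threshold and one-to-one resolution. Intended as a correctness oracle for
#' [run_step()] on small inputs; quadratic in registry size.
#'
#' @inheritParams run_step
#' @param apply_blocking if `FALSE`, skip the blocking-key filter and keep
#'   every supra-threshold pair (useful to show blocking only removes pairs).
#' @return `data.table` as [run_step()].
#' @export
brute_force_step <- function(left, right, step, params = similarity_params(),
                             apply_blocking = TRUE) {
  .check_normalized(left, "left"); .check_normalized(right, "right")
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  if (nrow(left) == 0 || nrow(right) == 0) {
    out <- data.table::data.table(left_id = character(0), right_id = character(0),
                                  step = integer(0), score = numeric(0))
    return(out)
  }
  all_pairs <- data.table::CJ(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
  if (step$method == "deterministic") {
    key <- if (step$slk_variant == "full") "slk_full" else "slk_mother_trimmed"
    a <- left[[key]][all_pairs$li]; b <- right[[key]][all_pairs$ri]
    keep <- !is.na(a) & !is.na(b) & a == b
    pairs <- all_pairs[keep]
    pairs[, score := 1.0]
  } else {
    sc <- composite_score(left[all_pairs$li], right[all_pairs$ri], step, params)
    pairs <- all_pairs[, score := sc][score > step$threshold]
    if (apply_blocking) {
      for (k in step$blocking) {
        a <- left[[k]][pairs$li]; b <- right[[k]][pairs$ri]
        pairs <- pairs[.key_present(a) & .key_present(b) & a == b]
      }
    }
  }
  pairs[, left_id := left$record_id[li]]
  pairs[, right_id := right$record_id[ri]]
  out <- resolve_one_to_one(pairs[, .(left_id, right_id, score)])
  out[, step := step$index]
  data.table::setcolorder(out, c("left_id", "right_id", "step", "score"))[]
}

#' Run the full hierarchical linkage
#'
#' Executes the strategy's steps in order. After each step, matched records
#' are removed from both registries so later, looser steps only see records
#' that are still unlinked — each record ends with at most one link, tagged
#' with the step that made it.
#'
#' @param left,right normalized registries.
#' @param strategy a [linkage_strategy()]; default [default_strategy()].
#' @param params [similarity_params()].
#' @return an object of class `linkage_result`: a list with `matches`
#'   (`data.table` of `left_id`, `right_id`, `step`, `score`),
#'   `per_step_counts` (named integer vector over step indices) and
#'   `unmatched_left` (character vector of left ids with no link).
#' @export
run_linkage <- function(left, right, strategy = default_strategy(),
                        params = similarity_params()) {
  .check_normalized(left, "left"); .check_normalized(right, "right")
  if (!inherits(strategy, "linkage_strategy")) stop_config("strategy must be a linkage_strategy")
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  if (anyDuplicated(left$record_id)) stop_validation("duplicate record_id in left registry")
  if (anyDuplicated(right$record_id)) stop_validation("duplicate record_id in right registry")

  all_left <- left$record_id
  matches <- vector("list", length(strategy))
  counts <- stats::setNames(integer(length(strategy)),
                            vapply(strategy, `[[`, 1L, "index"))
  lcur <- left; rcur <- right
  for (i in seq_along(strategy)) {
    st <- strategy[[i]]
    m <- run_step(lcur, rcur, st, params)
    matches[[i]] <- m
    counts[[as.character(st$index)]] <- nrow(m)
    if (nrow(m)) {
      lcur <- lcur[!record_id %in% m$left_id]
      rcur <- rcur[!record_id %in% m$right_id]
    }
    if (nrow(lcur) == 0 || nrow(rcur) == 0) break
  }
  all_m <- data.table::rbindlist(matches)
  data.table::setorder(all_m, step, left_id)
  structure(list(matches = all_m,
                 per_step_counts = counts,
                 unmatched_left = setdiff(all_left, all_m$left_id)),
            class = "linkage_result")
}

#' Link two raw registries end to end
#'
#' Convenience wrapper: normalizes both registries and runs the strategy.
#'
#' @param left,right raw registries as returned by [read_registry()].
#' @param strategy a [linkage_strategy()].
#' @param params [similarity_params()].
#' @param particles particles dropped during tokenization.
#' @return a `linkage_result`, see [run_linkage()].
#' @export
link_registries <- function(left, right, strategy = default_strategy(),
                            params = similarity_params(),
                            particles = default_particles()) {
  run_linkage(normalize_registry(left, particles),
              normalize_registry(right, particles),
              strategy, params)
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Linkage result:", nrow(x$matches), "links,",
      length(x$unmatched_left), "left records unmatched\n")
  nz <- x$per_step_counts[x$per_step_counts > 0]
  if (length(nz)) {
    cat("  per step:",
        paste(sprintf("%s:%d", names(nz), nz), collapse = "  "), "\n")
  }
  invisible(x)
}
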