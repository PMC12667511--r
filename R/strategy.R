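#' Define one linkage step
#'
#' A step is either deterministic (exact equality of a statistical linkage
#' key variant) or probabilistic (a weighted average of string similarities
#' over named record fields, accepted when strictly above a threshold, with
#' candidate pairs restricted to those agreeing exactly on the blocking
#' keys).
#'
#' @param index step position in the strategy (1-based, unique).
#' @param method `"deterministic"` or `"probabilistic"`.
#' @param slk_variant for deterministic steps: `"full"` or `"mother_trimmed"`.
#' @param metric for probabilistic steps: `"jaro"` or `"jaro_winkler"`.
#' @param components named numeric vector of positive weights over normalized
#'   field names (e.g. `c(name_joined = 2, mother_joined = 1)`).
#' @param divisor denominator of the weighted sum; defaults to the sum of the
#'   weights so the score stays in \[0, 1\].
#' @param threshold strict lower bound for acceptance (score must exceed it).
#' @param blocking character vector of normalized field names that candidate
#'   pairs must agree on exactly; empty means all pairs are compared.
#' @return an object of class `linkage_step`.
#' @export
linkage_step <- function(index, method = c("probabilistic", "deterministic"),
                         slk_variant = NULL, metric = NULL, components = NULL,
                         divisor = NULL, threshold = NULL,
                         blocking = character(0)) {
  method <- match.arg(method)
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop_config("step index must be a positive integer")
  if (method == "deterministic") {
    if (is.null(slk_variant) || !slk_variant %in% c("full", "mother_trimmed")) {
      stop_config("deterministic step ", index,
                  " needs slk_variant 'full' or 'mother_trimmed'")
    }
    if (length(blocking)) stop_config("deterministic steps take no blocking keys")
    spec <- list(index = index, method = method, slk_variant = slk_variant)
  } else {
    if (is.null(metric) || !metric %in% c("jaro", "jaro_winkler")) {
      stop_config("probabilistic step ", index, " needs metric 'jaro' or 'jaro_winkler'")
    }
    if (is.null(components) || is.null(names(components)) ||
        any(!nzchar(names(components))) || any(components <= 0)) {
      stop_config("probabilistic step ", index,
                  " needs a named vector of positive component weights")
    }
    if (is.null(divisor)) divisor <- sum(components)
    if (divisor <= 0) stop_config("divisor must be positive")
    if (is.null(threshold) || threshold < 0 || threshold > 1) {
      stop_config("probabilistic step ", index, " needs a threshold in [0, 1]")
    }
    spec <- list(index = index, method = method, metric = metric,
                 components = components, divisor = divisor,
                 threshold = threshold, blocking = as.character(blocking))
  }
  structure(spec, class = "linkage_step")
}

#' Assemble steps into a linkage strategy
#'
#' @param ... `linkage_step` objects with strictly increasing, unique indices.
#' @return an object of class `linkage_strategy` (a list of steps).
#' @export
linkage_strategy <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) &&
      !inherits(steps[[1]], "linkage_step")) {
    steps <- steps[[1]]
  }
  if (!length(steps)) stop_config("a strategy needs at least one step")
  ok <- vapply(steps, inherits, TRUE, "linkage_step")
  if (!all(ok)) stop_config("all strategy elements must be linkage_step objects")
  idx <- vapply(steps, `[[`, 1L, "index")
  if (anyDuplicated(idx)) stop_config("step indices must be unique")
  steps <- steps[order(idx)]
  structure(steps, class = "linkage_strategy")
}

#' The default 13-step hierarchical strategy
#'
#' Two deterministic steps on statistical linkage keys (full, then with the
#' mother's final surname dropped), followed by eleven probabilistic steps
#' whose thresholds and blocking keys loosen progressively, so the most
#' confident links are made first and removed from later comparisons.
#'
#' @return a `linkage_strategy` of 13 steps.
#' @export
default_strategy <- function() {
  jw <- "jaro_winkler"
  nm <- "name_joined"; mo <- "mother_joined"
  linkage_strategy(
    linkage_step(1, "deterministic", slk_variant = "full"),
    linkage_step(2, "deterministic", slk_variant = "mother_trimmed"),
    linkage_step(3, metric = jw,
                 components = c(name_joined = 1, mother_joined = 1, dob_digits = 1),
                 divisor = 3, threshold = 0.96,
                 blocking = c("first_name", "second_name",
                              "first_mother_name", "second_mother_name")),
    linkage_step(4, metric = jw,
                 components = c(name_joined = 1, mother_joined = 1),
                 divisor = 2, threshold = 0.95,
                 blocking = c("first_name", "second_name", "first_mother_name",
                              "birth_day", "birth_month")),
    linkage_step(5, metric = "jaro",
                 components = c(name_joined = 2, mother_joined = 1),
                 divisor = 3, threshold = 0.90,
                 blocking = c("first_name", "second_name", "first_mother_name",
                              "second_mother_name", "birth_day", "birth_month")),
    linkage_step(6, metric = jw,
                 components = c(name_joined = 2, mother_joined = 1),
                 divisor = 3, threshold = 0.91,
                 blocking = c("first_name", "second_name", "birth_day", "birth_month")),
    linkage_step(7, metric = jw,
                 components = c(name_joined = 2, mother_joined = 1),
                 divisor = 3, threshold = 0.96,
                 blocking = c("first_name", "birth_day", "birth_month")),
    linkage_step(8, metric = jw,
                 components = c(name_joined = 1, mother_no_last = 1),
                 divisor = 2, threshold = 0.97,
                 blocking = c("first_name", "birth_day", "birth_year")),
    linkage_step(9, metric = jw,
                 components = c(name_no_last = 1, dob_digits = 1),
                 divisor = 2, threshold = 0.99,
                 blocking = c("first_name", "second_name", "birth_month", "birth_year")),
    linkage_step(10, metric = "jaro",
                 components = c(name_joined = 1, mother_joined = 1),
                 divisor = 2, threshold = 0.91,
                 blocking = c("first_name", "birth_day", "birth_year")),
    linkage_step(11, metric = "jaro",
                 components = c(first_name = 1, second_name = 1, last_name = 1,
                                first_mother_name = 1, second_mother_name = 1),
                 divisor = 5, threshold = 0.97,
                 blocking = c("birth_day", "birth_month", "birth_year")),
    linkage_step(12, metric = jw,
                 components = c(name_joined = 1, mother_joined = 1),
                 divisor = 2, threshold = 0.98,
                 blocking = c("dob_digits", "first_mother_name")),
    linkage_step(13, metric = jw,
                 components = c(name_joined = 1),
                 divisor = 1, threshold = 0.95,
                 blocking = c("first_mother_name", "birth_day", "birth_month",
                              "birth_year"))
  )
}

#' Read a linkage strategy from a YAML file
#'
#' The file holds a list `steps:`; each entry gives `index`, `method`, and
#' either `slk_variant` (deterministic) or `metric`, `components` (a mapping
#' of field name to weight), optional `divisor`, `threshold` and `blocking`
#' (probabilistic).
#'
#' @param path YAML file path.
#' @return a `linkage_strategy`.
#' @export
read_strategy <- function(path) {
  if (!file.exists(path)) stop_config("strategy file not found: ", path)
  doc <- yaml::read_yaml(path)
  steps <- doc$steps
  if (is.null(steps)) stop_config("strategy file has no 'steps' list: ", path)
  built <- lapply(steps, function(s) {
    if (identical(s$method, "deterministic")) {
      linkage_step(s$index, "deterministic", slk_variant = s$slk_variant)
    } else {
      comp <- unlist(s$components)
      linkage_step(s$index, "probabilistic", metric = s$metric,
                   components = comp,
                   divisor = if (is.null(s$divisor)) sum(comp) else s$divisor,
                   threshold = s$threshold,
                   blocking = as.character(unlist(s$blocking)))
    }
  })
  linkage_strategy(built)
}

#' Write a linkage strategy to a YAML file
#'
#' @param strategy a `linkage_strategy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strategy <- function(strategy, path) {
  steps <- lapply(strategy, function(s) {
    if (s$method == "deterministic") {
      list(index = s$index, method = s$method, slk_variant = s$slk_variant)
    } else {
      list(index = s$index, method = s$method, metric = s$metric,
           components = as.list(s$components), divisor = s$divisor,
           threshold = s$threshold, blocking = as.list(s$blocking))
    }
  })
  yaml::write_yaml(list(steps = steps), path)
  invisible(path)
}

#' @export
print.linkage_strategy <- function(x, ...) {
  cat("Linkage strategy with", length(x), "steps\n")
  for (s in x) {
    if (s$method == "deterministic") {
      cat(sprintf("  %2d det  SLK[%s]\n", s$index, s$slk_variant))
    } else {
      comp <- paste(sprintf("%g*%s", s$components, names(s$components)),
                    collapse = " + ")
      cat(sprintf("  %2d prob %s (%s)/%g > %.2f  block: %s\n", s$index,
                  s$metric, comp, s$divisor, s$threshold,
                  if (length(s$blocking)) paste(s$blocking, collapse = ",") else "-"))
    }
  }
  invisible(x)
}
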