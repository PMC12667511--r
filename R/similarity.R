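#' Parameters of the Jaro-Winkler prefix adjustment
#'
#' `scale` is the prefix scaling factor (bonus per shared leading character),
#' `max_prefix` caps the rewarded prefix length, and `boost_threshold` is the
#' minimum Jaro score above which the prefix bonus is applied at all. The
#' defaults (0.1, 4, 0.7) are the canonical Winkler constants, shared by the
#' common SQL and Python implementations of the metric.
#'
#' @param scale prefix scaling factor, in \[0, 0.25\] so the result stays <= 1.
#' @param max_prefix maximum rewarded prefix length, non-negative integer.
#' @param boost_threshold Jaro score above which the bonus applies, in \[0, 1\].
#' @return an object of class `similarity_params`.
#' @export
similarity_params <- function(scale = 0.1, max_prefix = 4L, boost_threshold = 0.7) {
  if (scale < 0 || scale > 0.25) stop_config("scale must lie in [0, 0.25]")
  if (max_prefix < 0) stop_config("max_prefix must be non-negative")
  if (boost_threshold < 0 || boost_threshold > 1) {
    stop_config("boost_threshold must lie in [0, 1]")
  }
  structure(list(scale = scale, max_prefix = as.integer(max_prefix),
                 boost_threshold = boost_threshold),
            class = "similarity_params")
}

#' Jaro string similarity
#'
#' Fraction-based similarity built from the number of characters of `a` and
#' `b` that match within a sliding window of half the longer length, and the
#' number of transposed matched pairs. Two empty strings score 1; an empty
#' string against a non-empty one scores 0. Vectorized with recycling.
#'
#' @param a,b character vectors (compared element-wise, shorter recycled).
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' jaro("MARTHA", "MARHTA")
#' @export
jaro <- function(a, b) {
  .jaro_cpp(as.character(a), as.character(b))
}

#' Jaro-Winkler string similarity
#'
#' The Jaro score plus a bonus proportional to the length of the common
#' prefix: `j + l * scale * (1 - j)` where `l` is the shared prefix length
#' capped at `max_prefix`, applied only when `j` exceeds `boost_threshold`.
#' Rewarding prefixes suits person names, where early characters are typed
#' most reliably.
#'
#' @inheritParams jaro
#' @param params a [similarity_params()] object.
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")
#' jaro_winkler("DWAYNE", "DUANE")
#' @export
jaro_winkler <- function(a, b, params = similarity_params()) {
  .jaro_winkler_cpp(as.character(a), as.character(b),
                    params$scale, params$max_prefix, params$boost_threshold)
}
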