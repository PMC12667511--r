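#' Portuguese name particles dropped during tokenization
#'
#' The connective particles of Brazilian full names ("DA", "DE", "DO", "DAS",
#' "DOS", "E") carry no identifying information and are removed before token
#' roles (first / second / last name) are assigned. The list is a convention,
#' not a fixed rule of the method, and every function that tokenizes accepts
#' its own `particles` argument.
#'
#' @return character vector of particles.
#' @export
default_particles <- function() c("DA", "DE", "DO", "DAS", "DOS", "E")

#' Canonicalize raw name text
#'
#' Uppercases, folds diacritics to ASCII (c-cedilla to C, tilde-a to A, ...),
#' strips punctuation and digits, collapses runs of whitespace and trims.
#' Idempotent: applying it twice gives the same result as applying it once.
#'
#' @param x character vector of raw text; `NA` is treated as empty.
#' @return character vector of canonical text (possibly empty strings).
#' @examples
#' normalize_text("José  da Conceição")
#' @export
normalize_text <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_trans_toupper(x)
  x <- gsub("[^A-Z]+", " ", x)
  x <- gsub("^ +| +$", "", x)
  x
}

#' Split a canonical name into identifying tokens
#'
#' Splits on spaces and removes Portuguese particles, preserving order.
#'
#' @param canonical a single canonical string (output of [normalize_text()]).
#' @param particles particles to drop, see [default_particles()].
#' @return character vector of tokens (length 0 for empty or all-particle input).
#' @examples
#' tokenize_name("JOSE DA SILVA SANTOS")
#' @export
tokenize_name <- function(canonical, particles = default_particles()) {
  stopifnot(length(canonical) == 1)
  .tokenize_all(canonical, particles)[[1]]
}

.tokenize_all <- function(canonical, particles) {
  toks <- strsplit(canonical, " ", fixed = TRUE)
  lapply(toks, function(t) t[nzchar(t) & !(t %in% particles)])
}

#' Assign first / second / last roles to name tokens
#'
#' The first and second tokens become first and second name; the final token
#' is the last name when at least two tokens exist (with exactly two tokens
#' the second and last name coincide). Missing roles are empty strings.
#'
#' @param tokens character vector from [tokenize_name()].
#' @return named character vector `c(first=, second=, last=)`.
#' @export
assign_token_roles <- function(tokens) {
  n <- length(tokens)
  c(first  = if (n >= 1) tokens[1] else "",
    second = if (n >= 2) tokens[2] else "",
    last   = if (n >= 2) tokens[n] else "")
}

#' Drop the final surname from a joined name
#'
#' Removes the last space-delimited token; a single-token name is returned
#' unchanged since its only token cannot be dropped.
#'
#' @param joined character vector of canonical joined names.
#' @return character vector.
#' @examples
#' drop_last_surname("ANA SOUZA SILVA")
#' @export
drop_last_surname <- function(joined) {
  sub("\\s+\\S+$", "", joined)
}

#' Build a statistical linkage key
#'
#' Concatenates the de-spaced name, the de-spaced mother's name (optionally
#' with its final surname dropped) and the date of birth as YYYYMMDD, joined
#' with "|" so that component boundaries stay unambiguous. The key is `NA`
#' whenever any component is missing or empty: a partial key would collide
#' with unrelated records.
#'
#' @param normalized a normalized registry, see [normalize_registry()].
#' @param variant `"full"` (step 1) or `"mother_trimmed"` (step 2, mother's
#'   name without its last surname).
#' @return character vector of keys, `NA` where undefined.
#' @export
build_slk <- function(normalized, variant = c("full", "mother_trimmed")) {
  variant <- match.arg(variant)
  mother <- if (variant == "full") normalized$mother_joined else normalized$mother_no_last
  name <- normalized$name_joined
  dob <- normalized$dob_digits
  key <- paste0(gsub(" ", "", name, fixed = TRUE), "|",
                gsub(" ", "", mother, fixed = TRUE), "|", dob)
  key[!nzchar(name) | !nzchar(mother) | is.na(dob)] <- NA_character_
  key
}

#' Normalize a registry into comparison-ready form
#'
#' Expands each raw record into the canonical fields the linkage strategy
#' compares and blocks on: joined (particle-free) names, token roles for both
#' the person's and the mother's name, date-of-birth parts, the zero-padded
#' `dob_digits` string, and both statistical linkage key variants.
#'
#' @param registry data.frame with columns `record_id`, `full_name`,
#'   `mother_name`, `birth_date` (`Date`), optionally `truth_ref`; see
#'   [read_registry()].
#' @param particles particles dropped during tokenization.
#' @return a `data.table`, one row per record, with columns `record_id`,
#'   `name_joined`, `mother_joined`, `first_name`, `second_name`, `last_name`,
#'   `first_mother_name`, `second_mother_name`, `name_no_last`,
#'   `mother_no_last`, `birth_day`, `birth_month`, `birth_year`, `dob_digits`,
#'   `slk_full`, `slk_mother_trimmed` (and `truth_ref` if present).
#' @export
normalize_registry <- function(registry, particles = default_particles()) {
  stopifnot(is.data.frame(registry))
  req <- c("record_id", "full_name", "mother_name", "birth_date")
  miss <- setdiff(req, names(registry))
  if (length(miss)) stop_config("registry lacks columns: ", paste(miss, collapse = ", "))

  name_tok <- .tokenize_all(normalize_text(registry$full_name), particles)
  moth_tok <- .tokenize_all(normalize_text(registry$mother_name), particles)
  join <- function(tl) vapply(tl, paste, "", collapse = " ")
  role <- function(tl, i) vapply(tl, function(t) {
    n <- length(t)
    if (i == 1L) { if (n >= 1) t[1] else "" }
    else if (i == 2L) { if (n >= 2) t[2] else "" }
    else { if (n >= 2) t[n] else "" }
  }, "")

  bd <- as.Date(registry$birth_date)
  out <- data.table::data.table(
    record_id = as.character(registry$record_id),
    name_joined = join(name_tok),
    mother_joined = join(moth_tok),
    first_name = role(name_tok, 1L),
    second_name = role(name_tok, 2L),
    last_name = role(name_tok, 3L),
    first_mother_name = role(moth_tok, 1L),
    second_mother_name = role(moth_tok, 2L),
    birth_day = as.integer(format(bd, "%d")),
    birth_month = as.integer(format(bd, "%m")),
    birth_year = as.integer(format(bd, "%Y")),
    dob_digits = format(bd, "%Y%m%d")
  )
  out[, name_no_last := drop_last_surname(name_joined)]
  out[, mother_no_last := drop_last_surname(mother_joined)]
  out[, slk_full := build_slk(out, "full")]
  out[, slk_mother_trimmed := build_slk(out, "mother_trimmed")]
  if ("truth_ref" %in% names(registry)) {
    tr <- as.character(registry$truth_ref)
    tr[!is.na(tr) & !nzchar(tr)] <- NA_character_
    out[, truth_ref := tr]
  }
  out[]
}
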