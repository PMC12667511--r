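# Name pools for the synthetic registry generator: common Brazilian given
# names and surnames, pre-canonicalized (uppercase, no diacritics) so that
# generated text is a fixed point of normalize_text().

.br_given_names <- c(
  "MARIA", "JOSE", "ANA", "JOAO", "ANTONIO", "FRANCISCO", "CARLOS", "PAULO",
  "PEDRO", "LUCAS", "LUIZ", "MARCOS", "LUIS", "GABRIEL", "RAFAEL", "DANIEL",
  "MARCELO", "BRUNO", "EDUARDO", "FELIPE", "RAIMUNDO", "RODRIGO", "MANOEL",
  "MATEUS", "ANDRE", "FERNANDO", "FABIO", "LEONARDO", "GUSTAVO", "GUILHERME",
  "LEANDRO", "TIAGO", "SEBASTIAO", "ALEXANDRE", "RICARDO", "JORGE", "SERGIO",
  "CLAUDIO", "GERALDO", "ADRIANO", "ROBERTO", "DIEGO", "VITOR", "MURILO",
  "HEITOR", "JULIO", "CESAR", "RENATO", "BENEDITO", "MAURICIO", "OTAVIO",
  "DOUGLAS", "WELLINGTON", "VANDERLEI", "GILBERTO", "ROGERIO", "SAMUEL",
  "ALAN", "IGOR", "CAIO", "DAVI", "ARTHUR", "BERNARDO", "ENZO", "NICOLAS",
  "FRANCISCA", "ANTONIA", "ADRIANA", "JULIANA", "MARCIA", "FERNANDA",
  "PATRICIA", "ALINE", "SANDRA", "CAMILA", "AMANDA", "BRUNA", "JESSICA",
  "LETICIA", "JULIA", "LUCIANA", "VANESSA", "MARIANA", "GABRIELA", "VERA",
  "VITORIA", "LARISSA", "CLAUDIA", "BEATRIZ", "RITA", "TEREZA", "SONIA",
  "ROSANGELA", "SIMONE", "ELIANE", "RAIMUNDA", "RENATA", "JOSEFA", "CRISTINA",
  "DANIELA", "MARTA", "IRENE", "HELENA", "ALICE", "LAURA", "CECILIA",
  "CAROLINA", "PRISCILA", "TATIANE", "MICHELE", "ROSA", "NEUSA", "IVONE",
  "REGINA", "APARECIDA", "FATIMA", "LOURDES", "GRACA", "CONCEICAO", "SOCORRO",
  "SUELI", "MARLENE", "ZILDA", "NAIR", "ODETE", "DIRCE", "IRACEMA", "JANDIRA",
  "EDNA", "ELZA", "WILSON", "NELSON", "OSVALDO", "WALDEMAR", "DURVAL",
  "LAZARO", "JOAQUIM", "VALDIR", "AILTON", "EVERTON", "JAIR", "OSMAR",
  "DJALMA", "ARNALDO", "EURIDES", "ALZIRA", "CREUSA", "DALVA", "EUNICE",
  "GENI", "ILDA", "JUREMA", "LAURINDA", "MADALENA", "NOEMIA", "OLINDA",
  "PALMIRA", "QUITERIA", "ROSALINA", "SEVERINA", "TEREZINHA", "VALDENICE",
  "WANDA", "ZENAIDE", "ADEMIR", "BENTO", "CICERO", "DOMINGOS", "ELIAS",
  "FLAVIO", "GENIVALDO", "HAMILTON", "ISRAEL", "JONAS", "KLEBER", "LINDOMAR",
  "MOACIR", "NIVALDO", "ORLANDO", "PLINIO", "QUIRINO", "RUBENS", "SALOMAO",
  "TEODORO", "UBIRAJARA", "VALMIR", "WAGNER", "XAVIER", "YARA", "ZELIA"
)

.br_surnames <- c(
  "SILVA", "SANTOS", "OLIVEIRA", "SOUZA", "RODRIGUES", "FERREIRA", "ALVES",
  "PEREIRA", "LIMA", "GOMES", "COSTA", "RIBEIRO", "MARTINS", "CARVALHO",
  "ALMEIDA", "LOPES", "SOARES", "FERNANDES", "VIEIRA", "BARBOSA", "ROCHA",
  "DIAS", "NASCIMENTO", "ANDRADE", "MOREIRA", "NUNES", "MARQUES", "MACHADO",
  "MENDES", "FREITAS", "CARDOSO", "RAMOS", "GONCALVES", "SANTANA", "TEIXEIRA",
  "ARAUJO", "MELO", "BARROS", "PINTO", "MONTEIRO", "CAMPOS", "CORREIA",
  "CAVALCANTI", "DUARTE", "MORAES", "REIS", "MIRANDA", "BATISTA", "NOGUEIRA",
  "BRITO", "MOURA", "AZEVEDO", "CUNHA", "FARIAS", "QUEIROZ", "BORGES",
  "MEDEIROS", "CASTRO", "TAVARES", "SALES", "XAVIER", "PAIVA", "AGUIAR",
  "MAGALHAES", "SIQUEIRA", "BEZERRA", "GUIMARAES", "PACHECO", "VASCONCELOS",
  "COELHO", "FOGACA", "REZENDE", "SANTIAGO", "ASSIS", "MAIA", "CRUZ",
  "VARGAS", "FONSECA", "AMARAL", "PIRES", "BRANDAO", "PRADO", "LEAL",
  "BUENO", "MOTA", "ANTUNES", "ESTEVES", "CHAVES", "BITTENCOURT", "SAMPAIO",
  "LACERDA", "VALE", "GUEDES", "ABREU", "SERRA", "DOMINGUES", "TELES",
  "CAMARGO", "PENA", "NEVES", "PORTO", "BRAGA", "VALENTE", "FURTADO",
  "DANTAS", "PESSOA", "FIGUEIREDO", "CORDEIRO", "GALVAO", "MESQUITA",
  "BARRETO", "PARENTE", "AMORIM", "SEVERO", "MENEZES", "TRINDADE", "VILELA",
  "ORNELAS", "QUADROS", "JARDIM", "SALDANHA", "PEIXOTO", "BENTES", "CALDAS",
  "LESSA", "FRAGOSO", "HOLANDA", "ULHOA", "ZAGO", "YUNES", "WANDERLEY"
)

#' Benchmark cohort design
#'
#' Sizes of the injected true-positive set and of the negative pool, plus
#' the seed fixing the whole benchmark. Prevalence is
#' `n_true_pos / (n_true_pos + n_true_neg)`.
#'
#' @param n_true_pos number of records with a true counterpart.
#' @param n_true_neg number of records without one.
#' @param seed integer seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_true_pos, n_true_neg, seed = 1L) {
  if (n_true_pos < 0 || n_true_neg < 0 || n_true_pos + n_true_neg <= 0) {
    stop_config("need non-negative counts with a positive sum")
  }
  structure(list(n_true_pos = as.integer(n_true_pos),
                 n_true_neg = as.integer(n_true_neg),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Typographical corruption model
#'
#' Per-operator application rates, all in \[0, 1\]. Character-level operators
#' (substitution, transposition, deletion) and the token swap apply
#' independently to the full name and to the mother's name; the surname drop
#' applies to the full name, blanking to the mother's name, and the two date
#' operators to the birth date. The defaults emulate the error burden of
#' hurriedly typed surveillance records: most records survive untouched, a
#' minority carries one or two defects.
#'
#' @param substitution rate of replacing one letter with another.
#' @param transposition rate of swapping two adjacent letters.
#' @param deletion rate of deleting one letter.
#' @param token_swap rate of exchanging two name tokens.
#' @param surname_drop rate of losing the final surname.
#' @param mother_blank rate of losing the mother's name entirely.
#' @param date_swap rate of exchanging day and month (when the result is a
#'   valid date).
#' @param date_digit rate of a single wrong digit in the date.
#' @param scale multiplier applied to every rate (capped at 1), convenient
#'   for stress sweeps.
#' @return an object of class `corruption_config`.
#' @export
corruption_config <- function(substitution = 0.05, transposition = 0.02,
                              deletion = 0.02, token_swap = 0.02,
                              surname_drop = 0.05, mother_blank = 0.03,
                              date_swap = 0.02, date_digit = 0.02,
                              scale = 1) {
  rates <- c(substitution = substitution, transposition = transposition,
             deletion = deletion, token_swap = token_swap,
             surname_drop = surname_drop, mother_blank = mother_blank,
             date_swap = date_swap, date_digit = date_digit)
  if (any(rates < 0) || any(rates > 1)) stop_config("rates must lie in [0, 1]")
  if (scale < 0) stop_config("scale must be non-negative")
  structure(as.list(pmin(rates * scale, 1)), class = "corruption_config")
}

.rand_int <- function(n, max) floor(stats::runif(n) * max) + 1L

#' Draw synthetic Brazilian-style person records
#'
#' Full names are one or two given names followed by one to three surnames,
#' with connective particles (DA, DE, DOS, ...) inserted before surnames
#' with fixed probability. The mother's name shares at least one surname
#' with the person with probability 0.6, reflecting family names. Birth
#' dates are uniform over `date_range`. Uses the current RNG state: call
#' `set.seed()` first for reproducibility.
#'
#' @param n number of records.
#' @param id_prefix prefix for the generated `record_id`s.
#' @param date_range two `Date`s, inclusive bounds for birth dates.
#' @param particle_prob probability that a surname gets a particle.
#' @return raw registry `data.table` (`record_id`, `full_name`,
#'   `mother_name`, `birth_date`).
#' @export
sample_person <- function(n, id_prefix = "P",
                          date_range = as.Date(c("1930-01-01", "2005-12-31")),
                          particle_prob = 0.25) {
  n <- as.integer(n)
  if (n <= 0) {
    return(data.table::data.table(record_id = character(0), full_name = character(0),
                                  mother_name = character(0),
                                  birth_date = as.Date(character(0))))
  }
  particles <- c("DA", "DE", "DO", "DAS", "DOS")
  mk_surnames <- function(k, forced = NULL) {
    s <- c(forced, sample(.br_surnames, k - length(forced)))
    dec <- stats::runif(k) < particle_prob
    s[dec] <- paste(sample(particles, sum(dec), replace = TRUE), s[dec])
    s
  }
  mk_name <- function(forced_surname = NULL) {
    g <- sample(.br_given_names, 1L + (stats::runif(1) < 0.4))
    k <- sample(1:3, 1, prob = c(0.35, 0.45, 0.20))
    if (!is.null(forced_surname)) k <- max(k, 1L)
    paste(c(g, mk_surnames(k, forced_surname)), collapse = " ")
  }
  full <- character(n); mother <- character(n)
  for (i in seq_len(n)) {
    full[i] <- mk_name()
    toks <- strsplit(full[i], " ", fixed = TRUE)[[1]]
    own_last <- toks[length(toks)]
    shared <- if (stats::runif(1) < 0.6) own_last else NULL
    mother[i] <- mk_name(shared)
  }
  span <- as.integer(date_range[2] - date_range[1])
  bd <- date_range[1] + .rand_int(n, span + 1L) - 1L
  data.table::data.table(
    record_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    full_name = full, mother_name = mother, birth_date = bd)
}

.corrupt_chars <- function(x, op) {
  ch <- strsplit(x, "")[[1]]
  letters_at <- which(ch %in% LETTERS)
  if (!length(letters_at)) return(x)
  if (op == "substitution") {
    i <- letters_at[.rand_int(1, length(letters_at))]
    ch[i] <- sample(setdiff(LETTERS, ch[i]), 1)
  } else if (op == "deletion") {
    i <- letters_at[.rand_int(1, length(letters_at))]
    ch <- ch[-i]
  } else if (op == "transposition") {
    adj <- letters_at[letters_at < length(ch) & ch[pmin(letters_at + 1L, length(ch))] %in% LETTERS]
    adj <- adj[ch[adj] != ch[adj + 1L]]
    if (!length(adj)) return(x)
    i <- adj[.rand_int(1, length(adj))]
    ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
  }
  out <- paste(ch, collapse = "")
  gsub("^ +| +$", "", gsub(" +", " ", out))
}

.swap_tokens <- function(x) {
  t <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (length(t) < 2) return(x)
  i <- sort(sample(length(t), 2))
  t[i] <- t[rev(i)]
  paste(t, collapse = " ")
}

.date_digit_error <- function(d) {
  s <- format(d, "%Y%m%d")
  for (attempt in 1:10) {
    i <- .rand_int(1, 8L)
    dig <- substr(s, i, i)
    repl <- sample(setdiff(as.character(0:9), dig), 1)
    cand <- s
    substr(cand, i, i) <- repl
    parsed <- as.Date(cand, format = "%Y%m%d")
    if (!is.na(parsed)) return(parsed)
  }
  d
}

#' Corrupt one record with typographical errors
#'
#' Each operator in `config` fires independently with its configured rate.
#' The corrupted copy gets a fresh `record_id` and a `truth_ref` pointing at
#' the original, so ground truth survives the corruption. Uses the current
#' RNG state.
#'
#' @param record one-row raw registry.
#' @param config a [corruption_config()].
#' @param new_id id for the corrupted copy.
#' @return list with `record` (one-row registry with `truth_ref`) and `log`
#'   (character vector naming the operators applied, e.g. `"name:deletion"`).
#' @export
corrupt_record <- function(record, config, new_id = paste0(record$record_id, "-C")) {
  record <- data.table::as.data.table(record)
  stopifnot(nrow(record) == 1)
  name <- record$full_name
  mother <- record$mother_name
  bd <- record$birth_date
  log <- character(0)

  for (fld in c("name", "mother")) {
    val <- if (fld == "name") name else mother
    if (!nzchar(val)) next
    for (op in c("substitution", "transposition", "deletion")) {
      if (stats::runif(1) < config[[op]]) {
        val <- .corrupt_chars(val, op)
        log <- c(log, paste0(fld, ":", op))
      }
    }
    if (stats::runif(1) < config$token_swap) {
      val <- .swap_tokens(val)
      log <- c(log, paste0(fld, ":token_swap"))
    }
    if (fld == "name") name <- val else mother <- val
  }
  if (nzchar(name) && stats::runif(1) < config$surname_drop) {
    t <- strsplit(name, " ", fixed = TRUE)[[1]]
    if (length(t) >= 2) {
      name <- paste(t[-length(t)], collapse = " ")
      log <- c(log, "name:surname_drop")
    }
  }
  if (stats::runif(1) < config$mother_blank) {
    mother <- ""
    log <- c(log, "mother:blank")
  }
  if (!is.na(bd) && stats::runif(1) < config$date_swap) {
    d <- as.integer(format(bd, "%d")); m <- as.integer(format(bd, "%m"))
    swapped <- as.Date(sprintf("%s-%02d-%02d", format(bd, "%Y"), d, m),
                       format = "%Y-%m-%d")
    if (!is.na(swapped) && swapped != bd) {
      bd <- swapped
      log <- c(log, "date:day_month_swap")
    }
  }
  if (!is.na(bd) && stats::runif(1) < config$date_digit) {
    nd <- .date_digit_error(bd)
    if (nd != bd) {
      bd <- nd
      log <- c(log, "date:digit_error")
    }
  }
  out <- data.table::data.table(record_id = new_id, full_name = name,
                                mother_name = mother, birth_date = bd,
                                truth_ref = record$record_id)
  list(record = out, log = log)
}

#' Build a benchmark registry pair with known ground truth
#'
#' Emulates a validation design for mortality-surveillance linkage: a fixed
#' set of true positives is injected into a pool of negatives. `test1` holds
#' the `n_true_pos` original positive records (with `truth_ref` naming their
#' counterpart) plus `n_true_neg` records absent from `test2`; `test2` holds
#' corrupted copies of the positives plus `n_distractor` independent
#' records. Row orders are shuffled so position carries no truth signal.
#'
#' @param design a [cohort_design()].
#' @param config a [corruption_config()]; use rates 0 for a clean benchmark.
#' @param n_distractor number of independent right-side records; defaults to
#'   the number of positives.
#' @param hard_negatives if `TRUE`, each distractor copies the first given
#'   name of a random positive, stressing false-positive behavior.
#' @param date_range passed to [sample_person()].
#' @return list with `test1`, `test2` (raw registries) and `truth`
#'   (`data.table` of `test1_id`, `test2_id`), plus `logs` (per corrupted
#'   record).
#' @export
build_benchmark <- function(design, config = corruption_config(),
                            n_distractor = design$n_true_pos,
                            hard_negatives = FALSE,
                            date_range = as.Date(c("1930-01-01", "2005-12-31"))) {
  if (!inherits(design, "cohort_design")) stop_config("design must be a cohort_design")
  set.seed(design$seed)
  npos <- design$n_true_pos; nneg <- design$n_true_neg
  pool <- sample_person(npos + nneg + n_distractor, id_prefix = "S",
                        date_range = date_range)
  pos <- pool[seq_len(npos)]
  neg <- pool[npos + seq_len(nneg)]
  dis <- pool[npos + nneg + seq_len(n_distractor)]
  data.table::set(pos, j = "record_id", value = sprintf("T1P%06d", seq_len(npos)))
  data.table::set(neg, j = "record_id", value = sprintf("T1N%06d", seq_len(nneg)))
  data.table::set(dis, j = "record_id", value = sprintf("T2D%06d", seq_len(n_distractor)))
  if (hard_negatives && npos > 0 && n_distractor > 0) {
    donor <- pos$full_name[.rand_int(n_distractor, npos)]
    first <- vapply(strsplit(donor, " ", fixed = TRUE), `[[`, "", 1L)
    rest <- vapply(strsplit(dis$full_name, " ", fixed = TRUE),
                   function(t) paste(t[-1], collapse = " "), "")
    data.table::set(dis, j = "full_name", value = paste(first, rest))
  }

  corr <- vector("list", npos)
  logs <- vector("list", npos)
  for (i in seq_len(npos)) {
    res <- corrupt_record(pos[i], config, new_id = sprintf("T2P%06d", i))
    corr[[i]] <- res$record
    logs[[i]] <- res$log
  }
  test2 <- data.table::rbindlist(c(
    corr, list(dis[, .(record_id, full_name, mother_name, birth_date,
                       truth_ref = NA_character_)])))
  truth <- data.table::data.table(
    test1_id = pos$record_id,
    test2_id = if (npos) sprintf("T2P%06d", seq_len(npos)) else character(0))
  test1 <- data.table::rbindlist(list(
    pos[, .(record_id, full_name, mother_name, birth_date,
            truth_ref = truth$test2_id)],
    neg[, .(record_id, full_name, mother_name, birth_date,
            truth_ref = NA_character_)]))
  test1 <- test1[sample(nrow(test1))]
  test2 <- test2[sample(nrow(test2))]
  names(logs) <- truth$test2_id
  list(test1 = test1, test2 = test2, truth = truth, logs = logs)
}
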