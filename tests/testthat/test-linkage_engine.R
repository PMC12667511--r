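norm_toy <- function(...) normalize_registry(data.table::rbindlist(list(...)))

rec <- function(id, name, mother, dob) {
  data.table::data.table(record_id = id, full_name = name,
                         mother_name = mother,
                         birth_date = as.Date(dob))
}

test_that("blocking returns exactly the key-agreeing pairs", {
  left <- norm_toy(rec("A", "MARIA SILVA", "ANA SOUZA", "1950-01-02"))
  right <- norm_toy(rec("B", "MARIA LIMA", "RITA DIAS", "1960-02-03"),
                    rec("C", "ANA PINTO", "ROSA REIS", "1970-03-04"))
  got <- block_candidates(left, right, "first_name")
  expect_equal(got[, .(left_id, right_id)],
               data.table::data.table(left_id = "A", right_id = "B"))
  expect_equal(nrow(block_candidates(left, right, character(0))), 2L)
  expect_error(block_candidates(left, right, "shoe_size"),
               class = "hierlink_config_error")

  # records missing a key value yield no candidates for that step
  left2 <- norm_toy(rec("D", "MARIA", "ANA SOUZA", NA))
  expect_equal(nrow(block_candidates(left2, right, c("first_name", "birth_day"))), 0L)
  expect_equal(nrow(block_candidates(left2, right, "second_name")), 0L)
})

test_that("blocking equals a brute-force filter of the cross product", {
  set.seed(33)
  pair <- random_registry_pair(25, 25, 25)
  for (keys in list("first_name",
                    c("first_name", "birth_day", "birth_month"),
                    c("birth_day", "birth_month", "birth_year"),
                    c("dob_digits", "first_mother_name"))) {
    got <- block_candidates(pair$left, pair$right, keys)
    cross <- data.table::CJ(li = seq_len(nrow(pair$left)),
                            ri = seq_len(nrow(pair$right)))
    keep <- rep(TRUE, nrow(cross))
    for (k in keys) {
      a <- pair$left[[k]][cross$li]; b <- pair$right[[k]][cross$ri]
      ok <- if (is.character(a)) !is.na(a) & nzchar(a) else !is.na(a)
      okb <- if (is.character(b)) !is.na(b) & nzchar(b) else !is.na(b)
      keep <- keep & ok & okb & !is.na(a == b) & a == b
    }
    expect_equal(got[, .(li, ri)], cross[keep][order(li, ri)], ignore_attr = TRUE)
  }
})

test_that("composite scores are the weighted similarity average with missing parts as zero", {
  s <- default_strategy()
  l <- norm_toy(rec("A", "MARIA SILVA", "ANA SOUZA", "1950-01-02"))
  r_same <- norm_toy(rec("B", "MARIA SILVA", "ANA SOUZA", "1977-05-05"))
  expect_equal(composite_score(l, r_same, s[[4]]), 1.0)  # name+mother identical

  # step 3 on records differing only in the date digit string
  r_dob <- norm_toy(rec("B", "MARIA SILVA", "ANA SOUZA", "1950-01-03"))
  expect_equal(composite_score(l, r_dob, s[[3]]),
               (1 + 1 + oracle_jaro_winkler("19500102", "19500103")) / 3,
               tolerance = 1e-12)

  # step 6 arithmetic on the stated weights (2*name + mother)/3
  r_diff <- norm_toy(rec("B", "MARIA SALVA", "ANA SOUSA", "1950-01-02"))
  expect_equal(composite_score(l, r_diff, s[[6]]),
               (2 * oracle_jaro_winkler("MARIA SILVA", "MARIA SALVA") +
                  oracle_jaro_winkler("ANA SOUZA", "ANA SOUSA")) / 3,
               tolerance = 1e-12)

  # a missing component contributes zero but keeps its weight in the divisor
  r_nomom <- norm_toy(rec("B", "MARIA SILVA", "", "1950-01-02"))
  expect_equal(composite_score(l, r_nomom, s[[6]]), 2 / 3, tolerance = 1e-12)
})

test_that("one-to-one resolution is greedy by score with lexicographic ties", {
  scored <- data.table::data.table(
    left_id = c("L1", "L1", "L2"), right_id = c("R1", "R2", "R1"),
    score = c(0.99, 0.97, 0.98))
  got <- resolve_one_to_one(scored)
  expect_equal(got[, .(left_id, right_id)],
               data.table::data.table(left_id = "L1", right_id = "R1"))

  disjoint <- data.table::data.table(left_id = c("L1", "L2"),
                                     right_id = c("R1", "R2"),
                                     score = c(0.95, 0.99))
  expect_equal(nrow(resolve_one_to_one(disjoint)), 2L)

  tied <- data.table::data.table(left_id = c("L1", "L1"),
                                 right_id = c("R2", "R1"),
                                 score = c(0.99, 0.99))
  expect_equal(resolve_one_to_one(tied)$right_id, "R1")
})

test_that("deterministic steps distinguish the two linkage-key variants", {
  # mothers differ only in their final surname: full key differs, trimmed agrees
  left <- norm_toy(rec("A", "MARIA SILVA", "ANA SOUZA SILVA", "1950-01-02"))
  right <- norm_toy(rec("B", "MARIA SILVA", "ANA SOUZA SANTOS", "1950-01-02"))
  s <- default_strategy()
  expect_equal(nrow(run_step(left, right, s[[1]])), 0L)
  m2 <- run_step(left, right, s[[2]])
  expect_equal(m2$left_id, "A")
  expect_equal(m2$score, 1.0)
  expect_equal(m2$step, 2L)

  dup_l <- norm_toy(rec("A", "MARIA SILVA", "ANA SOUZA", "1950-01-02"))
  dup_r <- norm_toy(rec("B", "MARIA SILVA", "ANA SOUZA", "1950-01-02"))
  m1 <- run_step(dup_l, dup_r, s[[1]])
  expect_equal(m1$score, 1.0)
})

test_that("a probabilistic step accepts exactly the supra-threshold blocked pairs", {
  s <- default_strategy()
  # typo sits in the final surname so every step-4 blocking key still agrees
  left <- norm_toy(rec("A", "MARIA SILVA SANTOS", "ANA SOUZA", "1950-01-02"))
  right <- norm_toy(rec("B", "MARIA SILVA SANTUS", "ANA SOUZA", "1950-01-02"))
  jw <- oracle_jaro_winkler("MARIA SILVA SANTOS", "MARIA SILVA SANTUS")
  m <- run_step(left, right, s[[4]])
  expect_gt((jw + 1) / 2, 0.95)
  expect_equal(m$left_id, "A")
  expect_equal(m$score, (jw + 1) / 2, tolerance = 1e-12)

  # same pair with a harsher threshold is rejected: strict inequality
  harsh <- linkage_step(4, metric = "jaro_winkler",
                        components = c(name_joined = 1, mother_joined = 1),
                        divisor = 2, threshold = (jw + 1) / 2,
                        blocking = s[[4]]$blocking)
  expect_equal(nrow(run_step(left, right, harsh)), 0L)
})

test_that("run_step agrees with the brute-force oracle across all steps", {
  set.seed(44)
  s <- default_strategy()
  for (rep_i in 1:3) {
    pair <- random_registry_pair(30, 20, 20)
    for (st in s) {
      fast <- run_step(pair$left, pair$right, st)
      slow <- brute_force_step(pair$left, pair$right, st)
      data.table::setorder(fast, left_id); data.table::setorder(slow, left_id)
      expect_equal(fast, slow, ignore_attr = TRUE)
    }
  }
})

test_that("blocking only removes candidates, never adds them", {
  set.seed(55)
  pair <- random_registry_pair(30, 15, 15)
  s <- default_strategy()
  for (st in s[3:13]) {
    blocked <- brute_force_step(pair$left, pair$right, st)
    open <- brute_force_step(pair$left, pair$right, st, apply_blocking = FALSE)
    expect_true(all(paste(blocked$left_id, blocked$right_id) %in%
                      paste(open$left_id, open$right_id) |
                      nrow(blocked) == 0))
    expect_gte(nrow(open), nrow(blocked))
  }
})

test_that("full linkage links clean duplicates at step 1 and reports the rest unmatched", {
  reg <- data.table::rbindlist(list(
    rec("1", "MARIA SILVA", "ANA SOUZA", "1950-01-02"),
    rec("2", "JOSE SANTOS", "RITA LIMA", "1960-03-04"),
    rec("3", "ANA PINTO", "ROSA REIS", "1970-05-06"),
    rec("4", "CARLOS DIAS", "VERA MOTA", "1980-07-08"),
    rec("5", "PAULO ROCHA", "ALICE NEVES", "1990-09-10")))
  nr <- normalize_registry(reg)
  res <- run_linkage(nr, nr)
  expect_equal(nrow(res$matches), 5L)
  expect_true(all(res$matches$step == 1L))
  expect_length(res$unmatched_left, 0L)

  lonely <- normalize_registry(data.table::rbindlist(list(
    reg, rec("9", "XAVIER ULHOA ZAGO", "YARA YUNES", "1931-11-11"))))
  res2 <- run_linkage(lonely, nr)
  expect_equal(res2$unmatched_left, "9")
})

test_that("hierarchical removal keeps matches one-to-one and step-disjoint", {
  set.seed(66)
  pair <- random_registry_pair(60, 30, 30)
  res <- run_linkage(pair$left, pair$right)
  m <- res$matches
  expect_false(anyDuplicated(m$left_id) > 0)
  expect_false(anyDuplicated(m$right_id) > 0)
  expect_equal(sum(res$per_step_counts), nrow(m))
  expect_setequal(union(m$left_id, res$unmatched_left), pair$left$record_id)

  # determinism: identical inputs give identical results
  res_again <- run_linkage(pair$left, pair$right)
  expect_identical(res$matches, res_again$matches)

  # permuting the step order may move attributions but never breaks one-to-one
  perm <- default_strategy()[c(2, 1, 5, 4, 3, 7, 6, 9, 8, 11, 10, 13, 12)]
  for (i in seq_along(perm)) perm[[i]]$index <- i
  res_perm <- run_linkage(pair$left, pair$right, linkage_strategy(perm))
  expect_false(anyDuplicated(res_perm$matches$left_id) > 0)
  expect_false(anyDuplicated(res_perm$matches$right_id) > 0)
})
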