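# Small registry fixtures built in code.

toy_registry <- function() {
  data.table::data.table(
    record_id = c("L1", "L2", "L3"),
    full_name = c("MARIA SILVA", "JOSE DA SILVA SANTOS", "ANA SOUZA LIMA"),
    mother_name = c("ANA SOUZA", "TEREZA SANTOS DIAS", "CLARA LIMA PINTO"),
    birth_date = as.Date(c("1950-01-02", "1964-07-30", "1980-12-05"))
  )
}

# A pair of messy registries with overlapping people, for oracle-equivalence
# runs: corrupted duplicates plus independent records on both sides.
random_registry_pair <- function(n_shared, n_only_left, n_only_right,
                                 corruption = hierlink::corruption_config(scale = 3)) {
  base <- hierlink::sample_person(n_shared + n_only_left, id_prefix = "L")
  right_extra <- hierlink::sample_person(n_only_right, id_prefix = "X")
  shared <- base[seq_len(n_shared)]
  corrupted <- data.table::rbindlist(lapply(seq_len(n_shared), function(i) {
    hierlink::corrupt_record(shared[i], corruption,
                             new_id = sprintf("R%04d", i))$record
  }))
  left <- base[, .(record_id, full_name, mother_name, birth_date)]
  right <- data.table::rbindlist(list(
    corrupted[, .(record_id, full_name, mother_name, birth_date)],
    right_extra[, .(record_id, full_name, mother_name, birth_date)]))
  list(left = hierlink::normalize_registry(left),
       right = hierlink::normalize_registry(right))
}
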