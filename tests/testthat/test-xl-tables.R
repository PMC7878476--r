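toy_records <- function() {
  tibble::tibble(
    protein_a = "dnajb8", residue_a = c(34L, 208L, 34L),
    restype_a = c("K", "E", "K"),
    protein_b = "dnajb8", residue_b = c(208L, 34L, 208L),
    restype_b = c("E", "K", "E"),
    chemistry = "dmtmm", condition = "PBS_150mM",
    score = c(0.9, 0.8, 0.95)
  )
}

test_that("xl table round-trips through TSV and validates columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- toy_records()
  write_xl_table(rec, path)
  back <- read_xl_table(path)
  expect_equal(back[names(rec)], rec)
  expect_equal(back$intermolecular, rep("ambiguous", 3))

  # empty table with header
  write_xl_table(rec[0, ], path)
  expect_equal(nrow(read_xl_table(path)), 0)

  # missing mandatory column is named
  bad <- rec
  bad$chemistry <- NULL
  write_xl_table(bad, path)
  expect_error(read_xl_table(path), "chemistry")

  # residue 0 errors with the line number
  bad2 <- rec
  bad2$residue_a[2] <- 0L
  write_xl_table(bad2, path)
  expect_error(read_xl_table(path), "line 3")
})

test_that("records incompatible with their chemistry are flagged invalid", {
  rec <- toy_records()
  rec$restype_a[2] <- "G"
  out <- validate_xl_records(rec)
  expect_equal(out$valid, c(TRUE, FALSE, TRUE))
})

test_that("deduplication collapses symmetric and repeated pairs", {
  rec <- toy_records() # (34,208), (208,34), (34,208) -> one pair
  dd <- xl_deduplicate(rec)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$residue_a, 34L)
  expect_equal(dd$residue_b, 208L)
  expect_equal(dd$n_records, 3L)

  disjoint <- tibble::tibble(
    protein_a = "p", residue_a = c(1L, 2L), restype_a = "E",
    protein_b = "p", residue_b = c(5L, 6L), restype_b = "E",
    chemistry = "adh", condition = "c"
  )
  expect_equal(nrow(xl_deduplicate(disjoint)), 2)
})

test_that("deduplication matches the brute-force set oracle", {
  for (seed in 1:25) {
    rec <- random_xl_records(20, seed = seed)
    expect_equal(nrow(xl_deduplicate(rec)), oracle_dedup_count(rec))
  }
})

test_that("domain classification is symmetric and matches the map", {
  dm <- dnajb8_domains()
  p <- tibble::tibble(residue_a = c(34, 50, 90), residue_b = c(208, 60, 100))
  cls <- classify_pairs(p, dm)$class
  expect_equal(cls, c("CTD–JD", "JD–JD", "G/F–G/F"))
  # symmetry under end swap
  p_swap <- tibble::tibble(residue_a = p$residue_b, residue_b = p$residue_a)
  expect_equal(classify_pairs(p_swap, dm)$class, cls)
  # out-of-range residue
  p_out <- tibble::tibble(residue_a = 500, residue_b = 10)
  expect_match(classify_pairs(p_out, dm)$class, "unassigned")
})

test_that("contact map class counts sum to unique pairs and match oracle", {
  empty <- random_xl_records(5)[0, ]
  cm0 <- xl_contact_map(empty)
  expect_equal(nrow(cm0$pairs), 0)
  expect_equal(sum(cm0$class_counts$n_pairs), 0)

  planted <- tibble::tibble(
    protein_a = "p", residue_a = c(10L, 20L, 34L), restype_a = "E",
    protein_b = "p", residue_b = c(50L, 60L, 208L), restype_b = "K",
    chemistry = "dmtmm", condition = "c"
  )
  cm <- xl_contact_map(planted)
  counts <- setNames(cm$class_counts$n_pairs, cm$class_counts$class)
  expect_equal(counts[["JD–JD"]], 2L)
  expect_equal(counts[["CTD–JD"]], 1L)

  set.seed(42)
  rec <- random_xl_records(50, seed = 99)
  rec <- rec[rec$residue_a != rec$residue_b, ]
  cm2 <- xl_contact_map(rec)
  expect_equal(sum(cm2$class_counts$n_pairs), nrow(cm2$pairs))
  dm <- dnajb8_domains()
  oracle <- table(mapply(oracle_class, cm2$pairs$residue_a,
                         cm2$pairs$residue_b,
                         MoreArgs = list(domain_map = dm)))
  got <- setNames(cm2$class_counts$n_pairs, cm2$class_counts$class)
  expect_equal(got[sort(names(oracle))],
               c(oracle)[sort(names(oracle))])
})

test_that("condition comparison yields disjoint exhaustive sets", {
  rec <- dplyr::bind_rows(
    tibble::tibble(protein_a = "p", residue_a = c(34L, 50L),
                   restype_a = "E", protein_b = "p",
                   residue_b = c(208L, 60L), restype_b = "K",
                   chemistry = "dmtmm", condition = "PBS_150mM"),
    tibble::tibble(protein_a = "p", residue_a = 50L, restype_a = "E",
                   protein_b = "p", residue_b = 60L, restype_b = "K",
                   chemistry = "dmtmm", condition = "PBS_285mM")
  )
  cmp <- compare_conditions(rec, "PBS_150mM", "PBS_285mM")
  expect_equal(sort(cmp$status), c("a_only", "shared"))
  expect_equal(cmp$residue_a[cmp$status == "a_only"], 34L)
  expect_error(compare_conditions(rec, "PBS_150mM", "nope"), "nope")

  # identical conditions: everything shared
  rec2 <- rec
  rec2$condition <- "x"
  rec2b <- rec
  rec2b$condition <- "y"
  cmp2 <- compare_conditions(dplyr::bind_rows(rec2, rec2b), "x", "y")
  expect_true(all(cmp2$status == "shared"))
})

test_that("condition comparison matches brute-force set algebra", {
  for (seed in 1:20) {
    rec <- random_xl_records(30, n_res = 50, seed = seed + 100)
    cmp <- compare_conditions(rec, "PBS_150mM", "PBS_285mM")
    a_keys <- unique(oracle_pair_keys(
      rec[rec$condition == "PBS_150mM", ], with = character()))
    b_keys <- unique(oracle_pair_keys(
      rec[rec$condition == "PBS_285mM", ], with = character()))
    expect_equal(sum(cmp$status == "shared"),
                 length(intersect(a_keys, b_keys)))
    expect_equal(sum(cmp$status == "a_only"),
                 length(setdiff(a_keys, b_keys)))
    expect_equal(sum(cmp$status == "b_only"),
                 length(setdiff(b_keys, a_keys)))
    expect_equal(nrow(cmp), length(union(a_keys, b_keys)))
  }
})

test_that("monolink frequencies count per residue and compare conditions", {
  ml <- tibble::tibble(
    protein = "p", residue = c(208L, 208L, 208L, 10L),
    restype = "E", chemistry = "adh",
    condition = c("a", "a", "a", "a")
  )
  counts <- monolink_frequency(ml)
  expect_equal(counts$n[counts$residue == 208], 3L)
  expect_equal(nrow(monolink_frequency(ml[0, ])), 0)

  # equal planted counts in two conditions -> all differences zero
  ml2 <- dplyr::bind_rows(ml, dplyr::mutate(ml, condition = "b"))
  cmp <- monolink_frequency(ml2, "a", "b")
  expect_true(all(cmp$difference == 0))
})

test_that("covariation overlap applies threshold and window like the oracle", {
  pairs <- tibble::tibble(residue_a = 40L, residue_b = 210L)
  covar <- tibble::tibble(i = 40L, j = 210L, probability = 0.9)
  expect_equal(covariation_overlap(pairs, covar, window = 0)$count, 1)
  covar$probability <- 0.5
  expect_equal(covariation_overlap(pairs, covar, window = 0)$count, 0)
  expect_error(covariation_overlap(pairs, covar, window = -1))

  set.seed(7)
  for (seed in 1:10) {
    set.seed(seed)
    pairs <- tibble::tibble(residue_a = sample.int(100, 15),
                            residue_b = sample.int(100, 15))
    covar <- tibble::tibble(i = sample.int(100, 40, replace = TRUE),
                            j = sample.int(100, 40, replace = TRUE),
                            probability = runif(40))
    got <- covariation_overlap(pairs, covar, 0.7, 2)
    want <- oracle_covar_overlap(pairs, covar, 0.7, 2)
    expect_equal(got$per_pair$overlaps, want)
    expect_equal(got$fraction, mean(want))
  }
})

test_that("per-class counts are invariant under record shuffling", {
  rec <- random_xl_records(40, seed = 5)
  rec <- rec[rec$residue_a != rec$residue_b, ]
  cm1 <- xl_contact_map(rec)
  set.seed(1)
  cm2 <- xl_contact_map(rec[sample(nrow(rec)), ])
  expect_equal(cm1$class_counts, cm2$class_counts)
})
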