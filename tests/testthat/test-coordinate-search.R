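test_that("build_index splits compound variants and excludes missing coordinates", {
  snv <- kbmatch:::new_record("variant", 1, list(
    name = "snv", coordinates = coordinates("7", 100, 100,
                                            reference_bases = "A",
                                            variant_bases = "T")))
  nocoord <- kbmatch:::new_record("variant", 2, list(
    name = "nowhere", coordinates = coordinates()))
  fusion <- kbmatch:::new_record("variant", 3, list(
    name = "fus", coordinates = coordinates("2", 500, 600,
                                            chromosome2 = "4",
                                            start2 = 900, stop2 = 950)))
  idx <- build_index(list(snv, nocoord, fusion))
  expect_equal(nrow(idx), 3)                       # 1 + 0 + 2
  expect_equal(sum(idx$variant_id == 3), 2)        # two rows, one variant
  expect_equal(length(unique(idx$variant_key[idx$variant_id == 3])), 1)
  rep <- attr(idx, "build_report")
  expect_equal(rep$n_excluded, 1)
  expect_equal(rep$n_indexed, 2)
  expect_equal(nrow(build_index(list())), 0)
})

test_that("index ordering equals a generic tuple sort", {
  set.seed(11)
  inst <- random_instance(200, 0, chroms = c("1", "2", "10", "X", "MT"))
  idx <- index_from_table(inst$entries)
  # oracle: generic order() over the same tuples with the natural chromosome rank
  e <- inst$entries
  ord <- order(chromosome_rank(e$chromosome), e$start, e$stop, e$alt,
               e$variant_id, method = "radix", na.last = FALSE)
  expect_equal(idx$variant_id, e$variant_id[ord])
  expect_equal(idx$start, e$start[ord])
  # deterministic under rebuild
  expect_equal(index_from_table(inst$entries)$variant_id, idx$variant_id)
})

test_that("the match predicate follows the four mode definitions", {
  q <- list(chromosome = "1", start = 5, stop = 10, alt = "T")
  e_same <- list(chromosome = "1", start = 5, stop = 10, alt = "T")
  for (m in all_modes)
    expect_true(coordinates_match(q, e_same, m), label = m)

  # query encompasses the record: any and QE only
  q_wide <- list(chromosome = "1", start = 3, stop = 12, alt = NA)
  e_mid <- list(chromosome = "1", start = 5, stop = 10, alt = NA)
  expect_true(coordinates_match(q_wide, e_mid, "any"))
  expect_true(coordinates_match(q_wide, e_mid, "query_encompassing"))
  expect_false(coordinates_match(q_wide, e_mid, "record_encompassing"))
  expect_false(coordinates_match(q_wide, e_mid, "exact"))

  # allele mismatch blocks exact only
  e_alt <- list(chromosome = "1", start = 5, stop = 10, alt = "G")
  expect_false(coordinates_match(q, e_alt, "exact"))
  for (m in c("any", "query_encompassing", "record_encompassing"))
    expect_true(coordinates_match(q, e_alt, m), label = m)
  # wildcard and absent query alleles match any entry allele exactly
  q_wild <- modifyList(q, list(alt = "*"))
  q_null <- modifyList(q, list(alt = NA))
  expect_true(coordinates_match(q_wild, e_alt, "exact"))
  expect_true(coordinates_match(q_null, e_alt, "exact"))
  # chromosomes must agree
  expect_false(coordinates_match(modifyList(q, list(chromosome = "2")),
                                 e_same, "any"))
  expect_error(match_mode("fuzzy"), "unknown match mode")
})

test_that("bulk_search agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    inst <- random_instance(sample(0:60, 1), sample(0:40, 1))
    idx <- index_from_table(inst$entries)
    q <- coordinate_queries(inst$queries)
    for (m in all_modes) {
      expect_identical(plain_result(bulk_search(idx, q, m)),
                       oracle_search(inst$entries, inst$queries, m),
                       label = sprintf("rep %d mode %s", rep, m))
    }
  }
})

test_that("a long entry is reported for every overlapping query (pointer restore)", {
  entries <- data.frame(chromosome = "1",
                        start = c(1L, seq(1000L, 900000L, by = 1000L)),
                        stop = c(1000000L, seq(1000L, 900000L, by = 1000L) + 10L),
                        alt = NA_character_, stringsAsFactors = FALSE)
  entries$variant_id <- seq_len(nrow(entries))
  idx <- index_from_table(entries)
  qs <- seq(5000L, 895000L, by = 4973L)
  queries <- data.frame(chromosome = "1", start = qs, stop = qs + 5L)
  res <- bulk_search(idx, coordinate_queries(queries), "any")
  expect_true(all(vapply(res, function(v) 1L %in% v, logical(1))))
  expect_identical(plain_result(res), oracle_search(entries, queries, "any"))
})

test_that("mode nesting: exact within QE intersect RE within any", {
  set.seed(202)
  for (rep in 1:25) {
    inst <- random_instance(40, 25)
    idx <- index_from_table(inst$entries)
    q <- coordinate_queries(inst$queries)
    r <- lapply(setNames(nm = all_modes), function(m)
      plain_result(bulk_search(idx, q, m)))
    for (i in seq_len(nrow(inst$queries))) {
      both <- intersect(r$query_encompassing[[i]], r$record_encompassing[[i]])
      expect_true(all(r$exact[[i]] %in% both))
      expect_true(all(both %in% r$any[[i]]))
    }
  }
})

test_that("query order never changes match sets, only mapping order", {
  set.seed(303)
  inst <- random_instance(50, 30)
  idx <- index_from_table(inst$entries)
  perm <- sample.int(nrow(inst$queries))
  r1 <- plain_result(bulk_search(idx, coordinate_queries(inst$queries), "any"))
  r2 <- plain_result(bulk_search(idx,
                                 coordinate_queries(inst$queries[perm, ]),
                                 "any"))
  expect_identical(r2, r1[perm])
})

test_that("search_single equals bulk_search on a singleton", {
  set.seed(404)
  inst <- random_instance(60, 1)
  idx <- index_from_table(inst$entries)
  q <- inst$queries[1, ]
  for (m in all_modes) {
    expect_identical(search_single(idx, q, m),
                     bulk_search(idx, coordinate_queries(inst$queries), m)[[1]])
  }
  # exact query at a known fixture SNV returns exactly that variant
  coll <- parse_snapshot(tiny_snapshot())
  fx <- build_index(coll)
  hit <- search_single(fx, list(chromosome = "7", start = 140453136,
                                stop = 140453136, alt = "T"), "exact")
  expect_identical(hit, 10L)
  expect_identical(search_single(fx, list(chromosome = "12", start = 1,
                                          stop = 1), "any"), integer(0))
})

test_that("build mismatch and empty index contracts hold", {
  coll <- parse_snapshot(tiny_snapshot())
  idx <- build_index(coll)
  q38 <- coordinate_queries(data.frame(chromosome = "7", start = 1, stop = 2),
                            build = "GRCh38")
  expect_error(bulk_search(idx, q38, "any"), "build mismatch")
  empty <- build_index(list())
  res <- bulk_search(empty,
                     coordinate_queries(data.frame(chromosome = "7",
                                                   start = 1, stop = 10)),
                     "any")
  expect_identical(plain_result(res), list(integer(0)))
  expect_length(bulk_search(idx, coordinate_queries(
    data.frame(chromosome = character(0), start = integer(0),
               stop = integer(0))), "any"), 0)
})

test_that("a compound variant matching on both halves is reported once", {
  fusion <- kbmatch:::new_record("variant", 9, list(
    name = "fus", coordinates = coordinates("2", 100, 200,
                                            chromosome2 = "2",
                                            start2 = 150, stop2 = 400)))
  idx <- build_index(list(fusion))
  res <- bulk_search(idx, coordinate_queries(
    data.frame(chromosome = "2", start = 1, stop = 1000)), "any")
  expect_identical(res[[1]], 9L)
})
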