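mk_variant <- function(id, ..., evidence = list(), assertions = list(),
                       name = sprintf("v%d", id)) {
  kbmatch:::new_record("variant", id, list(
    name = name, aliases = character(0), variant_types = character(0),
    coordinates = coordinates(...), evidence = evidence,
    assertions = assertions))
}

mk_evidence <- function(id, status = "accepted", level = "B", ...) {
  kbmatch:::new_record("evidence", id, c(list(
    variant_id = 1L, status = status, evidence_level = level,
    evidence_direction = "Supports",
    clinical_significance = "Sensitivity/Response",
    disease = attribute_blob("disease", list(name = "melanoma")),
    drugs = list(), source_id = NA_integer_, rating = 4L), list(...)))
}

mk_assertion <- function(id, status = "accepted") {
  kbmatch:::new_record("assertion", id, list(
    status = status, amp_category = "Tier I", variant_id = 1L,
    evidence_ids = integer(0),
    disease = attribute_blob("disease", list(name = "melanoma")),
    drugs = list()))
}

test_that("VCF validity rules cover SNVs, indels, fusions and gaps", {
  snv <- mk_variant(1, "7", 140453136, 140453136,
                    reference_bases = "A", variant_bases = "T")
  expect_true(is_valid_for_vcf(snv))
  ins <- mk_variant(2, "5", 100, 100, variant_bases = "GATC")
  expect_true(is_valid_for_vcf(ins))            # insertions: alt only
  del <- mk_variant(3, "5", 200, 203, reference_bases = "ACGT")
  expect_true(is_valid_for_vcf(del))            # deletions: ref only
  fus <- mk_variant(4, "2", 100, 200, chromosome2 = "4",
                    start2 = 900, stop2 = 950)
  v <- is_valid_for_vcf(fus)
  expect_false(v); expect_equal(attr(v, "reason"), "second_coordinate_set")
  nostart <- mk_variant(5, "7", NA, NA)
  v <- is_valid_for_vcf(nostart)
  expect_false(v); expect_equal(attr(v, "reason"), "missing_position")
  bare <- mk_variant(6, "7", 100, 300)          # range with no alleles
  v <- is_valid_for_vcf(bare)
  expect_false(v); expect_equal(attr(v, "reason"), "missing_alleles")
})

test_that("add_record keeps valid drafts and warns (never errors) on invalid", {
  w <- vcf_writer("accepted")
  ok <- list(
    mk_variant(1, "7", 10, 10, reference_bases = "A", variant_bases = "T",
               evidence = list(mk_evidence(1))),
    mk_variant(2, "7", 20, 20, variant_bases = "G",
               evidence = list(mk_evidence(2))),
    mk_variant(3, "1", 30, 31, reference_bases = "AT",
               evidence = list(mk_evidence(3))))
  for (v in ok) expect_silent(add_record(w, v))
  fus <- mk_variant(4, "2", 1, 2, chromosome2 = "3", start2 = 5, stop2 = 6)
  expect_warning(add_record(w, fus), "second_coordinate_set")
  expect_length(w$drafts, 3)
  expect_equal(w$skipped$reason, "second_coordinate_set")

  # two variants sharing chrom/pos/ref stay separate records; no dedup on
  # double-add either
  w2 <- vcf_writer("accepted")
  a <- mk_variant(5, "7", 10, 10, reference_bases = "A", variant_bases = "T",
                  evidence = list(mk_evidence(4)))
  b <- mk_variant(6, "7", 10, 10, reference_bases = "A", variant_bases = "C",
                  evidence = list(mk_evidence(5)))
  add_record(w2, a); add_record(w2, b); add_record(w2, a)
  expect_length(w2$drafts, 3)
})

test_that("build_csq_entries emits one status-passing entry per statement", {
  v <- mk_variant(1, "7", 10, 10, reference_bases = "A", variant_bases = "T",
                  evidence = list(mk_evidence(11, "accepted"),
                                  mk_evidence(12, "accepted"),
                                  mk_evidence(13, "rejected")),
                  assertions = list(mk_assertion(21, "accepted")))
  entries <- build_csq_entries(v, "accepted", allele = "T")
  expect_length(entries, 3)                     # 2 evidence + 1 assertion
  nfields <- length(csq_fields())
  # count separators: strsplit would drop trailing empty fields
  expect_true(all(nchar(gsub("[^|]", "", entries)) + 1L == nfields))
  parts <- strsplit(entries, "|", fixed = TRUE)
  type_col <- which(csq_fields() == "KB_Entity_Type")
  expect_equal(vapply(parts, `[[`, "", type_col),
               c("evidence", "evidence", "assertion"))
  id_col <- which(csq_fields() == "KB_Entity_ID")
  expect_equal(vapply(parts, `[[`, "", id_col), c("11", "12", "21"))
  expect_length(build_csq_entries(v, "submitted"), 0)
})

test_that("CSQ escaping follows the documented reversible dialect", {
  expect_equal(encode_csq_value("loss of function"), "loss_of_function")
  expect_equal(encode_csq_value("a;b"), "a%3Bb")
  expect_equal(encode_csq_value(""), "")
  expect_equal(encode_csq_value("snake_case"), "snake%5Fcase")
  expect_equal(decode_csq_value("snake%5Fcase"), "snake_case")
  expect_equal(decode_csq_value("loss_of_function"), "loss of function")

  set.seed(9)
  pool <- rawToChar(as.raw(32:126), multiple = TRUE)
  for (i in 1:200) {
    s <- paste(sample(pool, sample(0:25, 1), replace = TRUE), collapse = "")
    enc <- encode_csq_value(s)
    expect_false(grepl("[ ;,=|]", enc), label = s)
    expect_identical(decode_csq_value(enc), s, label = s)
  }
  # multibyte input survives the byte-wise escape
  s <- enc2utf8("résistance µM")
  expect_identical(decode_csq_value(encode_csq_value(s)), s)
})

test_that("write_records emits parseable VCF 4.2 with correct CSQ counts", {
  w <- vcf_writer(c("accepted", "submitted"))
  v1 <- mk_variant(1, "7", 140453136, 140453136, reference_bases = "A",
                   variant_bases = "T",
                   evidence = list(mk_evidence(1, "accepted"),
                                   mk_evidence(2, "submitted"),
                                   mk_evidence(3, "rejected")))
  v2 <- mk_variant(2, "1", 500, 500, variant_bases = "GG",
                   evidence = list(mk_evidence(4, "accepted")),
                   assertions = list(mk_assertion(5, "accepted")))
  v3 <- mk_variant(3, "1", 900, 902, reference_bases = "TTT",
                   evidence = list(mk_evidence(6, "rejected")))
  for (v in list(v1, v2, v3)) add_record(w, v)
  out <- tempfile(fileext = ".vcf")
  n <- write_records(w, out)
  expect_equal(n, 2)               # v3 has no status-passing statements
  expect_error(write_records(w, out), "finalized")

  lines <- readLines(out)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  # sorted by chromosome natural order then position: chr1 before chr7
  expect_match(body[1], "^1\t500\t2\tN\tNGG\t")
  expect_match(body[2], "^7\t140453136\t1\tA\tT\t")
  # CSQ entry counts per record match build_csq_entries
  info <- sub(".*CSQ=", "", body)
  expect_equal(lengths(strsplit(info, ",", fixed = TRUE)), c(2L, 2L))
  # every entry splits into the declared field count; no reserved chars
  ent <- unlist(strsplit(info, ",", fixed = TRUE))
  expect_true(all(nchar(gsub("[^|]", "", ent)) + 1L ==
                    length(csq_fields())))
  vals <- unlist(strsplit(ent, "|", fixed = TRUE))
  expect_false(any(grepl("[ ;,=]", vals)))

  # an independent parser accepts the document
  vcf <- VariantAnnotation::readVcf(out, genome = "GRCh37")
  expect_equal(nrow(vcf), 2)
  csq <- unlist(VariantAnnotation::info(vcf)$CSQ)
  expect_length(csq, 4)

  # header-only documents still parse
  w0 <- vcf_writer("accepted")
  out0 <- tempfile(fileext = ".vcf")
  expect_equal(write_records(w0, out0), 0)
  expect_equal(nrow(VariantAnnotation::readVcf(out0, genome = "GRCh37")), 0)
})
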