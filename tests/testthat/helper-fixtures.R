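# Fixtures are built in code; nothing binary ships with the tests.

# Write a snapshot JSON file from plain R lists, filling in the envelope.
write_snapshot <- function(..., path = tempfile(fileext = ".json")) {
  doc <- list(format = "kb-snapshot", version = 1, reference_build = "GRCh37",
              genes = list(), variants = list(), variant_groups = list(),
              evidence = list(), assertions = list(), sources = list(),
              users = list(), organizations = list())
  over <- list(...)
  for (nm in names(over)) doc[[nm]] <- over[[nm]]
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           null = "null", digits = NA)),
             path, useBytes = TRUE)
  path
}

# Hand-built fixture: 1 gene, 2 variants, 3 evidence, 1 assertion, 1 source.
tiny_snapshot <- function(path = tempfile(fileext = ".json")) {
  write_snapshot(
    genes = list(list(id = 1, name = "BRAF", variant_ids = list(10, 11))),
    variants = list(
      list(id = 10, gene_id = 1, name = "V600E",
           aliases = list("p.Val600Glu"),
           variant_types = list("missense_variant"),
           coordinates = list(chromosome = "7", start = 140453136,
                              stop = 140453136, reference_bases = "A",
                              variant_bases = "T"),
           evidence_ids = list(100, 101), assertion_ids = list(500)),
      list(id = 11, gene_id = 1, name = "V600K",
           coordinates = list(chromosome = "7", start = 140453136,
                              stop = 140453137, reference_bases = "AC",
                              variant_bases = "TT"),
           evidence_ids = list(102), assertion_ids = list())),
    evidence = list(
      list(id = 100, variant_id = 10, status = "accepted",
           evidence_level = "A", evidence_direction = "Supports",
           clinical_significance = "Sensitivity/Response",
           disease = list(name = "melanoma"),
           drugs = list(list(name = "vemurafenib")),
           source_id = 900, rating = 5),
      list(id = 101, variant_id = 10, status = "rejected",
           evidence_level = "C", source_id = 900),
      list(id = 102, variant_id = 11, status = "submitted",
           evidence_level = "B", source_id = 900)),
    assertions = list(
      list(id = 500, variant_id = 10, status = "accepted",
           amp_category = "Tier I", evidence_ids = list(100))),
    sources = list(list(id = 900, citation = "Author et al., 2011",
                        source_type = "PubMed", citation_id = "21639808")),
    path = path)
}

# Build a coordinate index directly from a table of entries by wrapping each
# row in a minimal variant record (one variant per row).
index_from_table <- function(df) {
  df <- as.data.frame(df)
  variants <- lapply(seq_len(nrow(df)), function(i) {
    vb <- df$alt[i]
    kbmatch:::new_record("variant", df$variant_id[i], list(
      name = sprintf("v%d", df$variant_id[i]), aliases = character(0),
      variant_types = character(0), evidence = list(), assertions = list(),
      coordinates = coordinates(chromosome = df$chromosome[i],
                                start = df$start[i], stop = df$stop[i],
                                variant_bases = if (is.na(vb)) NA else vb)))
  })
  build_index(variants)
}

# Independent all-pairs oracle: per query, test every entry directly from
# the mode definitions (vectorized over entries, no pointer logic).
oracle_search <- function(entries, queries, mode) {
  entries <- as.data.frame(entries)
  queries <- as.data.frame(queries)
  lapply(seq_len(nrow(queries)), function(i) {
    qs <- queries$start[i]; qe <- queries$stop[i]
    qa <- if ("alt" %in% names(queries)) queries$alt[i] else NA_character_
    same <- entries$chromosome == queries$chromosome[i]
    es <- entries$start; ee <- entries$stop; ea <- entries$alt
    ok <- switch(mode,
      any = qs <= ee & es <= qe,
      query_encompassing = es >= qs & ee <= qe,
      record_encompassing = qs >= es & qe <= ee,
      exact = es == qs & ee == qe &
        (is.na(qa) | qa == "*" | (!is.na(ea) & ea == qa)))
    sort(unique(entries$variant_id[same & ok]))
  })
}

# Random search instance over a small genome.
random_instance <- function(n, m, chroms = c("1", "2", "X"),
                            span = 500L, maxlen = 30L) {
  alts <- c(NA, "A", "C", "G", "T")
  mk <- function(k, with_key = FALSE) {
    if (k == 0L)
      return(data.frame(chromosome = character(0), start = integer(0),
                        stop = integer(0), alt = character(0),
                        stringsAsFactors = FALSE))
    start <- sample.int(span, k, replace = TRUE)
    len <- pmin(1L + rgeom(k, 1 / 4), maxlen)
    data.frame(chromosome = sample(chroms, k, replace = TRUE),
               start = start, stop = start + len - 1L,
               alt = sample(alts, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  entries <- mk(n)
  entries$variant_id <- seq_len(nrow(entries))
  list(entries = entries, queries = mk(m))
}

all_modes <- c("exact", "query_encompassing", "record_encompassing", "any")

# Strip attributes for list-of-vectors comparison.
plain_result <- function(res) lapply(res, identity)
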