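MAF_REQUIRED_COLUMNS <- c("Tumor_Sample_Barcode", "Chromosome",
                          "Start_Position", "End_Position",
                          "Reference_Allele", "Tumor_Seq_Allele2")

MATCH_CLASSES <- c("exact", "any_only", "none", "no_variants")

#' Read a MAF-like cohort mutation table
#'
#' Parses a tab-separated per-sample somatic variant table using the
#' standard MAF column names (`Tumor_Sample_Barcode`, `Chromosome`,
#' `Start_Position`, `End_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`). Rows with unparseable coordinates are dropped and
#' counted; duplicated rows are preserved. Allele strings are upper-cased
#' and the MAF `"-"` convention maps to a missing allele.
#'
#' @param path TSV file path (a header row is required).
#' @return `data.table` with columns `sample_barcode`, `chromosome`,
#'   `start`, `stop`, `ref`, `alt`, and attribute `n_dropped`.
#' @export
read_cohort_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = TRUE)
  miss <- setdiff(MAF_REQUIRED_COLUMNS, names(dt))
  if (length(miss))
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  norm_allele <- function(x) {
    x <- toupper(as.character(x))
    x[x %in% c("-", "", ".")] <- NA_character_
    x
  }
  out <- dt[, .(sample_barcode = Tumor_Sample_Barcode,
                chromosome = normalize_chromosome(Chromosome),
                start = suppressWarnings(as.integer(Start_Position)),
                stop = suppressWarnings(as.integer(End_Position)),
                ref = norm_allele(Reference_Allele),
                alt = norm_allele(Tumor_Seq_Allele2))]
  ok <- !is.na(out$start) & !is.na(out$stop) & out$start <= out$stop &
    nzchar(out$sample_barcode) & !is.na(out$chromosome)
  n_dropped <- sum(!ok)
  out <- out[ok]
  setattr(out, "n_dropped", n_dropped)
  out[]
}

#' Convert cohort variants to tagged coordinate queries
#'
#' One query per sample variant, tagged with the tumor sample barcode in
#' the query `key`, sorted by the index ordering. Row identity is
#' recoverable through the `row_id` attribute (original row per sorted
#' query).
#'
#' @param variants Table from [read_cohort_table()] (or equivalent).
#' @param build Genome build label.
#' @return A sorted `kb_queries` table with attribute `row_id`.
#' @export
queries_from_cohort <- function(variants, build = "GRCh37") {
  v <- as.data.table(variants)
  q <- coordinate_queries(
    data.frame(chromosome = v$chromosome, start = v$start, stop = v$stop,
               alt = v$alt, key = v$sample_barcode,
               stringsAsFactors = FALSE), build = build)
  ord <- order(chromosome_rank(q$chromosome), q$start, q$stop, q$alt,
               method = "radix", na.last = FALSE)
  q2 <- q[ord]
  setattr(q2, "reference_build", build)
  setattr(q2, "class", c("kb_queries", class(data.table())))
  setattr(q2, "row_id", seq_len(nrow(v))[ord])
  q2[]
}

#' Classify samples by their match results
#'
#' Per-sample roll-up of exact and any-overlap search results: a sample is
#' class `exact` if at least one of its variants exact-matched, else
#' `any_only` if at least one matched under the any-overlap mode, else
#' `none` if it had variants, else `no_variants`. The classes always
#' partition the cohort. The highest evidence level is summarized over the
#' exact-matched variants only (any-only matches carry no level).
#'
#' @param exact_results,any_results `kb_search_result` objects from
#'   [bulk_search()] over the *same* query list in `exact` / `any` modes.
#' @param all_samples Character vector of every barcode in the cohort,
#'   including samples with zero variants.
#' @param cache Optional `kb_cache` (or `kb_collection`) used to look up
#'   evidence levels of matched variants; when absent, `highest_level` is
#'   `NA` throughout.
#' @param allowed_statuses Statuses whose evidence counts toward the level
#'   summary.
#' @return `data.table` with one row per sample: `sample_barcode`,
#'   `n_variants`, `n_exact`, `n_any_only`, `match_class`, `highest_level`.
#' @export
classify_samples <- function(exact_results, any_results, all_samples,
                             cache = NULL,
                             allowed_statuses = kb_default_statuses()) {
  keys_e <- attr(exact_results, "keys")
  keys_a <- attr(any_results, "keys")
  if (!identical(keys_e, keys_a))
    stop("exact and any results must come from the same query list",
         call. = FALSE)
  unknown <- setdiff(unique(keys_e[!is.na(keys_e)]), all_samples)
  if (length(unknown))
    stop("results reference barcode(s) absent from `all_samples`: ",
         paste(head(unknown, 3L), collapse = ", "), call. = FALSE)

  nhit_e <- vapply(exact_results, length, integer(1)) > 0L
  nhit_a <- vapply(any_results, length, integer(1)) > 0L

  per <- data.table(sample_barcode = keys_e, exact = nhit_e, any = nhit_a)
  agg <- per[, .(n_variants = .N, n_exact = sum(exact),
                 n_any_only = sum(any & !exact)), by = sample_barcode]
  out <- data.table(sample_barcode = all_samples)
  out <- merge(out, agg, by = "sample_barcode", all.x = TRUE, sort = FALSE)
  out[is.na(n_variants), `:=`(n_variants = 0L, n_exact = 0L, n_any_only = 0L)]
  out[, match_class := ifelse(n_variants == 0L, "no_variants",
                       ifelse(n_exact > 0L, "exact",
                       ifelse(n_any_only > 0L, "any_only", "none")))]
  out[, match_class := factor(match_class, levels = MATCH_CLASSES)]

  out[, highest_level := NA_character_]
  if (!is.null(cache)) {
    coll <- if (inherits(cache, "kb_cache")) cache$records else cache
    lvl_cache <- new.env(parent = emptyenv())
    variant_levels <- function(vid) {
      k <- as.character(vid)
      got <- lvl_cache[[k]]
      if (!is.null(got)) return(got)
      v <- kb_get(coll, "variant", vid)
      lv <- character(0)
      if (!is.null(v))
        for (e in v$evidence)
          if (!isTRUE(e$partial) && isTRUE(e$status %in% allowed_statuses) &&
              !is.na(e$evidence_level %na% NA))
            lv <- c(lv, e$evidence_level)
      lvl_cache[[k]] <- lv
      lv
    }
    exact_by_sample <- split(unlist(lapply(seq_along(exact_results),
      function(i) exact_results[[i]])),
      rep(keys_e, times = vapply(exact_results, length, integer(1))))
    for (bc in names(exact_by_sample)) {
      vids <- unique(exact_by_sample[[bc]])
      lv <- unlist(lapply(vids, variant_levels))
      out[sample_barcode == bc,
          highest_level := highest_evidence_level_of(lv)]
    }
  }
  out[]
}

#' Highest evidence level of a set
#'
#' Maximum under the ordering A > B > C > D > E (validated > clinical >
#' case study > preclinical > inferential).
#'
#' @param levels Character vector of levels (possibly empty).
#' @return Single level, or `NA_character_` when empty.
#' @export
highest_evidence_level_of <- function(levels) {
  levels <- levels[!is.na(levels) & levels %in% KB_EVIDENCE_LEVELS]
  if (length(levels) == 0L) return(NA_character_)
  KB_EVIDENCE_LEVELS[min(match(levels, KB_EVIDENCE_LEVELS))]
}

#' Highest evidence level among a sample's exact matches
#'
#' @param matched_variant_ids Integer vector of exact-matched variant ids.
#' @param coll A `kb_collection` (resolved).
#' @param allowed_statuses Statuses whose evidence counts.
#' @return Single level or `NA_character_` when there are no matches or no
#'   status-passing leveled evidence.
#' @export
highest_evidence_level <- function(matched_variant_ids, coll,
                                   allowed_statuses = kb_default_statuses()) {
  allowed_statuses <- chk_status_set(allowed_statuses)
  lv <- character(0)
  for (vid in unique(matched_variant_ids)) {
    v <- kb_get(coll, "variant", vid)
    if (is.null(v)) next
    for (e in v$evidence)
      if (!isTRUE(e$partial) && isTRUE(e$status %in% allowed_statuses) &&
          !is.na(e$evidence_level %na% NA))
        lv <- c(lv, e$evidence_level)
  }
  highest_evidence_level_of(lv)
}

#' Cohort-level match report
#'
#' Aggregates per-sample summaries into (a) match-class counts and
#' fractions over the whole cohort, (b) the highest-evidence-level
#' distribution among exact-matched samples, and (c) the distribution of
#' samples by number of exact-matched variants (0, 1, 2, 3, 4+).
#'
#' @param summaries Output of [classify_samples()] covering the cohort.
#' @return A `kb_cohort_report` list with elements `n_samples`, `classes`,
#'   `levels`, `exact_variant_distribution`.
#' @export
cohort_report <- function(summaries) {
  s <- as.data.table(summaries)
  n <- nrow(s)
  classes <- s[, .(n = .N), by = .(match_class)]
  classes <- merge(data.table(match_class = factor(MATCH_CLASSES,
                                                   levels = MATCH_CLASSES)),
                   classes, by = "match_class", all.x = TRUE)
  classes[is.na(n), n := 0L]
  classes[, fraction := n / max(nrow(s), 1L)]

  ex <- s[match_class == "exact"]
  # NA bucket: exact-matched samples with no status-passing leveled evidence
  levels <- data.table(highest_level = c(KB_EVIDENCE_LEVELS, NA_character_))
  lv <- ex[, .(n = .N), by = .(highest_level)]
  levels <- merge(levels, lv, by = "highest_level", all.x = TRUE, sort = FALSE)
  levels[is.na(n), n := 0L]
  levels[, fraction := n / max(nrow(ex), 1L)]

  bucket <- function(k) ifelse(k >= 4L, "4+", as.character(k))
  dist <- s[, .(n = .N), by = .(n_exact_variants = bucket(n_exact))]
  dist_all <- data.table(n_exact_variants = c("0", "1", "2", "3", "4+"))
  dist <- merge(dist_all, dist, by = "n_exact_variants", all.x = TRUE)
  dist[is.na(n), n := 0L]
  dist[, fraction := n / max(nrow(s), 1L)]

  structure(list(n_samples = n, classes = classes[], levels = levels[],
                 exact_variant_distribution = dist[]),
            class = "kb_cohort_report")
}

#' @export
print.kb_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d samples\n\nMatch classes:\n", x$n_samples))
  print(x$classes, row.names = FALSE)
  cat("\nHighest evidence level among exact-matched samples:\n")
  print(x$levels, row.names = FALSE)
  cat("\nSamples by number of exact-matched variants:\n")
  print(x$exact_variant_distribution, row.names = FALSE)
  invisible(x)
}

#' Run the full cohort pipeline
#'
#' Convenience driver: read a MAF-like table, build tagged queries, run
#' exact and any-overlap bulk searches against an index, classify samples
#' and aggregate the report.
#'
#' @param maf_path Path to the cohort TSV.
#' @param index A `kb_vci`.
#' @param cache `kb_cache`/`kb_collection` for evidence-level lookup.
#' @param all_samples Optional full barcode list (defaults to barcodes seen
#'   in the table; pass explicitly to include samples with no variants).
#' @param allowed_statuses Statuses counted for the level summary.
#' @return List with `summaries` (per sample) and `report`.
#' @export
run_cohort_analysis <- function(maf_path, index, cache = NULL,
                                all_samples = NULL,
                                allowed_statuses = kb_default_statuses()) {
  tab <- read_cohort_table(maf_path)
  if (is.null(all_samples)) all_samples <- unique(tab$sample_barcode)
  q <- queries_from_cohort(tab, build = attr(index, "reference_build") %na% "GRCh37")
  ex <- bulk_search(index, q, "exact")
  an <- bulk_search(index, q, "any")
  summaries <- classify_samples(ex, an, all_samples, cache = cache,
                                allowed_statuses = allowed_statuses)
  list(summaries = summaries, report = cohort_report(summaries),
       queries = q, exact = ex, any = an)
}
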