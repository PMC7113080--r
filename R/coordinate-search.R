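MATCH_MODES <- c("exact", "query_encompassing", "record_encompassing", "any")

#' Match modes
#'
#' Four search models over 1-based closed genomic intervals, from most
#' conservative to most sensitive:
#' \describe{
#'   \item{exact}{identical start and stop, and a compatible alternate
#'     allele (a missing or `"*"` query allele acts as a wildcard);}
#'   \item{query_encompassing}{the index record lies entirely inside the
#'     query interval;}
#'   \item{record_encompassing}{the query lies entirely inside the index
#'     record;}
#'   \item{any}{the intervals overlap by at least one base.}
#' }
#' The range modes are defined purely on coordinates; only `exact` consults
#' the alternate allele. `qe` and `re` are accepted as abbreviations.
#'
#' @param mode Mode name or abbreviation.
#' @return Canonical mode name.
#' @export
match_mode <- function(mode) {
  mode <- switch(tolower(mode), qe = "query_encompassing",
                 re = "record_encompassing", tolower(mode))
  if (!mode %in% MATCH_MODES)
    stop("unknown match mode '", mode, "'; expected one of ",
         paste(MATCH_MODES, collapse = ", "), call. = FALSE)
  mode
}

## ---- the variant coordinate index ------------------------------------------

vci_sort_order <- function(dt) {
  order(chromosome_rank(dt$chromosome), dt$start, dt$stop,
        dt$alt, dt$variant_id, method = "radix", na.last = FALSE)
}

#' Build the sorted variant coordinate index
#'
#' Extracts one row per usable coordinate set from every variant: simple
#' variants contribute one entry, compound variants (two coordinate sets,
#' e.g. fusions) contribute two entries sharing one variant reference, and
#' variants missing chromosome/start/stop contribute none (they are counted
#' in the build report). Rows are sorted by chromosome (natural order
#' 1-22, X, Y, MT), start, stop, then alternate sequence; ties break on the
#' variant identifier so rebuilds are deterministic.
#'
#' @param x A `kb_collection`, `kb_cache`, or list of variant records.
#' @param reference_build Build label stamped onto the index; queries must
#'   carry the same label.
#' @return A `kb_vci`: a `data.table` with columns `chromosome`, `start`,
#'   `stop`, `alt`, `variant_id`, `variant_key`, carrying attributes
#'   `reference_build` and `build_report` (counts of indexed / excluded
#'   variants).
#' @export
build_index <- function(x, reference_build = "GRCh37") {
  variants <-
    if (inherits(x, "kb_cache")) kb_all(x$records, "variant")
    else if (inherits(x, "kb_collection")) kb_all(x, "variant")
    else x
  rows <- vector("list", 2L * length(variants))
  nr <- 0L
  n_excluded <- 0L
  for (v in variants) {
    co <- v$coordinates
    if (is.null(co) || !has_primary_coords(co)) {
      n_excluded <- n_excluded + 1L
      next
    }
    nr <- nr + 1L
    rows[[nr]] <- list(chromosome = co$chromosome, start = co$start,
                       stop = co$stop, alt = co$variant_bases,
                       variant_id = v$record_id)
    if (has_second_coords(co)) {
      nr <- nr + 1L
      rows[[nr]] <- list(chromosome = co$chromosome2, start = co$start2,
                         stop = co$stop2, alt = NA_character_,
                         variant_id = v$record_id)
    }
  }
  dt <- if (nr == 0L)
    data.table(chromosome = character(0), start = integer(0),
               stop = integer(0), alt = character(0), variant_id = integer(0))
  else rbindlist(rows[seq_len(nr)])
  dt[, alt := as.character(alt)]
  dt <- dt[vci_sort_order(dt)]
  dt[, variant_key := vapply(variant_id, function(i) record_key("variant", i),
                             character(1))]
  setattr(dt, "reference_build", reference_build)
  setattr(dt, "build_report",
          list(n_variants = length(variants),
               n_indexed = length(variants) - n_excluded,
               n_excluded = n_excluded, n_entries = nrow(dt)))
  setattr(dt, "class", c("kb_vci", class(dt)))
  dt[]
}

## ---- queries ---------------------------------------------------------------

#' Construct coordinate queries
#'
#' `coordinate_query()` builds a single query; `coordinate_queries()`
#' normalizes a data frame of queries (columns `chromosome`, `start`,
#' `stop`, optional `alt` and `key`). `key` is an arbitrary caller tag —
#' e.g. a tumor sample barcode — carried through to results untouched.
#'
#' @param chromosome Chromosome label (normalized on input).
#' @param start,stop 1-based inclusive interval, `start <= stop`.
#' @param alt Optional alternate allele; `NA` or `"*"` act as wildcards in
#'   exact mode.
#' @param key Optional user tag.
#' @param build Genome build label; must equal the index build at search
#'   time.
#' @return `coordinate_query()`: a one-row query table; `coordinate_queries()`:
#'   a `data.table` with one row per query.
#' @export
coordinate_query <- function(chromosome, start, stop = start, alt = NA,
                             key = NA, build = "GRCh37") {
  coordinate_queries(data.frame(chromosome = chromosome, start = start,
                                stop = stop, alt = alt, key = key,
                                stringsAsFactors = FALSE), build = build)
}

#' @rdname coordinate_query
#' @param df Data frame of query coordinates.
#' @export
coordinate_queries <- function(df, build = "GRCh37") {
  dt <- as.data.table(df)
  need <- c("chromosome", "start", "stop")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("queries are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"alt" %in% names(dt)) dt[, alt := NA_character_]
  if (!"key" %in% names(dt)) dt[, key := NA_character_]
  norm_alt <- function(a) {
    a <- toupper(as.character(a))
    a[a %in% c("", "-", ".")] <- NA_character_   # absent-allele spellings
    a
  }
  dt <- dt[, .(chromosome = normalize_chromosome(chromosome),
               start = as.integer(start), stop = as.integer(stop),
               alt = norm_alt(alt), key = as.character(key))]
  bad <- which(!is.na(dt$start) & !is.na(dt$stop) & dt$start > dt$stop)
  if (length(bad))
    stop("query ", bad[1L], ": start > stop", call. = FALSE)
  setattr(dt, "reference_build", build)
  setattr(dt, "class", c("kb_queries", class(dt)))
  dt[]
}

## ---- the match predicate ---------------------------------------------------

# Vectorized mode predicate on parallel coordinate vectors; chromosome
# equality is the caller's concern. Closed-interval semantics throughout.
mode_predicate <- function(mode, qs, qe, qa, es, ee, ea) {
  switch(mode,
    any = qs <= ee & es <= qe,
    query_encompassing = es >= qs & ee <= qe,
    record_encompassing = qs >= es & qe <= ee,
    exact = es == qs & ee == qe &
      (is.na(qa) | qa == "*" | (!is.na(ea) & ea == qa))
  )
}

#' Does a query match an index entry?
#'
#' Pure predicate over one query/entry pair under a given mode. Different
#' chromosomes never match. See [match_mode()] for the four semantics.
#'
#' @param query One-row query (from [coordinate_query()]) or a list with
#'   `chromosome`, `start`, `stop`, `alt`.
#' @param entry One-row index entry or equivalent list.
#' @param mode Match mode.
#' @return Logical scalar.
#' @export
coordinates_match <- function(query, entry, mode) {
  mode <- match_mode(mode)
  if (!identical(normalize_chromosome(query$chromosome),
                 normalize_chromosome(entry$chromosome))) return(FALSE)
  qa <- if (is.null(query$alt)) NA_character_ else as.character(query$alt)
  ea <- if (is.null(entry$alt)) NA_character_ else as.character(entry$alt)
  isTRUE(mode_predicate(mode, query$start, query$stop, qa,
                        entry$start, entry$stop, ea))
}

## ---- bulk search -----------------------------------------------------------

#' Bulk coordinate search over the index
#'
#' Answers every query with its set of matched variant identifiers using a
#' two-pointer merge over the start-sorted index: both lists are sorted by
#' the index ordering; per chromosome, a permanent index pointer advances
#' past entries whose stop lies strictly before the current query start
#' (such entries can never match a later query, since queries are visited
#' in non-decreasing start order), and the candidate window then extends to
#' the last entry whose start does not exceed the query stop. The mode
#' predicate is evaluated only inside that window, and the pointer is
#' restored for the next query. Total predicate work is
#' O(|index| + |queries| + scanned overlap pairs).
#'
#' Unsorted query input is accepted: queries are sorted internally and the
#' result mapping is returned in the original input order. A variant whose
#' two compound entries both match a query is reported once.
#'
#' @param index A `kb_vci` from [build_index()].
#' @param queries A `kb_queries` table, a data frame, or a single query.
#' @param mode Match mode (see [match_mode()]).
#' @return A `kb_search_result`: a list, one element per input query (in
#'   input order), each an integer vector of matched variant ids, with
#'   attributes `mode`, `keys` (the query tags) and `comparisons` (the
#'   instrumented count of pointer advances plus predicate evaluations).
#' @export
bulk_search <- function(index, queries, mode = "exact") {
  mode <- match_mode(mode)
  stopifnot(inherits(index, "data.table"))
  if (!inherits(queries, "kb_queries")) queries <- coordinate_queries(queries)
  ib <- attr(index, "reference_build")
  qb <- attr(queries, "reference_build")
  if (!is.null(ib) && !is.null(qb) && !identical(ib, qb))
    stop("genome build mismatch: index is ", ib, ", queries are ", qb,
         call. = FALSE)

  m <- nrow(queries)
  out <- rep(list(integer(0)), m)
  comparisons <- 0L

  if (m > 0L && nrow(index) > 0L) {
    qord <- order(chromosome_rank(queries$chromosome), queries$start,
                  queries$stop, queries$alt, method = "radix",
                  na.last = FALSE)
    e_chr <- index$chromosome
    for (chr in unique(queries$chromosome[qord])) {
      qi <- qord[queries$chromosome[qord] == chr]
      ei <- which(e_chr == chr)
      if (length(ei) == 0L) next
      es <- index$start[ei]; ee <- index$stop[ei]
      ea <- index$alt[ei]; ev <- index$variant_id[ei]
      n <- length(ei)
      lo <- 1L
      for (q in qi) {
        qs <- queries$start[q]; qe <- queries$stop[q]
        qa <- queries$alt[q]
        # permanent advance: drop entries that end before this query starts
        while (lo <= n && ee[lo] < qs) {
          lo <- lo + 1L
          comparisons <- comparisons + 1L
        }
        comparisons <- comparisons + 1L   # the failing advance check
        if (lo > n) next
        # candidate window: entries starting at or before the query stop
        hi <- findInterval(qe, es)
        if (hi < lo) next
        idx <- lo:hi
        comparisons <- comparisons + length(idx)
        hitrows <- idx[mode_predicate(mode, qs, qe, qa,
                                      es[idx], ee[idx], ea[idx])]
        if (length(hitrows))
          out[[q]] <- sort(unique(ev[hitrows]))
      }
    }
  }
  structure(out, mode = mode, keys = queries$key,
            comparisons = comparisons, class = "kb_search_result")
}

#' @export
print.kb_search_result <- function(x, ...) {
  nhit <- sum(vapply(x, length, integer(1)) > 0)
  cat(sprintf("<kb_search_result: %d queries, %d with matches, mode=%s>\n",
              length(x), nhit, attr(x, "mode")))
  invisible(x)
}

#' Search a single coordinate query
#'
#' Convenience wrapper: identical to [bulk_search()] on a one-element query
#' list.
#'
#' @inheritParams bulk_search
#' @param query A single query (one-row table or list).
#' @return Integer vector of matched variant ids.
#' @export
search_single <- function(index, query, mode = "exact") {
  if (!inherits(query, "kb_queries")) {
    if (!is.data.frame(query)) {
      keep <- intersect(c("chromosome", "start", "stop", "alt", "key"),
                        names(query))
      query <- as.data.frame(query[keep], stringsAsFactors = FALSE)
    }
    query <- coordinate_queries(query)
  }
  bulk_search(index, query, mode)[[1L]]
}

#' Flatten a search result to a table
#'
#' @param result A `kb_search_result`.
#' @return `data.table` with columns `query_index`, `key`, `variant_id`,
#'   `match_mode`; zero rows for queries without matches.
#' @export
search_result_table <- function(result) {
  keys <- attr(result, "keys")
  mode <- attr(result, "mode")
  rows <- lapply(seq_along(result), function(i) {
    v <- result[[i]]
    if (length(v) == 0L) return(NULL)
    # note: `key` is a reserved data.table() argument, hence setnames()
    dt <- data.table(query_index = i, .key = keys[i], variant_id = v,
                     match_mode = mode)
    data.table::setnames(dt, ".key", "key")
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    out <- data.table(query_index = integer(0), .key = character(0),
                      variant_id = integer(0), match_mode = character(0))
    return(data.table::setnames(out, ".key", "key"))
  }
  rbindlist(rows)
}
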