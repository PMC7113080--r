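#' @importFrom data.table data.table rbindlist setorder setattr := .N .SD setDT as.data.table fread fwrite
#' @importFrom stats rpois setNames
#' @importFrom utils head tail write.table read.delim
NULL

# Entity types that carry a persistent public identifier and can be cached.
KB_RECORD_TYPES <- c("gene", "variant", "variant_group", "evidence",
                     "assertion", "source", "user", "organization")

KB_STATUSES <- c("accepted", "submitted", "rejected")
KB_EVIDENCE_LEVELS <- c("A", "B", "C", "D", "E")

#' Review statuses and evidence levels
#'
#' `kb_statuses()` returns the closed set of review lifecycle states
#' (`accepted`, `submitted`, `rejected`); `kb_levels()` returns the evidence
#' level grades in decreasing strength order: A (validated), B (clinical),
#' C (case study), D (preclinical), E (inferential).
#'
#' @return Character vector.
#' @export
kb_statuses <- function() KB_STATUSES

#' @rdname kb_statuses
#' @export
kb_levels <- function() KB_EVIDENCE_LEVELS

kb_default_statuses <- function() c("accepted", "submitted")

chk_status_set <- function(allowed) {
  if (length(allowed) == 0L)
    stop("`allowed` must be a non-empty subset of ",
         paste(KB_STATUSES, collapse = "/"), call. = FALSE)
  bad <- setdiff(allowed, KB_STATUSES)
  if (length(bad))
    stop("unknown review status(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unique(allowed)
}

## ---- record construction ---------------------------------------------------
## Records are environments so that resolved links are shared object
## instances: two evidence items citing one source hold the *same* source,
## and mutation-free traversal never copies.

rec_key_string <- function(record_type, record_id) {
  paste0(record_type, ":", record_id)
}

new_record <- function(record_type, record_id, fields = list()) {
  stopifnot(record_type %in% KB_RECORD_TYPES)
  record_id <- as.integer(record_id)
  if (is.na(record_id) || record_id < 1L)
    stop("record_id must be a positive integer", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$record_type <- record_type
  e$record_id <- record_id
  e$partial <- FALSE
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("kb_", record_type), "kb_record")
  e
}

#' Construct a partial record
#'
#' A partial record carries only its `(record_type, record_id)` identity. It
#' stands in for records referenced by a snapshot but absent from it
#' (dangling links), and is treated as equivalent to the full record for
#' cache-key purposes.
#'
#' @param record_type One of the entity type names (see [kb_statuses()] for
#'   the status enumeration; types are gene, variant, variant_group,
#'   evidence, assertion, source, user, organization).
#' @param record_id Positive integer public identifier.
#' @return A `kb_record` environment with `partial = TRUE`.
#' @export
partial_record <- function(record_type, record_id) {
  e <- new_record(record_type, record_id)
  e$partial <- TRUE
  e
}

#' @export
print.kb_record <- function(x, ...) {
  cat(sprintf("<%s %d%s>\n", x$record_type, x$record_id,
              if (isTRUE(x$partial)) " (partial)" else ""))
  invisible(x)
}

#' @export
format.kb_record <- function(x, ...) {
  sprintf("<%s %d%s>", x$record_type, x$record_id,
          if (isTRUE(x$partial)) " (partial)" else "")
}

## ---- coordinates -----------------------------------------------------------

CHROM_CANONICAL <- c(as.character(1:22), "X", "Y", "MT")

#' Normalize a chromosome name
#'
#' Strips a leading "chr" prefix, maps "M" to "MT", and upper-cases the
#' sex/mito names. Unknown labels are returned stripped but otherwise
#' untouched (they sort after the canonical set).
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chromosome <- function(chrom) {
  chrom <- as.character(chrom)
  chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
  up <- toupper(chrom)
  chrom[up == "M"] <- "MT"
  chrom[up %in% c("X", "Y", "MT")] <- up[up %in% c("X", "Y", "MT")]
  chrom
}

#' Chromosome sort rank
#'
#' Natural order 1-22, X, Y, MT; any other label sorts after those,
#' lexicographically. Used everywhere an index or output is sorted "by
#' chromosome".
#'
#' @param chrom Character vector of normalized chromosome names.
#' @return Numeric rank vector (smaller sorts first).
#' @export
chromosome_rank <- function(chrom) {
  r <- match(chrom, CHROM_CANONICAL)
  oth <- is.na(r)
  if (any(oth)) {
    extra <- sort(unique(chrom[oth]))
    r[oth] <- length(CHROM_CANONICAL) + match(chrom[oth], extra)
  }
  r
}

valid_bases <- function(x) {
  is.null(x) || is.na(x) || grepl("^[ACGTN]*$", x)
}

#' Build a coordinates object
#'
#' 1-based, fully-closed intervals on GRCh37. A second coordinate set
#' (`chromosome2`/`start2`/`stop2`) marks a compound variant such as a
#' fusion.
#'
#' @param chromosome,start,stop Primary interval (1-based inclusive).
#' @param reference_bases,variant_bases Optional upper-case allele strings
#'   (A/C/G/T/N only).
#' @param chromosome2,start2,stop2 Optional second interval for compound
#'   variants.
#' @param representative_transcript Optional transcript label.
#' @param reference_build Genome build label; only "GRCh37" is supported.
#' @return A list of class `kb_coordinates`.
#' @export
coordinates <- function(chromosome = NA, start = NA, stop = NA,
                        reference_bases = NA, variant_bases = NA,
                        chromosome2 = NA, start2 = NA, stop2 = NA,
                        representative_transcript = NA,
                        reference_build = "GRCh37") {
  as1 <- function(x) if (is.null(x) || length(x) == 0L) NA else x[[1L]]
  chromosome <- as1(chromosome); start <- as1(start); stop <- as1(stop)
  reference_bases <- as1(reference_bases); variant_bases <- as1(variant_bases)
  chromosome2 <- as1(chromosome2); start2 <- as1(start2); stop2 <- as1(stop2)
  if (!is.na(chromosome)) chromosome <- normalize_chromosome(chromosome)
  if (!is.na(chromosome2)) chromosome2 <- normalize_chromosome(chromosome2)
  start <- if (is.na(start)) NA_integer_ else as.integer(start)
  stop <- if (is.na(stop)) NA_integer_ else as.integer(stop)
  start2 <- if (is.na(start2)) NA_integer_ else as.integer(start2)
  stop2 <- if (is.na(stop2)) NA_integer_ else as.integer(stop2)
  if (!is.na(start) && !is.na(stop) && start > stop)
    stop("coordinates: start > stop", call. = FALSE)
  if (!is.na(chromosome2) && (is.na(start2) || is.na(stop2)))
    stop("coordinates: second coordinate set requires start2 and stop2",
         call. = FALSE)
  if (!is.na(start2) && !is.na(stop2) && start2 > stop2)
    stop("coordinates: start2 > stop2", call. = FALSE)
  for (b in list(reference_bases, variant_bases))
    if (!valid_bases(b))
      stop("coordinates: base strings may contain only A,C,G,T,N",
           call. = FALSE)
  structure(list(
    reference_build = reference_build,
    chromosome = chromosome, start = start, stop = stop,
    reference_bases = if (is.na(reference_bases)) NA_character_ else toupper(reference_bases),
    variant_bases = if (is.na(variant_bases)) NA_character_ else toupper(variant_bases),
    chromosome2 = chromosome2, start2 = start2, stop2 = stop2,
    representative_transcript = if (is.na(representative_transcript)) NA_character_ else representative_transcript
  ), class = "kb_coordinates")
}

has_primary_coords <- function(co) {
  !is.na(co$chromosome) && !is.na(co$start) && !is.na(co$stop)
}

has_second_coords <- function(co) !is.na(co$chromosome2)

## ---- snapshot parsing ------------------------------------------------------

SNAPSHOT_FORMAT <- "kb-snapshot"
SNAPSHOT_VERSION <- 1L

snap_entity_keys <- c(gene = "genes", variant = "variants",
                      variant_group = "variant_groups",
                      evidence = "evidence", assertion = "assertions",
                      source = "sources", user = "users",
                      organization = "organizations")

sfield <- function(x, nm, default = NA) {
  v <- x[[nm]]
  if (is.null(v) || length(v) == 0L) default else v
}

schr <- function(x, nm) {
  v <- sfield(x, nm, NA_character_)
  if (length(v) > 1L) v <- v[[1L]]
  if (is.na(v)) NA_character_ else as.character(v)
}

sint <- function(x, nm) {
  v <- sfield(x, nm, NA_integer_)
  if (is.na(v)) NA_integer_ else as.integer(v)
}

slist <- function(x, nm) {
  v <- x[[nm]]
  if (is.null(v)) list() else v
}

schrvec <- function(x, nm) {
  v <- x[[nm]]
  if (is.null(v) || length(v) == 0L) character(0) else unlist(v, use.names = FALSE)
}

sints <- function(x, nm) {
  v <- x[[nm]]
  if (is.null(v) || length(v) == 0L) integer(0) else as.integer(unlist(v, use.names = FALSE))
}

parse_coordinates <- function(co) {
  if (is.null(co)) return(coordinates())
  coordinates(chromosome = sfield(co, "chromosome"),
              start = sfield(co, "start"), stop = sfield(co, "stop"),
              reference_bases = sfield(co, "reference_bases"),
              variant_bases = sfield(co, "variant_bases"),
              chromosome2 = sfield(co, "chromosome2"),
              start2 = sfield(co, "start2"), stop2 = sfield(co, "stop2"),
              representative_transcript = sfield(co, "representative_transcript"),
              reference_build = schr(co, "reference_build") %na% "GRCh37")
}

`%na%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

open_snapshot_connection <- function(path) {
  if (inherits(path, "connection")) return(path)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b))))
    gzfile(path, "rb") else file(path, "rb")
}

#' Parse a knowledgebase snapshot file
#'
#' Reads one JSON document holding a top-level array per entity type
#' (`genes`, `variants`, `evidence`, `assertions`, `sources`, optionally
#' `variant_groups`, `users`, `organizations`) and returns a record
#' collection. Link fields hold raw identifiers until [resolve_links()] is
#' called. Plain and gzip-compressed files are accepted.
#'
#' @param path File path (plain or `.gz`) or a connection.
#' @return A `kb_collection`: an environment with a key-addressed record
#'   table, per-type id lists, and a `dangling` link table (populated by
#'   [resolve_links()]).
#' @export
parse_snapshot <- function(path) {
  con <- open_snapshot_connection(path)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  txt <- paste(readLines(con, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  doc <- tryCatch(
    jsonlite::parse_json(txt),
    error = function(e) stop("snapshot parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.list(doc))
    stop("snapshot parse error: top level is not a JSON object", call. = FALSE)
  known <- c("format", "version", "reference_build", unname(snap_entity_keys))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("snapshot schema error: unknown record type section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  coll <- new.env(parent = emptyenv())
  coll$records <- new.env(parent = emptyenv())   # "type:id" -> record env
  coll$ids <- lapply(setNames(nm = KB_RECORD_TYPES), function(t) integer(0))
  coll$dangling <- data.table(record_type = character(0),
                              record_id = integer(0),
                              referenced_by = character(0))
  coll$resolved <- FALSE
  class(coll) <- "kb_collection"

  add <- function(rec) {
    k <- rec_key_string(rec$record_type, rec$record_id)
    if (!is.null(coll$records[[k]]))
      stop("snapshot schema error: duplicate record ", k, call. = FALSE)
    coll$records[[k]] <- rec
    coll$ids[[rec$record_type]] <- c(coll$ids[[rec$record_type]], rec$record_id)
  }

  for (g in slist(doc, "genes")) {
    add(new_record("gene", sint(g, "id"), list(
      name = schr(g, "name"), entrez_id = sint(g, "entrez_id"),
      description = schr(g, "description"),
      variant_ids = sints(g, "variant_ids"))))
  }
  for (v in slist(doc, "variants")) {
    add(new_record("variant", sint(v, "id"), list(
      gene_id = sint(v, "gene_id"), name = schr(v, "name"),
      aliases = schrvec(v, "aliases"),
      variant_types = schrvec(v, "variant_types"),
      coordinates = parse_coordinates(v$coordinates),
      evidence_ids = sints(v, "evidence_ids"),
      assertion_ids = sints(v, "assertion_ids"))))
  }
  for (vg in slist(doc, "variant_groups")) {
    add(new_record("variant_group", sint(vg, "id"), list(
      name = schr(vg, "name"), variant_ids = sints(vg, "variant_ids"))))
  }
  for (e in slist(doc, "evidence")) {
    st <- schr(e, "status")
    lv <- schr(e, "evidence_level")
    if (!is.na(st) && !st %in% KB_STATUSES)
      stop("snapshot schema error: evidence ", sint(e, "id"),
           " has unknown status '", st, "'", call. = FALSE)
    if (!is.na(lv) && !lv %in% KB_EVIDENCE_LEVELS)
      stop("snapshot schema error: evidence ", sint(e, "id"),
           " has unknown level '", lv, "'", call. = FALSE)
    add(new_record("evidence", sint(e, "id"), list(
      variant_id = sint(e, "variant_id"), status = st, evidence_level = lv,
      evidence_direction = schr(e, "evidence_direction"),
      clinical_significance = schr(e, "clinical_significance"),
      disease = attribute_blob("disease", slist(e, "disease")),
      drugs = lapply(slist(e, "drugs"), function(d) attribute_blob("drug", d)),
      source_id = sint(e, "source_id"), rating = sint(e, "rating"))))
  }
  for (a in slist(doc, "assertions")) {
    st <- schr(a, "status")
    if (!is.na(st) && !st %in% KB_STATUSES)
      stop("snapshot schema error: assertion ", sint(a, "id"),
           " has unknown status '", st, "'", call. = FALSE)
    add(new_record("assertion", sint(a, "id"), list(
      status = st, amp_category = schr(a, "amp_category"),
      variant_id = sint(a, "variant_id"),
      evidence_ids = sints(a, "evidence_ids"),
      disease = attribute_blob("disease", slist(a, "disease")),
      drugs = lapply(slist(a, "drugs"), function(d) attribute_blob("drug", d)))))
  }
  for (s in slist(doc, "sources")) {
    add(new_record("source", sint(s, "id"), list(
      citation = schr(s, "citation"), source_type = schr(s, "source_type"),
      citation_id = schr(s, "citation_id"))))
  }
  for (u in slist(doc, "users")) {
    add(new_record("user", sint(u, "id"), list(name = schr(u, "name"))))
  }
  for (o in slist(doc, "organizations")) {
    add(new_record("organization", sint(o, "id"), list(name = schr(o, "name"))))
  }
  coll
}

#' Attribute blob
#'
#' Composite payloads (diseases, drugs, ...) that carry no public identifier
#' of their own: never cached standalone, never independently addressable.
#'
#' @param name Attribute kind, e.g. "disease" or "drug".
#' @param payload Nested key/value content (list).
#' @return A list of class `kb_attribute`.
#' @export
attribute_blob <- function(name, payload = list()) {
  structure(list(name = name, payload = payload), class = "kb_attribute")
}

#' @export
print.kb_collection <- function(x, ...) {
  n <- vapply(x$ids, length, integer(1))
  cat("<kb_collection: ",
      paste(sprintf("%d %s", n[n > 0], names(n)[n > 0]), collapse = ", "),
      if (all(n == 0)) "empty", ">\n", sep = "")
  invisible(x)
}

#' Number of records in a collection
#' @param x A `kb_collection`.
#' @param type Optional entity type to count.
#' @return Integer count.
#' @export
kb_count <- function(x, type = NULL) {
  if (is.null(type)) sum(vapply(x$ids, length, integer(1)))
  else length(x$ids[[type]])
}

#' Look up one record
#' @param coll A `kb_collection`.
#' @param record_type,record_id Identity of the record.
#' @return The record environment, or `NULL` if absent.
#' @export
kb_get <- function(coll, record_type, record_id) {
  coll$records[[rec_key_string(record_type, record_id)]]
}

#' All records of one type
#' @param coll A `kb_collection`.
#' @param type Entity type name.
#' @return List of records, ascending id.
#' @export
kb_all <- function(coll, type) {
  ids <- sort(coll$ids[[type]])
  lapply(ids, function(i) kb_get(coll, type, i))
}

## ---- link resolution -------------------------------------------------------

resolve_one <- function(coll, record_type, record_id, referenced_by) {
  if (is.na(record_id)) return(NULL)
  rec <- kb_get(coll, record_type, record_id)
  if (!is.null(rec)) return(rec)
  # dangling: materialize (and register) a shared partial record
  k <- rec_key_string(record_type, record_id)
  p <- coll$partials[[k]]
  if (is.null(p)) {
    p <- partial_record(record_type, record_id)
    coll$partials[[k]] <- p
  }
  coll$dangling <- rbind(coll$dangling,
                         data.table(record_type = record_type,
                                    record_id = as.integer(record_id),
                                    referenced_by = referenced_by))
  p
}

#' Materialize links between records
#'
#' Replaces raw identifier link fields with the linked record objects
#' themselves, so that chains such as variant -> evidence -> source can be
#' traversed with `$`. Links that point at records absent from the snapshot
#' resolve to shared partial records (never an error); each such dangling
#' link is logged in `coll$dangling`.
#'
#' @param coll A `kb_collection` from [parse_snapshot()].
#' @return The same collection, modified in place and returned invisibly.
#' @export
resolve_links <- function(coll) {
  if (isTRUE(coll$resolved)) return(invisible(coll))
  coll$partials <- new.env(parent = emptyenv())

  for (v in kb_all(coll, "variant")) {
    me <- rec_key_string("variant", v$record_id)
    v$gene <- resolve_one(coll, "gene", v$gene_id, me)
    v$evidence <- Filter(Negate(is.null), lapply(
      v$evidence_ids, function(i) resolve_one(coll, "evidence", i, me)))
    v$assertions <- Filter(Negate(is.null), lapply(
      v$assertion_ids, function(i) resolve_one(coll, "assertion", i, me)))
  }
  for (g in kb_all(coll, "gene")) {
    me <- rec_key_string("gene", g$record_id)
    g$variants <- Filter(Negate(is.null), lapply(
      g$variant_ids, function(i) resolve_one(coll, "variant", i, me)))
  }
  for (e in kb_all(coll, "evidence")) {
    me <- rec_key_string("evidence", e$record_id)
    e$variant <- resolve_one(coll, "variant", e$variant_id, me)
    e$source <- resolve_one(coll, "source", e$source_id, me)
  }
  for (a in kb_all(coll, "assertion")) {
    me <- rec_key_string("assertion", a$record_id)
    a$variant <- resolve_one(coll, "variant", a$variant_id, me)
    a$evidence <- Filter(Negate(is.null), lapply(
      a$evidence_ids, function(i) resolve_one(coll, "evidence", i, me)))
  }
  for (vg in kb_all(coll, "variant_group")) {
    me <- rec_key_string("variant_group", vg$record_id)
    vg$variants <- Filter(Negate(is.null), lapply(
      vg$variant_ids, function(i) resolve_one(coll, "variant", i, me)))
  }
  # Cross-check: every evidence linked under a variant must cite it back.
  for (v in kb_all(coll, "variant")) {
    for (e in v$evidence) {
      if (!isTRUE(e$partial) && !identical(e$variant_id, v$record_id))
        stop("inconsistent snapshot: evidence ", e$record_id,
             " linked under variant ", v$record_id,
             " but cites variant ", e$variant_id, call. = FALSE)
    }
  }
  coll$resolved <- TRUE
  invisible(coll)
}

## ---- status filtering ------------------------------------------------------

#' Restrict a collection to evidence/assertions of given statuses
#'
#' Genes and variants are always retained; their evidence and assertion
#' link lists become filtered views. Evidence and assertion records whose
#' status falls outside `allowed` are absent from the returned collection.
#' The input collection is not modified. Most downstream work wants only
#' accepted and/or submitted material, which is the default.
#'
#' @param coll A resolved `kb_collection`.
#' @param allowed Non-empty subset of `kb_statuses()`.
#' @return A new `kb_collection` sharing evidence/assertion/source objects
#'   with the input; variant and gene containers are fresh filtered shells.
#' @export
filter_by_status <- function(coll, allowed = kb_default_statuses()) {
  allowed <- chk_status_set(allowed)
  resolve_links(coll)

  out <- new.env(parent = emptyenv())
  out$records <- new.env(parent = emptyenv())
  out$ids <- lapply(setNames(nm = KB_RECORD_TYPES), function(t) integer(0))
  out$dangling <- coll$dangling
  out$partials <- coll$partials
  out$resolved <- TRUE
  class(out) <- "kb_collection"

  keep_ev <- function(e) !isTRUE(e$partial) && isTRUE(e$status %in% allowed)
  keep_as <- keep_ev

  put <- function(rec) {
    k <- rec_key_string(rec$record_type, rec$record_id)
    if (is.null(out$records[[k]])) {
      out$records[[k]] <- rec
      out$ids[[rec$record_type]] <- c(out$ids[[rec$record_type]], rec$record_id)
    }
  }

  for (e in kb_all(coll, "evidence")) if (keep_ev(e)) put(e)
  for (a in kb_all(coll, "assertion")) if (keep_as(a)) put(a)
  for (s in kb_all(coll, "source")) put(s)
  for (u in kb_all(coll, "user")) put(u)
  for (o in kb_all(coll, "organization")) put(o)

  # Variants become shallow filtered shells so the input stays untouched.
  for (v in kb_all(coll, "variant")) {
    nv <- new_record("variant", v$record_id, list(
      gene_id = v$gene_id, name = v$name, aliases = v$aliases,
      variant_types = v$variant_types, coordinates = v$coordinates,
      gene = v$gene,
      evidence = Filter(keep_ev, v$evidence),
      assertions = Filter(keep_as, v$assertions)))
    nv$evidence_ids <- vapply(nv$evidence, function(e) e$record_id, integer(1))
    nv$assertion_ids <- vapply(nv$assertions, function(a) a$record_id, integer(1))
    put(nv)
  }
  for (g in kb_all(coll, "gene")) {
    ng <- new_record("gene", g$record_id, list(
      name = g$name, entrez_id = g$entrez_id, description = g$description,
      variant_ids = g$variant_ids,
      variants = lapply(g$variant_ids, function(i) kb_get(out, "variant", i))))
    put(ng)
  }
  for (vg in kb_all(coll, "variant_group")) put(vg)
  out
}

## ---- serialization (round-trip support) ------------------------------------

coords_to_list <- function(co) {
  keep <- !vapply(co, function(x) length(x) == 1L && is.na(x), logical(1))
  co[keep]
}

#' Serialize a collection back to the snapshot JSON dialect
#'
#' Inverse of [parse_snapshot()]: `parse_snapshot(serialize_snapshot(x))`
#' reproduces `x` field by field.
#'
#' @param coll A `kb_collection`.
#' @param path Output file path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
serialize_snapshot <- function(coll, path = NULL) {
  drop_na <- function(x) {
    x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
  }
  blob_payload <- function(b) if (is.null(b)) NULL else b$payload
  doc <- list(
    format = SNAPSHOT_FORMAT, version = SNAPSHOT_VERSION,
    reference_build = "GRCh37",
    genes = lapply(kb_all(coll, "gene"), function(g) drop_na(list(
      id = g$record_id, name = g$name, entrez_id = g$entrez_id,
      description = g$description,
      variant_ids = as.list(g$variant_ids)))),
    variants = lapply(kb_all(coll, "variant"), function(v) drop_na(list(
      id = v$record_id, gene_id = v$gene_id, name = v$name,
      aliases = as.list(v$aliases),
      variant_types = as.list(v$variant_types),
      coordinates = coords_to_list(v$coordinates),
      evidence_ids = as.list(v$evidence_ids),
      assertion_ids = as.list(v$assertion_ids)))),
    variant_groups = lapply(kb_all(coll, "variant_group"), function(vg) drop_na(list(
      id = vg$record_id, name = vg$name,
      variant_ids = as.list(vg$variant_ids)))),
    evidence = lapply(kb_all(coll, "evidence"), function(e) drop_na(list(
      id = e$record_id, variant_id = e$variant_id, status = e$status,
      evidence_level = e$evidence_level,
      evidence_direction = e$evidence_direction,
      clinical_significance = e$clinical_significance,
      disease = blob_payload(e$disease),
      drugs = lapply(e$drugs, blob_payload),
      source_id = e$source_id, rating = e$rating))),
    assertions = lapply(kb_all(coll, "assertion"), function(a) drop_na(list(
      id = a$record_id, status = a$status, amp_category = a$amp_category,
      variant_id = a$variant_id, evidence_ids = as.list(a$evidence_ids),
      disease = blob_payload(a$disease),
      drugs = lapply(a$drugs, blob_payload)))),
    sources = lapply(kb_all(coll, "source"), function(s) drop_na(list(
      id = s$record_id, citation = s$citation, source_type = s$source_type,
      citation_id = s$citation_id))),
    users = lapply(kb_all(coll, "user"), function(u) drop_na(list(
      id = u$record_id, name = u$name))),
    organizations = lapply(kb_all(coll, "organization"), function(o) drop_na(list(
      id = o$record_id, name = o$name)))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}
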