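# CSQ annotation schema. One pipe-delimited entry per clinical statement
# (evidence item or assertion); KB_Entity_Type discriminates the two.
# Multi-valued fields join their elements with "&" after escaping.
CSQ_FIELDS <- c(
  "Allele", "Gene", "Variant_Name", "Variant_ID", "Variant_Aliases",
  "Variant_Types", "KB_Entity_Type", "KB_Entity_ID", "KB_Entity_Status",
  "Evidence_Level", "Evidence_Direction", "Clinical_Significance",
  "Evidence_Rating", "Disease", "Drugs", "Source", "AMP_Category")

#' CSQ field names
#'
#' The ordered annotation fields declared in the VCF `CSQ` INFO header.
#' @return Character vector of field names.
#' @export
csq_fields <- function() CSQ_FIELDS

## ---- value escaping --------------------------------------------------------

CSQ_SAFE_CLASS <- "A-Za-z0-9.:/-"   # besides these, everything is escaped

#' Escape / unescape a CSQ field value
#'
#' Reversible encoding that keeps values free of the VCF-reserved
#' characters (whitespace, `;`, `,`, `=`, `|`): spaces become underscores
#' and every other character outside `[A-Za-z0-9_.:/-]` — including literal
#' underscores, so the mapping stays invertible — is percent-encoded as
#' uppercase `%XX` over its UTF-8 bytes. `decode_csq_value()` is the exact
#' inverse: `decode_csq_value(encode_csq_value(s))` is `s` for any string.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
encode_csq_value <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    b <- as.integer(charToRaw(enc2utf8(s)))   # escape UTF-8 byte-wise
    enc <- sprintf("%%%02X", b)
    safe <- (b >= 48L & b <= 57L) | (b >= 65L & b <= 90L) |
      (b >= 97L & b <= 122L) | b %in% c(45L, 46L, 47L, 58L)  # [0-9A-Za-z.:/-]
    if (any(safe))
      enc[safe] <- rawToChar(as.raw(b[safe]), multiple = TRUE)
    enc[b == 32L] <- "_"
    paste(enc, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname encode_csq_value
#' @export
decode_csq_value <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return("")
    s <- gsub("_", " ", s, fixed = TRUE)
    if (!grepl("%", s, fixed = TRUE)) return(s)
    parts <- strsplit(s, "%", fixed = TRUE)[[1L]]
    bytes <- charToRaw(parts[1L])
    for (p in parts[-1L]) {
      bytes <- c(bytes, as.raw(strtoi(substr(p, 1L, 2L), 16L)),
                 charToRaw(substring(p, 3L)))
    }
    out <- rawToChar(bytes)
    Encoding(out) <- "UTF-8"
    out
  }, character(1), USE.NAMES = FALSE)
}

## ---- validity --------------------------------------------------------------

#' Can a variant be written to VCF?
#'
#' A variant is exportable when its chromosome and start position are
#' curated and its allele information fits one of three shapes: reference
#' and variant bases both present (SNVs and complex variants), variant
#' bases only (insertions), or reference bases only (deletions). Variants
#' carrying a second coordinate set (fusions) are not supported.
#'
#' @param variant A variant record.
#' @return Logical scalar with attribute `reason` (one of `ok`,
#'   `missing_position`, `missing_alleles`, `second_coordinate_set`).
#' @export
is_valid_for_vcf <- function(variant) {
  co <- variant$coordinates
  res <- function(ok, reason) structure(ok, reason = reason)
  if (is.null(co) || is.na(co$chromosome) || is.na(co$start))
    return(res(FALSE, "missing_position"))
  if (has_second_coords(co))
    return(res(FALSE, "second_coordinate_set"))
  has_ref <- !is.na(co$reference_bases) && nzchar(co$reference_bases)
  has_alt <- !is.na(co$variant_bases) && nzchar(co$variant_bases)
  if (!has_ref && !has_alt)
    return(res(FALSE, "missing_alleles"))
  res(TRUE, "ok")
}

# REF/ALT/POS under the documented no-reference-FASTA dialect:
# both alleles -> verbatim at start; insertion -> REF "N", ALT "N"+alt at
# start; deletion -> REF "N"+ref at start-1, ALT "N".
vcf_alleles <- function(co) {
  has_ref <- !is.na(co$reference_bases) && nzchar(co$reference_bases)
  has_alt <- !is.na(co$variant_bases) && nzchar(co$variant_bases)
  if (has_ref && has_alt)
    list(pos = co$start, ref = co$reference_bases, alt = co$variant_bases)
  else if (has_alt)
    list(pos = co$start, ref = "N", alt = paste0("N", co$variant_bases))
  else
    list(pos = max(co$start - 1L, 1L),
         ref = paste0("N", co$reference_bases), alt = "N")
}

## ---- the writer ------------------------------------------------------------

#' VCF writer for knowledgebase variants
#'
#' Collects variant records (one VCF record per variant — co-located
#' variants are never merged) and writes a VCF 4.2 document whose `CSQ`
#' INFO field carries one entry per evidence item or assertion passing the
#' status filter. Invalid variants are skipped with a warning, never an
#' error. Duplicate `add_record()` calls are not deduplicated.
#'
#' @param include_status Statuses whose evidence/assertions are annotated;
#'   variants with no status-passing statement are dropped at write time.
#' @return A `kb_vcf_writer`.
#' @export
vcf_writer <- function(include_status = kb_default_statuses()) {
  include_status <- chk_status_set(include_status)
  w <- new.env(parent = emptyenv())
  w$include_status <- include_status
  w$drafts <- list()
  w$skipped <- data.table(variant_id = integer(0), reason = character(0))
  w$finalized <- FALSE
  class(w) <- "kb_vcf_writer"
  w
}

#' @export
print.kb_vcf_writer <- function(x, ...) {
  cat(sprintf("<kb_vcf_writer: %d draft(s), %d skipped, statuses=%s%s>\n",
              length(x$drafts), nrow(x$skipped),
              paste(x$include_status, collapse = "+"),
              if (x$finalized) ", finalized" else ""))
  invisible(x)
}

#' Add a variant to a VCF writer
#'
#' Valid variants are appended as drafts; invalid ones are skipped with a
#' warning naming the reason and logged in `writer$skipped`.
#'
#' @param writer A `kb_vcf_writer`.
#' @param variant A variant record.
#' @return `TRUE` (added) or `FALSE` (skipped), invisibly.
#' @export
add_record <- function(writer, variant) {
  if (writer$finalized)
    stop("writer already finalized; records were written", call. = FALSE)
  ok <- is_valid_for_vcf(variant)
  if (!ok) {
    reason <- attr(ok, "reason")
    writer$skipped <- rbind(writer$skipped,
                            data.table(variant_id = variant$record_id,
                                       reason = reason))
    warning(sprintf("variant %d ('%s') not added to VCF: %s",
                    variant$record_id, variant$name %na% "", reason),
            call. = FALSE)
    return(invisible(FALSE))
  }
  writer$drafts[[length(writer$drafts) + 1L]] <- variant
  invisible(TRUE)
}

#' CSQ entries for one variant
#'
#' One pipe-delimited entry per linked evidence item and per assertion
#' whose status is allowed, ordered evidence first then assertions,
#' ascending id. All values pass through [encode_csq_value()].
#'
#' @param variant A resolved variant record.
#' @param allowed_statuses Non-empty subset of [kb_statuses()].
#' @param allele The ALT string written for this variant (first CSQ field).
#' @return Character vector of encoded entries (possibly empty).
#' @export
build_csq_entries <- function(variant, allowed_statuses = kb_default_statuses(),
                              allele = NA) {
  allowed_statuses <- chk_status_set(allowed_statuses)
  enc <- encode_csq_value
  join <- function(xs) paste(enc(xs), collapse = "&")
  blob_name <- function(b) {
    if (is.null(b) || length(b$payload) == 0L) return("")
    as.character(b$payload$name %na% "")
  }
  gene_name <- if (!is.null(variant$gene) && !isTRUE(variant$gene$partial))
    variant$gene$name %na% "" else ""
  common <- c(
    Allele = enc(allele %na% ""),
    Gene = enc(gene_name),
    Variant_Name = enc(variant$name %na% ""),
    Variant_ID = as.character(variant$record_id),
    Variant_Aliases = join(variant$aliases),
    Variant_Types = join(variant$variant_types))

  entries <- character(0)
  ev <- Filter(function(e) !isTRUE(e$partial) &&
                 isTRUE(e$status %in% allowed_statuses), variant$evidence)
  ev <- ev[order(vapply(ev, function(e) e$record_id, integer(1)))]
  for (e in ev) {
    src <- if (!is.null(e$source) && !isTRUE(e$source$partial))
      e$source$citation_id %na% "" else ""
    f <- c(common,
           KB_Entity_Type = "evidence",
           KB_Entity_ID = as.character(e$record_id),
           KB_Entity_Status = enc(e$status %na% ""),
           Evidence_Level = enc(e$evidence_level %na% ""),
           Evidence_Direction = enc(e$evidence_direction %na% ""),
           Clinical_Significance = enc(e$clinical_significance %na% ""),
           Evidence_Rating = if (is.na(e$rating %na% NA)) "" else as.character(e$rating),
           Disease = enc(blob_name(e$disease)),
           Drugs = join(vapply(e$drugs, blob_name, character(1))),
           Source = enc(src),
           AMP_Category = "")
    entries <- c(entries, paste(f[CSQ_FIELDS], collapse = "|"))
  }
  as_ <- Filter(function(a) !isTRUE(a$partial) &&
                  isTRUE(a$status %in% allowed_statuses), variant$assertions)
  as_ <- as_[order(vapply(as_, function(a) a$record_id, integer(1)))]
  for (a in as_) {
    f <- c(common,
           KB_Entity_Type = "assertion",
           KB_Entity_ID = as.character(a$record_id),
           KB_Entity_Status = enc(a$status %na% ""),
           Evidence_Level = "", Evidence_Direction = "",
           Clinical_Significance = "", Evidence_Rating = "",
           Disease = enc(blob_name(a$disease)),
           Drugs = join(vapply(a$drugs, blob_name, character(1))),
           Source = "",
           AMP_Category = enc(a$amp_category %na% ""))
    entries <- c(entries, paste(f[CSQ_FIELDS], collapse = "|"))
  }
  entries
}

#' Write collected variants as a VCF 4.2 document
#'
#' Emits the header (fileformat, reference, contigs, the `CSQ` INFO
#' declaration listing [csq_fields()]) and one body line per draft variant
#' that has at least one status-passing CSQ entry, sorted by chromosome
#' (natural order) then position. Finalization is single-shot.
#'
#' @param writer A `kb_vcf_writer` with `>= 0` drafts.
#' @param path Output file path or connection.
#' @return Invisibly, the number of records written.
#' @export
write_records <- function(writer, path) {
  if (writer$finalized)
    stop("writer already finalized; records were written", call. = FALSE)
  rows <- list()
  for (v in writer$drafts) {
    al <- vcf_alleles(v$coordinates)
    csq <- build_csq_entries(v, writer$include_status, allele = al$alt)
    if (length(csq) == 0L) next
    rows[[length(rows) + 1L]] <- data.table(
      chrom = v$coordinates$chromosome, pos = as.integer(al$pos),
      id = as.character(v$record_id), ref = al$ref, alt = al$alt,
      info = paste0("CSQ=", paste(csq, collapse = ",")))
  }
  body <- if (length(rows)) rbindlist(rows) else
    data.table(chrom = character(0), pos = integer(0), id = character(0),
               ref = character(0), alt = character(0), info = character(0))
  body <- body[order(chromosome_rank(chrom), pos)]

  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")),
    sprintf("##source=kbmatch-%s",
            as.character(utils::packageVersion("kbmatch"))),
    "##reference=GRCh37",
    sprintf("##contig=<ID=%s>",
            unique(body$chrom)[order(chromosome_rank(unique(body$chrom)))]),
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=",
           "\"Clinical annotations from the variant knowledgebase. ",
           "One entry per evidence item or assertion. Format: ",
           paste(CSQ_FIELDS, collapse = "|"), "\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  lines <- c(hdr, if (nrow(body))
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
            body$chrom, body$pos, body$id, body$ref, body$alt, body$info))
  if (inherits(path, "connection")) writeLines(lines, path)
  else writeLines(lines, path, useBytes = TRUE)
  writer$finalized <- TRUE
  invisible(nrow(body))
}
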