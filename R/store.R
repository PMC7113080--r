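# Session-scoped salt for record keys. Regenerated on every package load so
# keys are deliberately NOT stable across sessions; persisted caches are
# keyed by (type, id) and keys are recomputed on load.
.kb_session <- new.env(parent = emptyenv())

session_salt <- function() {
  if (is.null(.kb_session$salt)) {
    .kb_session$salt <- sprintf("%08x%08x",
                                as.integer(Sys.getpid()),
                                as.integer(as.numeric(Sys.time()) %% 2^31))
  }
  .kb_session$salt
}

# test hook: force a "new session"
reset_session_salt <- function() {
  .kb_session$salt <- NULL
  invisible(NULL)
}

#' Session-scoped cache key for a record identity
#'
#' Equal `(record_type, record_id)` pairs yield equal keys within one R
#' session; a partial record and its fully-populated counterpart therefore
#' share a key and are treated as equivalent. Keys are salted per session
#' and must never be persisted.
#'
#' @param record_type Entity type name.
#' @param record_id Positive integer identifier.
#' @return Opaque key string.
#' @export
record_key <- function(record_type, record_id) {
  if (!record_type %in% KB_RECORD_TYPES)
    stop("unknown record_type: ", record_type, call. = FALSE)
  record_id <- as.integer(record_id)
  if (is.na(record_id) || record_id < 1L)
    stop("record_id must be a positive integer", call. = FALSE)
  paste0(session_salt(), "/", record_type, ":", record_id)
}

#' @rdname record_key
#' @param record A `kb_record` (full or partial).
#' @export
record_key_for <- function(record) {
  record_key(record$record_type, record$record_id)
}

CACHE_FORMAT_VERSION <- 1L

#' Cache envelope
#'
#' Wraps a record collection together with its build timestamp and expiry
#' horizon, and a session-key lookup map.
#'
#' @param records A `kb_collection`.
#' @param built_at UTC timestamp (`POSIXct`) when the cache content was
#'   generated; defaults to now.
#' @param expiry_days Positive number of days after which the cache counts
#'   as stale; default 7.
#' @return A `kb_cache` object.
#' @export
cache_envelope <- function(records, built_at = Sys.time(), expiry_days = 7) {
  stopifnot(inherits(records, "kb_collection"))
  if (!is.numeric(expiry_days) || expiry_days <= 0)
    stop("expiry_days must be > 0", call. = FALSE)
  built_at <- as.POSIXct(built_at, tz = "UTC")
  env <- new.env(parent = emptyenv())
  env$built_at <- built_at
  env$expiry_days <- as.numeric(expiry_days)
  env$records <- records
  env$keys <- new.env(parent = emptyenv())   # session key -> record
  for (t in KB_RECORD_TYPES)
    for (id in records$ids[[t]])
      env$keys[[record_key(t, id)]] <- kb_get(records, t, id)
  class(env) <- "kb_cache"
  env
}

#' @export
print.kb_cache <- function(x, ...) {
  cat(sprintf("<kb_cache built %s UTC, expiry %g d, %d records>\n",
              format(x$built_at, "%Y-%m-%d %H:%M:%S"),
              x$expiry_days, kb_count(x$records)))
  invisible(x)
}

#' Retrieve a record from a cache by session key
#'
#' @param cache A `kb_cache`.
#' @param key Key produced by [record_key()] in this session.
#' @return The record, or `NULL`.
#' @export
cache_get <- function(cache, key) cache$keys[[key]]

#' Is a cache stale?
#'
#' Pure predicate: `TRUE` iff `now - built_at` strictly exceeds
#' `expiry_days`. A cache exactly at the boundary is still valid.
#'
#' @param cache A `kb_cache`.
#' @param now Comparison time; defaults to the current time.
#' @param expiry_days Override of the envelope's expiry horizon.
#' @return Logical scalar.
#' @export
is_stale <- function(cache, now = Sys.time(), expiry_days = cache$expiry_days) {
  now <- as.POSIXct(now, tz = "UTC")
  if (now < cache$built_at)
    stop("clock skew: `now` precedes the cache build time", call. = FALSE)
  age_days <- as.numeric(difftime(now, cache$built_at, units = "days"))
  age_days > expiry_days
}

#' Save / load a cache
#'
#' The on-disk format is the snapshot JSON dialect wrapped in a small
#' metadata header (`built_at`, `expiry_days`, format version) — human
#' inspectable, and keyed only by `(type, id)`: session keys are never
#' persisted and are recomputed on load.
#'
#' @param cache A `kb_cache`.
#' @param path File path.
#' @return `save_cache()`: `path`, invisibly. `load_cache()`: a `kb_cache`.
#' @export
save_cache <- function(cache, path) {
  doc <- list(
    cache_format_version = CACHE_FORMAT_VERSION,
    built_at = format(cache$built_at, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC"),
    expiry_days = cache$expiry_days,
    snapshot = jsonlite::parse_json(serialize_snapshot(cache$records))
  )
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)),
             tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_cache
#' @export
load_cache <- function(path) {
  if (!file.exists(path))
    stop("cache file does not exist: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::parse_json(paste(readLines(path, warn = FALSE), collapse = "\n")),
    error = function(e) stop("corrupt cache file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ver <- doc$cache_format_version
  if (is.null(ver) || is.null(doc$snapshot) || is.null(doc$built_at))
    stop("corrupt cache file ", path, ": missing header fields", call. = FALSE)
  if (!identical(as.integer(ver), CACHE_FORMAT_VERSION))
    stop("incompatible cache format version ", ver, " in ", path,
         " (expected ", CACHE_FORMAT_VERSION, ")", call. = FALSE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(jsonlite::toJSON(doc$snapshot, auto_unbox = TRUE,
                                           digits = NA)),
             tmp, useBytes = TRUE)
  records <- parse_snapshot(tmp)
  built_at <- as.POSIXct(strptime(doc$built_at, "%Y-%m-%dT%H:%M:%OSZ",
                                  tz = "UTC"))
  if (is.na(built_at))
    stop("corrupt cache file ", path, ": unparseable built_at", call. = FALSE)
  cache_envelope(records, built_at = built_at,
                 expiry_days = doc$expiry_days %na% 7)
}

#' Default cache location
#'
#' A platform-appropriate per-user cache directory, overridable with the
#' `KBMATCH_CACHE` environment variable.
#'
#' @return Directory path (not created).
#' @export
default_cache_path <- function() {
  override <- Sys.getenv("KBMATCH_CACHE", "")
  if (nzchar(override)) return(override)
  file.path(tools::R_user_dir("kbmatch", which = "cache"), "cache.json")
}

#' Rebuild the cache from a snapshot source
#'
#' Reads a snapshot (local file path, `file://` URL, or connection), builds
#' a fresh envelope stamped with the retrieval time, and — when
#' `cache_path` is given — replaces the on-disk cache atomically: a failed
#' refresh leaves any previous cache untouched.
#'
#' @param source Snapshot file path / URL / connection.
#' @param cache_path Optional path to persist the refreshed cache.
#' @param expiry_days Expiry horizon for the new envelope.
#' @return The new `kb_cache`.
#' @export
refresh_cache <- function(source, cache_path = NULL, expiry_days = 7) {
  src <- source
  if (is.character(src) && grepl("^file://", src))
    src <- sub("^file://", "", src)
  records <- tryCatch(
    parse_snapshot(src),
    error = function(e) stop("snapshot retrieval failed (existing cache ",
                             "left untouched): ", conditionMessage(e),
                             call. = FALSE))
  env <- cache_envelope(records, built_at = Sys.time(),
                        expiry_days = expiry_days)
  if (!is.null(cache_path)) {
    dir.create(dirname(cache_path), recursive = TRUE, showWarnings = FALSE)
    save_cache(env, cache_path)   # write-then-rename inside
  }
  env
}
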