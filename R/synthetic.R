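# Deterministic generation: run `code` under `seed` without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

SIM_CHROMS <- as.character(1:5)   # simulated genome: 5 chromosomes x 1 Mb
SIM_CHROM_LEN <- 1e6L
SIM_KB_REGION <- c(1L, 700000L)        # knowledgebase variants live here
SIM_BG_REGION <- c(800001L, 999000L)   # background (never-matching) region

#' Synthetic generator configuration
#'
#' Parameters of the simulated knowledgebase and tumor cohort. Defaults
#' encode the stated world the generator emulates: tumors report on
#' average 6.88 variants; 7.6% of cohort variants are planted as exact
#' copies of knowledgebase variants and a further 42.9% as non-exact
#' overlaps; 8.7% of samples carry no variants at all.
#'
#' @param seed Integer random seed; equal seeds give byte-identical
#'   snapshots.
#' @param n_genes,n_variants,n_evidence,n_assertions Entity counts.
#' @param fraction_compound Proportion of variants given a second
#'   coordinate set (fusion-like).
#' @param fraction_missing_coords Proportion of variants lacking usable
#'   coordinates (excluded from the index by construction).
#' @param status_weights Named probabilities over accepted / submitted /
#'   rejected.
#' @param level_weights Named probabilities over evidence levels A-E.
#' @param cohort_size Number of tumor samples.
#' @param variants_per_sample_mean Poisson mean of per-sample variant
#'   counts (default 6.88).
#' @param planted_exact_fraction Probability that a cohort variant copies a
#'   knowledgebase variant's exact coordinates and allele (default 0.076).
#' @param planted_overlap_fraction Probability of a coordinate overlap
#'   without exactness (default 0.429).
#' @param fraction_empty_samples Proportion of samples with zero reported
#'   variants (default 0.087).
#' @return A validated `kb_generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 25L, n_variants = 300L,
                             n_evidence = 600L, n_assertions = 30L,
                             fraction_compound = 0.10,
                             fraction_missing_coords = 0.05,
                             status_weights = c(accepted = 0.60,
                                                submitted = 0.25,
                                                rejected = 0.15),
                             level_weights = c(A = 0.05, B = 0.30, C = 0.30,
                                               D = 0.25, E = 0.10),
                             cohort_size = 200L,
                             variants_per_sample_mean = 6.88,
                             planted_exact_fraction = 0.076,
                             planted_overlap_fraction = 0.429,
                             fraction_empty_samples = 0.087) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_variants = as.integer(n_variants),
              n_evidence = as.integer(n_evidence),
              n_assertions = as.integer(n_assertions),
              fraction_compound = fraction_compound,
              fraction_missing_coords = fraction_missing_coords,
              status_weights = status_weights,
              level_weights = level_weights,
              cohort_size = as.integer(cohort_size),
              variants_per_sample_mean = variants_per_sample_mean,
              planted_exact_fraction = planted_exact_fraction,
              planted_overlap_fraction = planted_overlap_fraction,
              fraction_empty_samples = fraction_empty_samples)
  fr <- c(cfg$fraction_compound, cfg$fraction_missing_coords,
          cfg$planted_exact_fraction, cfg$planted_overlap_fraction,
          cfg$fraction_empty_samples)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("generator fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$planted_exact_fraction + cfg$planted_overlap_fraction > 1)
    stop("planted fractions must sum to at most 1", call. = FALSE)
  for (w in list(cfg$status_weights, cfg$level_weights))
    if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
      stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (!setequal(names(cfg$status_weights), KB_STATUSES) ||
      !setequal(names(cfg$level_weights), KB_EVIDENCE_LEVELS))
    stop("weights must be named over the full status / level sets",
         call. = FALSE)
  if (any(c(cfg$n_genes, cfg$n_variants, cfg$n_evidence, cfg$n_assertions,
            cfg$cohort_size) < 0L))
    stop("counts must be >= 0", call. = FALSE)
  if (cfg$variants_per_sample_mean < 0)
    stop("variants_per_sample_mean must be >= 0", call. = FALSE)
  structure(cfg, class = "kb_generator_config")
}

rbase <- function(n, exclude = NULL) {
  pool <- setdiff(c("A", "C", "G", "T"), exclude)
  sample(pool, n, replace = TRUE)
}

#' Generate a synthetic knowledgebase snapshot
#'
#' Builds a snapshot document (linked genes, variants, evidence,
#' assertions, sources) over a small simulated genome (5 chromosomes of
#' 1 Mb) together with a ground-truth ledger of every variant's
#' coordinates and every evidence item's status and level. Variant shapes
#' mix SNVs, insertions, deletions, bare ranges, compound (two-coordinate)
#' variants and coordinate-free variants, in the configured proportions.
#' The same seed always yields a byte-identical snapshot.
#'
#' @param config A `kb_generator_config`.
#' @param path Optional file path; when given the snapshot JSON is written
#'   there.
#' @return List with `snapshot` (JSON string), `collection` (parsed and
#'   resolved `kb_collection`), and `ledger` (list of `variants` and
#'   `evidence` ground-truth tables).
#' @export
generate_knowledgebase <- function(config = generator_config(), path = NULL) {
  stopifnot(inherits(config, "kb_generator_config"))
  res <- with_seed(config$seed, {
    n_v <- config$n_variants
    n_g <- max(config$n_genes, if (n_v > 0L) 1L else 0L)
    genes <- lapply(seq_len(n_g), function(i)
      list(id = i, name = sprintf("GENE%03d", i),
           entrez_id = 1000L + i, variant_ids = list()))

    vrows <- vector("list", n_v)
    variants <- vector("list", n_v)
    for (i in seq_len(n_v)) {
      gid <- sample.int(n_g, 1L)
      shape_u <- runif(1)
      missing <- runif(1) < config$fraction_missing_coords
      compound <- !missing && runif(1) < config$fraction_compound
      chrom <- sample(SIM_CHROMS, 1L)
      start <- sample(SIM_KB_REGION[1L]:SIM_KB_REGION[2L], 1L)
      ref <- NA_character_; alt <- NA_character_
      stop_ <- start
      chrom2 <- NA_character_; start2 <- NA_integer_; stop2 <- NA_integer_
      if (missing) {
        chrom <- NA_character_; start <- NA_integer_; stop_ <- NA_integer_
      } else if (compound) {
        stop_ <- start + sample.int(200L, 1L) - 1L
        chrom2 <- sample(SIM_CHROMS, 1L)
        start2 <- sample(SIM_KB_REGION[1L]:SIM_KB_REGION[2L], 1L)
        stop2 <- start2 + sample.int(200L, 1L) - 1L
      } else if (shape_u < 0.70) {        # SNV
        ref <- rbase(1L); alt <- rbase(1L, exclude = ref)
      } else if (shape_u < 0.80) {        # insertion: alt only
        alt <- paste(rbase(sample.int(8L, 1L)), collapse = "")
      } else if (shape_u < 0.90) {        # deletion: ref only
        len <- sample.int(12L, 1L)
        stop_ <- start + len - 1L
        ref <- paste(rbase(len), collapse = "")
      } else {                            # bare range (no alleles)
        stop_ <- start + sample.int(200L, 1L) - 1L
      }
      co <- list(chromosome = chrom, start = start, stop = stop_,
                 reference_bases = ref, variant_bases = alt,
                 chromosome2 = chrom2, start2 = start2, stop2 = stop2)
      co <- co[!vapply(co, is.na, logical(1))]
      variants[[i]] <- list(
        id = i, gene_id = gid, name = sprintf("VAR%04d", i),
        aliases = as.list(sprintf("VAR%04d-alias", i)),
        variant_types = list(if (compound) "fusion" else "single_nucleotide_variant"),
        coordinates = co, evidence_ids = list(), assertion_ids = list())
      genes[[gid]]$variant_ids <- c(genes[[gid]]$variant_ids, list(i))
      vrows[[i]] <- data.table(
        variant_id = i, chromosome = chrom, start = start, stop = stop_,
        ref = ref, alt = alt, compound = compound, missing_coords = missing,
        chromosome2 = chrom2, start2 = start2, stop2 = stop2)
    }

    n_src <- max(3L, config$n_evidence %/% 4L)
    sources <- lapply(seq_len(if (config$n_evidence > 0L) n_src else 0L),
                      function(i) list(id = i,
                                       citation = sprintf("Author et al., %d", 1990L + (i %% 30L)),
                                       source_type = "PubMed",
                                       citation_id = as.character(10000L + i)))

    erows <- vector("list", config$n_evidence)
    evidence <- vector("list", config$n_evidence)
    diseases <- c("melanoma", "lung adenocarcinoma", "colorectal cancer",
                  "breast cancer", "acute myeloid leukemia")
    drugs <- c("trametinib", "vemurafenib", "erlotinib", "imatinib")
    for (j in seq_len(config$n_evidence)) {
      if (n_v == 0L) break
      vid <- sample.int(n_v, 1L)
      st <- sample(names(config$status_weights), 1L,
                   prob = config$status_weights)
      lv <- sample(names(config$level_weights), 1L,
                   prob = config$level_weights)
      evidence[[j]] <- list(
        id = j, variant_id = vid, status = st, evidence_level = lv,
        evidence_direction = sample(c("Supports", "Does Not Support"), 1L),
        clinical_significance = sample(c("Sensitivity/Response", "Resistance",
                                         "Poor Outcome", "Better Outcome"), 1L),
        disease = list(name = sample(diseases, 1L)),
        drugs = lapply(sample(drugs, sample.int(2L, 1L)),
                       function(d) list(name = d)),
        source_id = sample.int(n_src, 1L), rating = sample.int(5L, 1L))
      variants[[vid]]$evidence_ids <- c(variants[[vid]]$evidence_ids, list(j))
      erows[[j]] <- data.table(evidence_id = j, variant_id = vid,
                               status = st, level = lv)
    }

    assertions <- vector("list", config$n_assertions)
    for (k in seq_len(config$n_assertions)) {
      if (n_v == 0L || config$n_evidence == 0L) break
      vid <- sample.int(n_v, 1L)
      eids <- unlist(variants[[vid]]$evidence_ids)
      if (length(eids) == 0L) eids <- sample.int(config$n_evidence, 1L)
      assertions[[k]] <- list(
        id = k, status = sample(names(config$status_weights), 1L,
                                prob = config$status_weights),
        amp_category = sample(c("Tier I", "Tier II"), 1L),
        variant_id = vid, evidence_ids = as.list(eids),
        disease = list(name = sample(diseases, 1L)), drugs = list())
      variants[[vid]]$assertion_ids <- c(variants[[vid]]$assertion_ids,
                                         list(k))
    }
    assertions <- Filter(Negate(is.null), assertions)
    evidence <- Filter(Negate(is.null), evidence)

    doc <- list(format = SNAPSHOT_FORMAT, version = SNAPSHOT_VERSION,
                reference_build = "GRCh37",
                genes = genes, variants = variants, variant_groups = list(),
                evidence = evidence, assertions = assertions,
                sources = sources, users = list(), organizations = list())
    json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                          null = "null", digits = NA))
    ledger <- list(
      variants = if (n_v > 0L) rbindlist(vrows) else
        data.table(variant_id = integer(0), chromosome = character(0),
                   start = integer(0), stop = integer(0), ref = character(0),
                   alt = character(0), compound = logical(0),
                   missing_coords = logical(0), chromosome2 = character(0),
                   start2 = integer(0), stop2 = integer(0)),
      evidence = if (config$n_evidence > 0L && n_v > 0L) rbindlist(erows) else
        data.table(evidence_id = integer(0), variant_id = integer(0),
                   status = character(0), level = character(0)))
    list(json = json, ledger = ledger)
  })
  if (!is.null(path)) writeLines(res$json, path, useBytes = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(res$json, tmp, useBytes = TRUE)
  coll <- parse_snapshot(tmp)
  unlink(tmp)
  resolve_links(coll)
  list(snapshot = res$json, collection = coll, ledger = res$ledger)
}

#' Generate a synthetic tumor cohort with known ground truth
#'
#' Simulates a MAF-like table of per-sample variants against a generated
#' knowledgebase. Per-sample counts are Poisson; a configured fraction of
#' samples report no variants at all. Each variant row is planted as one
#' of: an `exact` copy of a knowledgebase variant's coordinates and allele;
#' an `overlap` — the interval of a knowledgebase variant expanded by
#' 1-50 bases on either side (guaranteed to overlap, guaranteed not to
#' coincide with any knowledgebase interval); or `none` — drawn from a
#' background region of the simulated genome disjoint from all
#' knowledgebase coordinates. The truth label of every row is therefore
#' consistent with the search predicates by construction.
#'
#' @param config A `kb_generator_config`.
#' @param ledger Ledger from [generate_knowledgebase()].
#' @param path Optional path; when given the MAF TSV is written there.
#' @return List with `maf` (data.table in MAF column layout), `truth`
#'   (per-row labels), and `samples` (every barcode, including empty
#'   samples).
#' @export
generate_cohort <- function(config, ledger, path = NULL) {
  stopifnot(inherits(config, "kb_generator_config"))
  lv <- ledger$variants
  eligible <- lv[lv$missing_coords == FALSE & lv$compound == FALSE]
  exact_pool <- eligible
  with_coords <- lv[lv$missing_coords == FALSE]
  compounds <- lv[lv$compound == TRUE]
  coord_keys <- unique(c(
    if (nrow(with_coords))
      paste(with_coords$chromosome, with_coords$start, with_coords$stop)
    else character(0),
    if (nrow(compounds))
      paste(compounds$chromosome2, compounds$start2, compounds$stop2)
    else character(0)))

  with_seed(config$seed + 1L, {
    barcodes <- sprintf("SAMPLE-%05d", seq_len(config$cohort_size))
    empty <- runif(config$cohort_size) < config$fraction_empty_samples
    rows <- list()
    truth <- character(0)
    for (s in seq_len(config$cohort_size)) {
      if (empty[s]) next
      k <- rpois(1L, config$variants_per_sample_mean)
      if (k == 0L) next
      for (i in seq_len(k)) {
        u <- runif(1)
        if (u < config$planted_exact_fraction && nrow(exact_pool) > 0L) {
          src <- exact_pool[sample.int(nrow(exact_pool), 1L)]
          row <- list(barcode = barcodes[s], chrom = src$chromosome,
                      start = src$start, stop = src$stop,
                      ref = src$ref, alt = src$alt)
          lab <- "exact"
        } else if (u < config$planted_exact_fraction +
                     config$planted_overlap_fraction && nrow(eligible) > 0L) {
          src <- eligible[sample.int(nrow(eligible), 1L)]
          repeat {
            j1 <- sample(0:50, 1L); j2 <- sample(0:50, 1L)
            if (j1 + j2 == 0L) next
            ns <- max(1L, src$start - j1); ne <- src$stop + j2
            if (!(paste(src$chromosome, ns, ne) %in% coord_keys)) break
          }
          row <- list(barcode = barcodes[s], chrom = src$chromosome,
                      start = ns, stop = ne, ref = NA_character_,
                      alt = rbase(1L, exclude = src$alt))
          lab <- "overlap"
        } else {
          chrom <- sample(SIM_CHROMS, 1L)
          start <- sample(SIM_BG_REGION[1L]:SIM_BG_REGION[2L], 1L)
          ref <- rbase(1L)
          row <- list(barcode = barcodes[s], chrom = chrom, start = start,
                      stop = start, ref = ref, alt = rbase(1L, exclude = ref))
          lab <- "none"
        }
        rows[[length(rows) + 1L]] <- row
        truth <- c(truth, lab)
      }
    }
    maf <- if (length(rows)) {
      rb <- rbindlist(lapply(rows, as.data.table))
      data.table(Tumor_Sample_Barcode = rb$barcode,
                 Chromosome = rb$chrom,
                 Start_Position = rb$start, End_Position = rb$stop,
                 Reference_Allele = ifelse(is.na(rb$ref), "-", rb$ref),
                 Tumor_Seq_Allele2 = ifelse(is.na(rb$alt), "-", rb$alt))
    } else data.table(Tumor_Sample_Barcode = character(0),
                      Chromosome = character(0),
                      Start_Position = integer(0), End_Position = integer(0),
                      Reference_Allele = character(0),
                      Tumor_Seq_Allele2 = character(0))
    if (!is.null(path))
      fwrite(maf, path, sep = "\t", quote = FALSE)
    list(maf = maf, truth = truth, samples = barcodes)
  })
}
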