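# reading, QC, aggregation, pooling, subsampling and writing of clonotype tables

# column synonyms for the ImmunoSEQ-style dialect (matched case-insensitively)
.IMMUNOSEQ_SYNONYMS <- list(
  cdr3aa = c("amino_acid", "aminoacid", "aminoAcid", "cdr3_amino_acid", "cdr3aa"),
  v_gene = c("v_gene", "vgenename", "v_resolved", "vresolved"),
  j_gene = c("j_gene", "jgenename", "j_resolved", "jresolved"),
  count  = c("templates", "count", "reads", "count_templates_reads",
             "count (templates/reads)", "templates/reads"),
  frame  = c("frame_type", "frametype", "sequencestatus", "sequence_status")
)

.matchColumn <- function(cols, synonyms) {
  hit <- match(tolower(synonyms), tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit)) cols[hit[1L]] else NA_character_
}

#' Read a clonotype table
#'
#' Reads tab-separated clonotype tables in three dialects: `"simple"`
#' (columns `cdr3aa`, `v_gene`, `j_gene`, `count`), `"airr"` (AIRR-C
#' rearrangement columns `junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`) and `"immunoseq"` (ImmunoSEQ-style export; column
#' names are matched case-insensitively against a synonym list, and rows not
#' marked in-frame by a frame/productive column, when present, are dropped).
#' Frequencies are always recomputed from counts; any frequency column in the
#' file is ignored. Rows with an empty CDR3 are dropped with a message.
#'
#' @param path file path.
#' @param dialect one of `"simple"`, `"airr"`, `"immunoseq"`.
#' @param sampleId sample identifier; defaults to the file's base name.
#' @param metadata named list of sample metadata.
#' @return a [Repertoire-class]
#' @export
readClonotypeTable <- function(path, dialect = c("simple", "airr", "immunoseq"),
                               sampleId = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cols <- colnames(tab)
  pick <- function(wanted) {
    miss <- setdiff(wanted, cols)
    if (length(miss)) {
      stop(sprintf("%s dialect: missing mandatory column(s): %s",
                   dialect, paste(miss, collapse = ", ")))
    }
  }
  if (dialect == "simple") {
    pick(c("cdr3aa", "v_gene", "j_gene", "count"))
    df <- data.frame(cdr3aa = tab$cdr3aa, v_gene = tab$v_gene,
                     j_gene = tab$j_gene, count = as.integer(tab$count),
                     stringsAsFactors = FALSE)
  } else if (dialect == "airr") {
    pick(c("junction_aa", "v_call", "j_call", "duplicate_count"))
    df <- data.frame(cdr3aa = tab$junction_aa, v_gene = tab$v_call,
                     j_gene = tab$j_call, count = as.integer(tab$duplicate_count),
                     stringsAsFactors = FALSE)
  } else {
    aa <- .matchColumn(cols, .IMMUNOSEQ_SYNONYMS$cdr3aa)
    ct <- .matchColumn(cols, .IMMUNOSEQ_SYNONYMS$count)
    if (is.na(aa)) stop("immunoseq dialect: missing mandatory amino-acid column (amino_acid)")
    if (is.na(ct)) stop("immunoseq dialect: missing mandatory count column (templates)")
    vg <- .matchColumn(cols, .IMMUNOSEQ_SYNONYMS$v_gene)
    jg <- .matchColumn(cols, .IMMUNOSEQ_SYNONYMS$j_gene)
    df <- data.frame(
      cdr3aa = tab[[aa]],
      v_gene = if (!is.na(vg)) tab[[vg]] else NA_character_,
      j_gene = if (!is.na(jg)) tab[[jg]] else NA_character_,
      count = as.integer(tab[[ct]]), stringsAsFactors = FALSE)
    fr <- .matchColumn(cols, .IMMUNOSEQ_SYNONYMS$frame)
    if (!is.na(fr)) {
      keep <- tolower(tab[[fr]]) %in% c("in", "in-frame", "inframe", "productive")
      if (any(!keep)) message(sprintf("dropped %d row(s) not marked in-frame", sum(!keep)))
      df <- df[keep, , drop = FALSE]
    }
  }
  empty <- is.na(df$cdr3aa) | df$cdr3aa == ""
  if (any(empty)) {
    message(sprintf("dropped %d row(s) with empty CDR3", sum(empty)))
    df <- df[!empty, , drop = FALSE]
  }
  if (nrow(df) == 0L || sum(df$count) == 0L) {
    stop("empty repertoire: no rows with reads after reading")
  }
  if (is.null(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  Repertoire(df, sampleId = sampleId, metadata = metadata)
}

#' Remove non-functional clonotypes
#'
#' Drops clonotypes whose CDR3 contains a stop (`*`) or frameshift marker
#' (`_`, `#`), lowercase or non-standard residues, or is shorter than
#' `minLength` residues; frequencies are recomputed over the survivors.
#' Idempotent. Surviving sequences match
#' `^C?[ACDEFGHIKLMNPQRSTVWY]+F?$`.
#'
#' @param rep a [Repertoire-class].
#' @param minLength minimum CDR3 length kept (default 5).
#' @return the filtered `Repertoire`; the number removed is reported via
#'   `message()`.
#' @export
filterFunctional <- function(rep, minLength = 5L) {
  assertRepertoire(rep)
  cl <- rep@clonotypes
  ok <- isFunctionalCdr3(cl$cdr3aa, minLength = minLength)
  if (all(!ok)) stop("empty repertoire: all clonotypes are non-functional")
  if (any(!ok)) message(sprintf("removed %d non-functional clonotype(s)", sum(!ok)))
  cl <- recomputeFrequencies(cl[ok, , drop = FALSE])
  rownames(cl) <- NULL
  methods::initialize(rep, clonotypes = cl)
}

#' @rdname filterFunctional
#' @param cdr3aa character vector of CDR3 amino-acid sequences.
#' @export
isFunctionalCdr3 <- function(cdr3aa, minLength = 5L) {
  !is.na(cdr3aa) &
    nchar(cdr3aa) >= minLength &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3aa)
}

#' Merge duplicate clonotypes under an identity key
#'
#' Clonotypes identical under the chosen key are merged with counts summed.
#' Under the `"cdr3"` key the V/J genes of the largest merged row are kept.
#'
#' @param rep a [Repertoire-class].
#' @param key `"cdr3_v"` (default: CDR3 + V gene) or `"cdr3"`.
#' @return a `Repertoire` with unique keys.
#' @export
aggregateDuplicates <- function(rep, key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  assertRepertoire(rep)
  cl <- rep@clonotypes
  k <- cloneKey(cl, key)
  if (!anyDuplicated(k)) return(rep)
  ord <- order(k, -cl$count)
  cl <- cl[ord, , drop = FALSE]
  k <- k[ord]
  first <- !duplicated(k)
  merged <- cl[first, , drop = FALSE]
  merged$count <- as.integer(tapply(cl$count, k, sum)[k[first]])
  merged <- recomputeFrequencies(merged)
  rownames(merged) <- NULL
  methods::initialize(rep, clonotypes = merged)
}

#' Pool repertoires into one sample
#'
#' Takes the union of clonotypes across samples with counts summed under the
#' identity key, then renormalises frequencies over the pool — the standard
#' join used when combining replicates or timepoints of one subject.
#'
#' @param reps non-empty list of [Repertoire-class] objects.
#' @param newId sample identifier of the pool.
#' @param key clone identity key, as in [aggregateDuplicates()].
#' @return the pooled `Repertoire`.
#' @export
poolRepertoires <- function(reps, newId = "pool", key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  if (!length(reps)) stop("poolRepertoires: empty repertoire list")
  lapply(reps, assertRepertoire)
  cl <- do.call(rbind, lapply(reps, function(r) r@clonotypes[, c("cdr3aa", "v_gene", "j_gene", "count")]))
  pooled <- Repertoire(cl, sampleId = newId)
  aggregateDuplicates(pooled, key = key)
}

#' Subsample a repertoire to a fixed read depth
#'
#' Draws `depth` reads without replacement (a multivariate hypergeometric
#' draw over clones, realised by sequential conditional [stats::rhyper()]
#' draws); returned counts sum exactly to `depth`. Deterministic for a fixed
#' seed. Clones drawn zero times are removed.
#'
#' @param rep a [Repertoire-class].
#' @param depth number of reads to keep; must not exceed the total.
#' @param seed integer seed.
#' @return the subsampled `Repertoire`.
#' @export
subsampleRepertoire <- function(rep, depth, seed) {
  assertRepertoire(rep)
  cl <- rep@clonotypes
  total <- sum(cl$count)
  depth <- as.integer(depth)
  if (depth <= 0L) stop("depth must be positive")
  if (depth > total) stop(sprintf("depth (%d) exceeds total reads (%d)", depth, total))
  draws <- withSeed(seed, {
    out <- integer(nrow(cl))
    remaining <- total
    need <- depth
    for (i in seq_len(nrow(cl))) {
      if (need == 0L) break
      remaining <- remaining - cl$count[i]
      if (remaining == 0L) { out[i] <- need; need <- 0L; break }
      x <- stats::rhyper(1L, cl$count[i], remaining, need)
      out[i] <- x
      need <- need - x
    }
    out
  })
  keep <- draws > 0L
  cl <- cl[keep, , drop = FALSE]
  cl$count <- draws[keep]
  cl <- recomputeFrequencies(cl)
  rownames(cl) <- NULL
  methods::initialize(rep, clonotypes = cl)
}

#' Write a clonotype table
#'
#' Writes the `"simple"` or `"airr"` dialect as tab-separated text such that
#' [readClonotypeTable()] inverts it exactly (CDR3, V/J genes, counts).
#'
#' @param rep a non-empty [Repertoire-class].
#' @param path output path.
#' @param dialect `"simple"` or `"airr"`.
#' @export
writeClonotypeTable <- function(rep, path, dialect = c("simple", "airr")) {
  dialect <- match.arg(dialect)
  assertRepertoire(rep)
  cl <- rep@clonotypes
  out <- if (dialect == "simple") {
    data.frame(cdr3aa = cl$cdr3aa, v_gene = cl$v_gene, j_gene = cl$j_gene,
               count = cl$count, stringsAsFactors = FALSE)
  } else {
    data.frame(junction_aa = cl$cdr3aa, v_call = cl$v_gene, j_call = cl$j_gene,
               duplicate_count = cl$count, stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
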