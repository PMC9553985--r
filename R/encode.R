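# fixed-length numeric encoding of CDR3 sequences
#
# Residues are embedded via a spectral decomposition of the BLOSUM62
# substitution matrix (so similar residues map to nearby vectors), and the
# variable-length CDR3 is placed in a fixed frame IMGT-style: split at the
# midpoint, left half left-aligned, right half right-aligned, centre slots
# zero-coded as gaps.

.tcrscopeCache <- new.env(parent = emptyenv())

# d-dimensional residue embedding from BLOSUM62: rows of V_d sqrt(|lambda_d|)
# for the top-d eigenvalues by magnitude (deterministic)
residueEmbedding <- function(d = 6L) {
  key <- paste0("blosum_", d)
  if (!is.null(.tcrscopeCache[[key]])) return(.tcrscopeCache[[key]])
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62[AA_STANDARD, AA_STANDARD]
  eg <- eigen(B, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(d)]
  E <- eg$vectors[, ord, drop = FALSE] %*% diag(sqrt(abs(eg$values[ord])), d)
  # fix the sign convention so the embedding is reproducible across BLAS
  for (j in seq_len(d)) if (E[which.max(abs(E[, j])), j] < 0) E[, j] <- -E[, j]
  rownames(E) <- AA_STANDARD
  .tcrscopeCache[[key]] <- E
  E
}

#' Encode CDR3 sequences as fixed-length numeric vectors
#'
#' Each sequence is optionally trimmed by `trim` residues at both ends, split
#' at its midpoint, and written into a `maxLen`-slot frame with the left half
#' left-aligned and the right half right-aligned; unfilled centre slots are
#' gap-coded as zero vectors. Each residue occupies `d` dimensions given by a
#' spectral BLOSUM62 embedding, so the output has `maxLen * d` columns.
#' Deterministic.
#'
#' @param cdr3aa character vector of QC-passing CDR3 sequences.
#' @param maxLen frame length in residues (default 22); sequences whose core
#'   exceeds it raise an error.
#' @param trim residues removed from each end before encoding (default 0).
#' @param d embedding dimension per residue (default 6).
#' @return numeric matrix, one row per sequence.
#' @export
encodeCdr3 <- function(cdr3aa, maxLen = 22L, trim = 0L, d = 6L) {
  E <- residueEmbedding(d)
  n <- length(cdr3aa)
  out <- matrix(0, n, maxLen * d)
  for (i in seq_len(n)) {
    s <- cdr3aa[i]
    if (is.na(s)) stop("NA sequence cannot be encoded")
    core <- if (trim > 0L) substr(s, trim + 1L, nchar(s) - trim) else s
    len <- nchar(core)
    if (len < 1L) stop(sprintf("sequence '%s' empty after trimming", s))
    if (len > maxLen) stop(sprintf("sequence '%s' longer than maxLen = %d", s, maxLen))
    res <- strsplit(core, "")[[1]]
    idx <- match(res, AA_STANDARD)
    if (anyNA(idx)) {
      stop(sprintf("non-standard residue '%s' in sequence '%s'",
                   res[which(is.na(idx))[1]], s))
    }
    nl <- ceiling(len / 2)
    slots <- c(seq_len(nl), maxLen - (len - nl) + seq_len(len - nl))
    for (j in seq_len(len)) {
      out[i, (slots[j] - 1L) * d + seq_len(d)] <- E[idx[j], ]
    }
  }
  rownames(out) <- names(cdr3aa)
  out
}

# TRUE where a sequence can be encoded under the given frame
encodableCdr3 <- function(cdr3aa, maxLen = 22L, trim = 0L) {
  core <- nchar(cdr3aa) - 2L * trim
  !is.na(cdr3aa) & core >= 1L & core <= maxLen &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3aa)
}
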