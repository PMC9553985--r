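#' @import methods
NULL

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Repertoire: a sample's TCR-beta clonotype table
#'
#' A `Repertoire` holds one sample's clonotypes (CDR3 amino-acid sequence,
#' V/J gene calls, read count and read frequency) together with sample-level
#' metadata. Frequencies are always derived from counts by the package and
#' renormalised after every mutating operation, so rounding in input files
#' cannot propagate.
#'
#' @slot sampleId single sample identifier.
#' @slot clonotypes `data.frame` with columns `cdr3aa`, `v_gene`, `j_gene`,
#'   `count`, `frequency` (extra columns, e.g. specificity labels added by
#'   [classifyRepertoire()], are permitted and preserved).
#' @slot metadata named list; recognised keys include `subject`, `timepoint`
#'   (`"pre"`, `"post"`, `"none"`), `tissue`, `group`, `age`, `response`.
#'
#' @seealso [readClonotypeTable()], [filterFunctional()], [poolRepertoires()]
#' @export
setClass("Repertoire",
  representation(
    sampleId   = "character",
    clonotypes = "data.frame",
    metadata   = "list"
  ),
  prototype(sampleId = NA_character_, metadata = list())
)

setValidity("Repertoire", function(object) {
  cl <- object@clonotypes
  need <- c("cdr3aa", "v_gene", "j_gene", "count", "frequency")
  miss <- setdiff(need, colnames(cl))
  if (length(miss)) {
    return(sprintf("clonotype table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  if (any(cl$count < 0, na.rm = TRUE)) return("counts must be non-negative")
  tot <- sum(cl$count)
  if (nrow(cl) > 0L && tot > 0) {
    if (abs(sum(cl$frequency) - 1) > 1e-9) {
      return("frequencies must sum to 1 (within 1e-9) when total count > 0")
    }
    if (max(abs(cl$frequency - cl$count / tot)) > 1e-12) {
      return("frequency must equal count / total count (within 1e-12)")
    }
  }
  TRUE
})

#' TrainingSet: epitope-labelled CDR3 sequences plus background
#'
#' Positives are CDR3-beta sequences sorted (experimentally or synthetically)
#' against one epitope, optionally with subject identifiers to support
#' leave-one-subject-out cross-validation. The background holds non-specific
#' CDR3s; when `balanced` is `TRUE` the background size equals the number of
#' positives, mirroring the 1:1 training construction used for the classifier.
#'
#' @slot epitope epitope name, e.g. `"MART1_AAGIGILTV"`.
#' @slot positives `data.frame` with columns `cdr3aa` and `subject`
#'   (`NA` when unknown).
#' @slot background character vector of background CDR3s (possibly empty
#'   before [trainEpitopeModel()] draws one from a pool).
#' @slot balanced logical flag.
#' @export
setClass("TrainingSet",
  representation(
    epitope    = "character",
    positives  = "data.frame",
    background = "character",
    balanced   = "logical"
  ),
  prototype(balanced = FALSE, background = character())
)

setValidity("TrainingSet", function(object) {
  if (!all(c("cdr3aa", "subject") %in% colnames(object@positives))) {
    return("positives must have columns cdr3aa and subject")
  }
  if (length(object@background) &&
      any(object@positives$cdr3aa %in% object@background)) {
    return("a sequence appears in both positives and background")
  }
  if (isTRUE(object@balanced) && length(object@background) &&
      length(object@background) != nrow(object@positives)) {
    return("balanced set requires |background| == |positives|")
  }
  TRUE
})

#' EpitopeModel: a calibrated probabilistic CDR3 classifier for one epitope
#'
#' Wraps a Laplace-approximate Gaussian-process classifier (squared-exponential
#' kernel over substitution-matrix CDR3 embeddings) with its encoder
#' configuration, fitted state, optional FPR-calibrated decision threshold and
#' optional cross-validation report.
#'
#' @slot epitope epitope name.
#' @slot config list: `max_len`, `trim`, `d` (embedding dimension),
#'   `lengthscale`, `sigma2` (signal variance), `jitter`.
#' @slot fit list with the training encodings, latent solution and
#'   likelihood bookkeeping (see [trainEpitopeModel()]); `fit$method` records
#'   whether the Laplace GP or the kernel-logistic fallback was used.
#' @slot threshold decision threshold on the predicted probability scale, or
#'   `NA` before [calibrateThreshold()].
#' @slot cvReport list (a ROC report, see [crossValidate()]) or empty.
#' @slot seed integer seed used for the background draw.
#' @export
setClass("EpitopeModel",
  representation(
    epitope   = "character",
    config    = "list",
    fit       = "list",
    threshold = "numeric",
    cvReport  = "list",
    seed      = "integer"
  ),
  prototype(threshold = NA_real_, cvReport = list(), seed = NA_integer_)
)

setValidity("EpitopeModel", function(object) {
  if (length(object@threshold) != 1L) return("threshold must be length 1")
  if (!is.na(object@threshold) &&
      (object@threshold < 0 || object@threshold > 1)) {
    return("threshold must lie in [0, 1] (probability scale)")
  }
  TRUE
})

#' ModelPanel: a named set of epitope models with group-combination rules
#'
#' Groups map a label (e.g. `"MAA"`, `"VIRAL"`) to the epitopes whose models
#' vote for it; a clonotype is group-positive when *any* grouped model calls it
#' positive (the union rule used for the in-silico multimer sort).
#'
#' @slot models named list of [EpitopeModel-class] objects.
#' @slot groups named list mapping group name to a character vector of epitope
#'   names present in `models`.
#' @export
setClass("ModelPanel",
  representation(models = "list", groups = "list"),
  prototype(models = list(), groups = list())
)

setValidity("ModelPanel", function(object) {
  if (length(object@models) && is.null(names(object@models))) {
    return("models must be a named list")
  }
  for (g in names(object@groups)) {
    bad <- setdiff(object@groups[[g]], names(object@models))
    if (length(bad)) {
      return(sprintf("group '%s' references unknown epitope(s): %s",
                     g, paste(bad, collapse = ", ")))
    }
  }
  TRUE
})

#' @describeIn Repertoire-class number of clonotypes
#' @param x,object a `Repertoire`
#' @export
setMethod("length", "Repertoire", function(x) nrow(x@clonotypes))

setMethod("show", "Repertoire", function(object) {
  cl <- object@clonotypes
  cat(sprintf("Repertoire '%s': %d clonotypes, %d reads\n",
              object@sampleId, nrow(cl), sum(cl$count)))
  if (nrow(cl)) {
    top <- utils::head(cl[order(-cl$count), c("cdr3aa", "v_gene", "count", "frequency")], 3L)
    cat("  top clones:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s %s  count=%d  freq=%.4g\n", top$cdr3aa[i],
                  ifelse(is.na(top$v_gene[i]), ".", top$v_gene[i]),
                  top$count[i], top$frequency[i]))
    }
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), unlist(lapply(object@metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet '%s': %d positives (%d subject(s)), %d background%s\n",
              object@epitope, nrow(object@positives),
              length(unique(stats::na.omit(object@positives$subject))),
              length(object@background),
              if (isTRUE(object@balanced)) ", balanced" else ""))
  invisible(NULL)
})

setMethod("show", "EpitopeModel", function(object) {
  cat(sprintf("EpitopeModel '%s' (%s): %d training points, lengthscale %.3g%s\n",
              object@epitope,
              if (length(object@fit)) object@fit$method else "unfitted",
              if (length(object@fit)) nrow(object@fit$X) else 0L,
              if (length(object@config$lengthscale)) object@config$lengthscale else NA_real_,
              if (!is.na(object@threshold))
                sprintf(", threshold %.4g", object@threshold) else ", uncalibrated"))
  invisible(NULL)
})

setMethod("show", "ModelPanel", function(object) {
  cat(sprintf("ModelPanel: %d models, %d groups\n",
              length(object@models), length(object@groups)))
  for (g in names(object@groups)) {
    cat(sprintf("  %s: %s\n", g, paste(object@groups[[g]], collapse = ", ")))
  }
  invisible(NULL)
})

#' Construct a Repertoire from a clonotype data.frame
#'
#' Frequencies are (re)computed from `count`; input frequency columns are
#' ignored.
#'
#' @param clonotypes data.frame with at least `cdr3aa` and `count`; optional
#'   `v_gene`, `j_gene` (missing genes kept as `NA`).
#' @param sampleId sample identifier.
#' @param metadata named list of sample-level metadata.
#' @return a [Repertoire-class]
#' @export
Repertoire <- function(clonotypes, sampleId = "sample", metadata = list()) {
  stopifnot(is.data.frame(clonotypes), all(c("cdr3aa", "count") %in% colnames(clonotypes)))
  cl <- data.frame(
    cdr3aa = as.character(clonotypes$cdr3aa),
    v_gene = if ("v_gene" %in% colnames(clonotypes))
      as.character(clonotypes$v_gene) else NA_character_,
    j_gene = if ("j_gene" %in% colnames(clonotypes))
      as.character(clonotypes$j_gene) else NA_character_,
    count = as.integer(clonotypes$count),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(colnames(clonotypes), c(colnames(cl), "frequency"))
  for (nm in extra) cl[[nm]] <- clonotypes[[nm]]
  cl$v_gene[!is.na(cl$v_gene) & cl$v_gene == ""] <- NA_character_
  cl$j_gene[!is.na(cl$j_gene) & cl$j_gene == ""] <- NA_character_
  cl <- recomputeFrequencies(cl)
  methods::new("Repertoire", sampleId = sampleId, clonotypes = cl,
               metadata = metadata)
}

#' @rdname Repertoire-class
#' @export
sampleId <- function(object) object@sampleId

#' @rdname Repertoire-class
#' @export
clonotypes <- function(object) object@clonotypes

#' @rdname Repertoire-class
#' @export
repMetadata <- function(object) object@metadata

#' Accessors for TrainingSet / EpitopeModel / ModelPanel
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
epitopeName <- function(object) object@epitope

#' @rdname accessors
#' @export
positives <- function(object) object@positives

#' @rdname accessors
#' @export
backgroundSeqs <- function(object) object@background

#' @rdname accessors
#' @export
modelThreshold <- function(object) object@threshold

#' @rdname accessors
#' @export
cvReport <- function(object) object@cvReport

#' @rdname accessors
#' @export
panelModels <- function(object) object@models

#' @rdname accessors
#' @export
panelGroups <- function(object) object@groups
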