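# longitudinal clonal dynamics: expansion calling and clonal replacement

#' Per-clone expansion test between paired pre/post repertoires
#'
#' For every clone (union of both samples under the identity key) with at
#' least `minTotal` reads overall, runs a two-sided Fisher exact test on the
#' 2x2 table of unnormalised read depths
#' `[(count_pre, total_pre - count_pre), (count_post, total_post - count_post)]`,
#' adjusts across all tested clones of the pair with Benjamini-Hochberg, and
#' flags a clone *expanded* when the adjusted p is below `alpha` and its
#' post-therapy frequency exceeds its pre-therapy frequency (significant
#' contractions are `direction = "down"`, not expanded). Clones absent from
#' one sample enter with count 0.
#'
#' @param pre,post [Repertoire-class] objects with counts.
#' @param minTotal minimum pre+post reads to test a clone (default 2; set to
#'   0 to test singletons too).
#' @param alpha BH significance level for the expanded flag (default 0.05).
#' @param key clone identity key (see [aggregateDuplicates()]).
#' @return `data.frame` of class `ExpansionResult`: `clone_key`,
#'   `count_pre`, `count_post`, `total_pre`, `total_post`, `odds_ratio`
#'   (Haldane-corrected post/pre cross-product), `p_value`, `p_adjusted`,
#'   `direction`, `expanded`; untested clones carry `NA` p-values.
#' @export
expansionTest <- function(pre, post, minTotal = 2L, alpha = 0.05,
                          key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  assertRepertoire(pre); assertRepertoire(post)
  totPre <- sum(pre@clonotypes$count)
  totPost <- sum(post@clonotypes$count)
  if (totPre == 0L || totPost == 0L) stop("zero-depth sample")
  kp <- cloneKey(pre@clonotypes, key)
  kq <- cloneKey(post@clonotypes, key)
  keys <- union(kp, kq)
  cPre <- pre@clonotypes$count[match(keys, kp)]
  cPost <- post@clonotypes$count[match(keys, kq)]
  cPre[is.na(cPre)] <- 0L
  cPost[is.na(cPost)] <- 0L
  test <- (cPre + cPost) >= minTotal
  p <- rep(NA_real_, length(keys))
  p[test] <- vapply(which(test), function(i) {
    stats::fisher.test(matrix(c(cPre[i], totPre - cPre[i],
                                cPost[i], totPost - cPost[i]), 2L,
                              byrow = TRUE))$p.value
  }, numeric(1))
  padj <- rep(NA_real_, length(keys))
  padj[test] <- bhAdjust(p[test])
  fPre <- cPre / totPre
  fPost <- cPost / totPost
  direction <- ifelse(fPost > fPre, "up", ifelse(fPost < fPre, "down", "flat"))
  or <- ((cPost + 0.5) * (totPre - cPre + 0.5)) /
        ((cPre + 0.5) * (totPost - cPost + 0.5))
  out <- data.frame(clone_key = keys, count_pre = cPre, count_post = cPost,
                    total_pre = totPre, total_post = totPost,
                    odds_ratio = or, p_value = p, p_adjusted = padj,
                    direction = direction,
                    expanded = !is.na(padj) & padj < alpha & direction == "up",
                    stringsAsFactors = FALSE)
  class(out) <- c("ExpansionResult", "data.frame")
  out
}

#' Count expanded clones per specificity group
#'
#' @param er an [expansionTest()] result.
#' @param labels named character vector mapping clone keys to group labels
#'   (`"MAA"`, `"VIRAL"`, ...); clones without an entry count as `"none"`.
#' @param groups group labels to tabulate.
#' @return named integer vector of expanded-clone counts per group.
#' @export
countExpandedByLabel <- function(er, labels,
                                 groups = c("MAA", "VIRAL", "none")) {
  stopifnot(inherits(er, "ExpansionResult"))
  keys <- er$clone_key[er$expanded]
  lab <- labels[keys]
  lab[is.na(lab)] <- "none"
  out <- stats::setNames(integer(length(groups)), groups)
  tb <- table(factor(lab, levels = groups))
  out[names(tb)] <- as.integer(tb)
  out
}

#' Clonal replacement metrics for a pre/post pair
#'
#' The replacing set is the post-therapy clones absent from the pre-therapy
#' sample (by identity key); its summed post-sample frequency equals
#' 1 minus the frequency of persisting clones, exactly. The clonality of the
#' replacing clones is computed as for whole repertoires, and an optional
#' per-specificity-group breakdown of the replacing frequency is returned.
#'
#' @param pre,post non-empty [Repertoire-class] objects.
#' @param labels optional named vector mapping clone keys to group labels.
#' @param key clone identity key.
#' @return list: `replacing_frequency`, `persisting_frequency`,
#'   `n_replacing`, `replacing_clonality`, `by_group` (named numeric or
#'   `NULL`), `replacing_keys`.
#' @export
replacementMetrics <- function(pre, post, labels = NULL,
                               key = c("cdr3_v", "cdr3")) {
  key <- match.arg(key)
  assertRepertoire(pre); assertRepertoire(post)
  kp <- unique(cloneKey(pre@clonotypes, key))
  cl <- post@clonotypes
  kq <- cloneKey(cl, key)
  repl <- !(kq %in% kp)
  persisting <- sum(cl$frequency[!repl])
  p <- cl$frequency[repl]
  p <- p / sum(p)
  clonRepl <- if (sum(repl) >= 2L) 1 - (-sum(p * log(p))) / log(sum(repl)) else NA_real_
  byGroup <- NULL
  if (!is.null(labels)) {
    lab <- labels[kq]
    lab[is.na(lab)] <- "none"
    byGroup <- vapply(split(cl$frequency[repl], lab[repl]), sum, numeric(1))
  }
  list(replacing_frequency = 1 - persisting,
       persisting_frequency = persisting,
       n_replacing = sum(repl),
       replacing_clonality = clonRepl,
       by_group = byGroup,
       replacing_keys = kq[repl])
}
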