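# independent oracles used across the suite; deliberately brute-force and
# kept separate from the package's own computation paths

# one-sided (greater) Fisher p for [a, NT-a; b, NR-b] by direct enumeration
# of the hypergeometric pmf
oracleFisherGreater <- function(a, NT, b, NR) {
  K <- a + b                 # motif-positive margin
  n <- NT + NR
  xs <- max(0, K - NR):min(K, NT)
  probs <- exp(lchoose(NT, xs) + lchoose(NR, K - xs) - lchoose(n, K))
  sum(probs[xs >= a])
}

# two-sided Fisher p for a 2x2 table (rows = samples): sum of hypergeometric
# probabilities not exceeding the observed one (standard definition, with
# the customary 1e-7 relative tolerance at ties)
oracleFisherTwoSided <- function(a, b, c, d) {
  K <- a + b
  xs <- max(0, K - (b + d)):min(K, a + c)
  probs <- exp(lchoose(a + c, xs) + lchoose(b + d, K - xs) -
                 lchoose(a + b + c + d, K))
  pObs <- probs[xs == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# textbook BH step-up
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# exhaustive concordant-pair AUROC (ties count 1/2)
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# tiny repertoire builder (distinct functional CDR3s by default)
makeRep <- function(counts, cdr3 = NULL, v = NULL, id = "r") {
  n <- length(counts)
  if (is.null(cdr3)) {
    cdr3 <- vapply(seq_len(n), function(i) {
      paste0("CASS", paste(AA[(i + 0:2) %% 20 + 1], collapse = ""), "EQYF")
    }, "")
  }
  Repertoire(data.frame(cdr3aa = cdr3,
                        v_gene = if (is.null(v)) "TRBV9" else v,
                        j_gene = "TRBJ2-1", count = counts,
                        stringsAsFactors = FALSE), sampleId = id)
}
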