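## geNorm stability analysis. The stability of gene j is the mean SD of the
## pairwise log2 ratios against all other candidates (M value); the least
## stable gene is excluded and M recomputed until the most stable pair
## remains. V(n/n+1), the SD of log2(NF_n / NF_{n+1}), decides how many
## reference genes a normalization factor needs (conventional cutoff 0.15).

#' Transform collapsed Ct values to relative quantities
#'
#' `Q[g, s] = E_g ^ (minCt_g - Ct[g, s])` with `E_g` the gene's
#' amplification efficiency, so the lowest-Ct (highest-expression) sample
#' of each gene gets quantity 1.
#'
#' Genes with some missing wells are dropped with a warning (the analysis
#' needs a complete matrix); a gene with no values at all is an error.
#'
#' @param ct a [CtTable], already collapsed to one well per sample
#'   (see [collapseReplicates()]).
#' @return a [QuantityMatrix].
#' @export
ctToQuantity <- function(ct) {
  cd <- colData(ct)
  if (anyDuplicated(cd$sample_id))
    stop("collapse technical replicates first (collapseReplicates)")
  m <- assay(ct, "ct")
  colnames(m) <- cd$sample_id
  all_missing <- rownames(m)[rowSums(!is.na(m)) == 0]
  if (length(all_missing) > 0)
    stop("gene(s) with no Ct values at all: ",
         paste(all_missing, collapse = ", "))
  incomplete <- rownames(m)[rowSums(is.na(m)) > 0]
  if (length(incomplete) > 0) {
    warning("dropping gene(s) with missing wells: ",
            paste(incomplete, collapse = ", "))
    m <- m[!rownames(m) %in% incomplete, , drop = FALSE]
  }
  e <- efficiencies(ct)[rownames(m)]
  q <- e ^ (apply(m, 1, min) - m)
  new("QuantityMatrix", q = q, efficiency = e)
}

#' Relative quantities of a QuantityMatrix
#'
#' @param x a [QuantityMatrix].
#' @return the gene x sample numeric matrix.
#' @export
quantities <- function(x) x@q

#' Pairwise stability matrix
#'
#' `V[j, k]` is the sample SD over samples of `log2(Q_j / Q_k)`;
#' symmetric with a zero diagonal.
#'
#' @param q a [QuantityMatrix] (at least 2 genes and 2 samples).
#' @return gene x gene numeric matrix.
#' @export
pairwiseStability <- function(q) {
  L <- log2(quantities(q))
  G <- nrow(L)
  stopifnot(G >= 2, ncol(L) >= 2)
  V <- matrix(0, G, G, dimnames = list(rownames(L), rownames(L)))
  for (j in seq_len(G - 1)) {
    for (k in (j + 1):G) {
      V[j, k] <- V[k, j] <- sd(L[j, ] - L[k, ])
    }
  }
  V
}

#' geNorm M values over an active gene set
#'
#' `M_j` is the mean of the pairwise stabilities of gene `j` against every
#' other active gene. With exactly two genes both M equal their pairwise V.
#'
#' @param q a [QuantityMatrix].
#' @param active gene symbols to evaluate (default all).
#' @return named numeric vector.
#' @export
mValues <- function(q, active = NULL) {
  V <- pairwiseStability(q)
  if (is.null(active)) active <- rownames(V)
  if (length(active) < 2) stop("need at least 2 active genes")
  V <- V[active, active, drop = FALSE]
  rowSums(V) / (length(active) - 1)
}

#' Per-sample normalization factor from a gene set
#'
#' Geometric mean of the selected genes' relative quantities; duplicated
#' gene names are used once.
#'
#' @param q a [QuantityMatrix].
#' @param genes nonempty set of gene symbols.
#' @return named numeric vector, one value per sample.
#' @export
normalizationFactor <- function(q, genes) {
  genes <- unique(genes)
  stopifnot(length(genes) >= 1)
  m <- quantities(q)[genes, , drop = FALSE]
  exp(colMeans(log(m)))
}

#' Pairwise variation series V(n/n+1) along a stability ranking
#'
#' For n = 2 .. G-1, `V(n/n+1)` is the sample SD over samples of
#' `log2(NF_n / NF_{n+1})`, genes added in stability order. The
#' recommended number of reference genes is the smallest n with
#' `V < cutoff` (NA when never achieved).
#'
#' @param q a [QuantityMatrix] with at least 3 genes.
#' @param ranking gene symbols, most stable first (all genes of `q`).
#' @param cutoff V threshold, default 0.15.
#' @return list with elements `v_series` (data.frame n, v) and
#'   `recommended_n` (integer or NA).
#' @export
pairwiseVariation <- function(q, ranking, cutoff = 0.15) {
  G <- length(ranking)
  stopifnot(G >= 3, setequal(ranking, rownames(quantities(q))))
  v <- vapply(2:(G - 1), function(n) {
    nf_n <- normalizationFactor(q, ranking[seq_len(n)])
    nf_n1 <- normalizationFactor(q, ranking[seq_len(n + 1)])
    sd(log2(nf_n / nf_n1))
  }, numeric(1))
  vs <- data.frame(n = 2:(G - 1), v = v)
  hit <- which(vs$v < cutoff)
  list(v_series = vs,
       recommended_n = if (length(hit) > 0) vs$n[hit[1]] else NA_integer_)
}

#' geNorm analysis: stepwise exclusion ranking, M values and V series
#'
#' Repeatedly removes the gene with the highest M (recomputing M each
#' round) until two genes remain; those form the most stable pair and
#' share rank 1. Ties on M are broken by excluding the gene occurring
#' later in input order. Each gene's reported stability is its M at the
#' round of its elimination; the final pair shares its two-gene M.
#'
#' @param x a [QuantityMatrix], or a collapsed [CtTable] (transformed via
#'   [ctToQuantity()] first).
#' @param cutoff V(n/n+1) threshold for the recommended number of
#'   reference genes, default 0.15.
#' @return a [GenormResult].
#' @examples
#' d <- data.frame(sample_id = paste0("s", 1:4), organ = "root", stage = "LP")
#' ct <- CtTable(matrix(20 + rnorm(12), 3, 4,
#'               dimnames = list(paste0("g", 1:3), d$sample_id)), d)
#' geNorm(ct)
#' @export
geNorm <- function(x, cutoff = 0.15) {
  q <- if (is(x, "CtTable")) ctToQuantity(x) else x
  stopifnot(is(q, "QuantityMatrix"))
  genes <- rownames(quantities(q))
  G <- length(genes)
  if (G < 3) stop("geNorm needs at least 3 genes")
  V <- pairwiseStability(q)
  active <- genes
  exclusion <- character(0)
  stab <- setNames(numeric(G), genes)
  while (length(active) > 2) {
    M <- rowSums(V[active, active, drop = FALSE]) / (length(active) - 1)
    worst_val <- max(M)
    ties <- active[M >= worst_val - 1e-15]
    # later input order loses on a tie
    worst <- ties[which.max(match(ties, genes))]
    stab[worst] <- M[worst]
    exclusion <- c(exclusion, worst)
    active <- setdiff(active, worst)
  }
  pair_m <- V[active[1], active[2]]
  stab[active] <- pair_m
  pair <- genes[genes %in% active]  # input order within the final pair
  ranking <- c(pair, rev(exclusion))
  pv <- pairwiseVariation(q, ranking, cutoff)
  new("GenormResult", stability = stab, ranking = ranking,
      exclusionOrder = exclusion, stablePair = pair,
      vSeries = pv$v_series,
      recommendedN = as.integer(pv$recommended_n), cutoff = cutoff)
}
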