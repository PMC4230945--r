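## BestKeeper-style descriptive stability: per-gene Ct dispersion (SD as
## mean absolute deviation around the arithmetic mean, CV = 100*SD/mean),
## a per-sample geometric-mean Ct index over the candidate set, and each
## gene's Pearson correlation with that index. Ranking is by CV, SD as
## tie-break.

.ctSampleMatrix <- function(ct) {
  cd <- colData(ct)
  if (anyDuplicated(cd$sample_id))
    stop("collapse technical replicates first (collapseReplicates)")
  m <- assay(ct, "ct")
  colnames(m) <- cd$sample_id
  m
}

#' Per-gene descriptive Ct statistics
#'
#' @param ct a collapsed [CtTable]; missing cells are dropped per gene
#'   with a message reporting how many.
#' @param sdMethod `"mad"` (mean absolute deviation around the arithmetic
#'   mean, the BestKeeper convention; default) or `"classic"` (n-1 SD).
#' @return data.frame: gene, n, geo_mean, ar_mean, min, max, sd, cv_pct.
#' @examples
#' # Ct (20, 22): arithmetic mean 21, geometric mean 20.976, MAD 1, CV 4.762%
#' @export
descriptiveStats <- function(ct, sdMethod = c("mad", "classic")) {
  sdMethod <- match.arg(sdMethod)
  m <- .ctSampleMatrix(ct)
  if (any(!is.na(m) & m <= 0)) stop("Ct values must be positive")
  n_dropped <- sum(is.na(m))
  if (n_dropped > 0)
    message("descriptiveStats: dropping ", n_dropped, " missing well(s)")
  res <- lapply(rownames(m), function(g) {
    x <- m[g, ]
    x <- x[!is.na(x)]
    if (length(x) < 2)
      stop(sprintf("gene '%s' has fewer than 2 observations", g))
    mu <- mean(x)
    s <- if (sdMethod == "mad") mean(abs(x - mu)) else sd(x)
    data.frame(gene = g, n = length(x), geo_mean = exp(mean(log(x))),
               ar_mean = mu, min = min(x), max = max(x), sd = s,
               cv_pct = 100 * s / mu, row.names = NULL)
  })
  do.call(rbind, res)
}

#' BestKeeper index: per-sample geometric mean Ct over a gene set
#'
#' @param ct a collapsed [CtTable].
#' @param genes 2 or more gene symbols (duplicates are used once); the
#'   original applet caps the input at 10 genes, enforced here via `cap`.
#' @param cap maximum number of genes (default 10; raise to lift the
#'   applet-inherited limit).
#' @return named numeric vector, one index value per sample.
#' @export
bestKeeperIndex <- function(ct, genes, cap = 10L) {
  genes <- unique(genes)
  if (length(genes) < 2) stop("the index needs at least 2 genes")
  if (length(genes) > cap)
    stop(sprintf("%d genes exceed the method's %d-gene limit (raise cap to override)",
                 length(genes), cap))
  m <- .ctSampleMatrix(ct)[genes, , drop = FALSE]
  if (anyNA(m)) stop("index genes must have complete rows")
  exp(colMeans(log(m)))
}

#' Pearson correlation of each gene's Ct with the index
#'
#' Two-sided p-values from the t distribution with n - 2 degrees of
#' freedom. A zero-variance gene has no defined correlation and is
#' reported as NA with a reason.
#'
#' @param ct a collapsed [CtTable] with at least 3 samples.
#' @param index per-sample index values (named by sample).
#' @return data.frame: gene, r, p, note.
#' @export
indexCorrelations <- function(ct, index) {
  m <- .ctSampleMatrix(ct)
  if (ncol(m) < 3) stop("need at least 3 samples")
  idx <- index[colnames(m)]
  res <- lapply(rownames(m), function(g) {
    x <- m[g, ]
    keep <- !is.na(x) & !is.na(idx)
    if (sd(x[keep]) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        note = "zero-variance gene", row.names = NULL))
    ht <- cor.test(x[keep], idx[keep], method = "pearson")
    data.frame(gene = g, r = unname(ht$estimate), p = ht$p.value,
               note = "", row.names = NULL)
  })
  do.call(rbind, res)
}

#' BestKeeper analysis: dispersion, index and index correlations
#'
#' @param ct a collapsed [CtTable].
#' @param genes genes entering the index (default: all genes of `ct`,
#'   which must then respect `cap`).
#' @param cap gene limit for the index (default 10).
#' @param sdMethod dispersion convention, see [descriptiveStats()].
#' @return a [BestkeeperResult]; ranks are by CV, then SD, then input
#'   order, and are invariant to sample order.
#' @export
bestKeeper <- function(ct, genes = NULL, cap = 10L,
                       sdMethod = c("mad", "classic")) {
  sdMethod <- match.arg(sdMethod)
  if (is.null(genes)) genes <- rownames(ct)
  stats <- descriptiveStats(ct[genes, ], sdMethod)
  index <- bestKeeperIndex(ct, genes, cap = cap)
  corr <- indexCorrelations(ct[genes, ], index)
  stats <- merge(stats, corr, by = "gene", sort = FALSE)
  stats$rank <- rank_order <- order(stats$cv_pct, stats$sd,
                                    seq_len(nrow(stats)))
  stats$rank[rank_order] <- seq_len(nrow(stats))
  new("BestkeeperResult", stats = stats, index = index, sdMethod = sdMethod)
}
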