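## Candidate reference-gene screening from an abundance matrix: per-group
## mean/SD/CV/MFC, an expression-window filter, and CV/MFC thresholding.
## Groups are either one organ across all stages or one stage across all
## organs, so a 3 organ x 5 stage design yields 8 groups.

#' Per-group descriptive statistics (mean, SD, CV, MFC) per gene
#'
#' CV is the percent coefficient of variation (100 * SD / mean) and MFC the
#' maximum fold change (max / min) of a gene's abundances within a group.
#'
#' @param expr an [ExpressionTable].
#' @param grouping `"organ"` (each organ across stages) or `"stage"` (each
#'   stage across organs).
#' @param sdDenominator `"n-1"` (sample SD, default) or `"n"`.
#' @return data.frame: gene, group, mean, sd, cv_pct, mfc.
#' @examples
#' # (100, 200, 300) within a group: CV 50%, MFC 3
#' @export
groupStats <- function(expr, grouping = c("organ", "stage"),
                       sdDenominator = c("n-1", "n")) {
  grouping <- match.arg(grouping)
  sdDenominator <- match.arg(sdDenominator)
  m <- assay(expr, "abundance")
  fac <- colData(expr)[[grouping]]
  levels <- unique(fac)
  res <- lapply(levels, function(g) {
    cols <- which(fac == g)
    if (length(cols) < 2)
      stop(sprintf("group '%s' has fewer than 2 samples", g))
    sub <- m[, cols, drop = FALSE]
    if (any(sub <= 0))
      stop(sprintf("non-positive abundance in group '%s' (gene '%s')",
                   g, rownames(sub)[which(sub <= 0, arr.ind = TRUE)[1, 1]]))
    mu <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    if (sdDenominator == "n")
      s <- s * sqrt((length(cols) - 1) / length(cols))
    data.frame(gene = rownames(sub), group = g, mean = mu, sd = s,
               cv_pct = 100 * s / mu,
               mfc = apply(sub, 1, max) / apply(sub, 1, min),
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Expression-window filter on group mean abundance
#'
#' Keeps the genes whose mean abundance in every group (both the per-organ
#' and per-stage margins) lies inside the window. Extremely abundant genes
#' (ribosomal RNA-like, means in the thousands) are thereby excluded.
#'
#' @param expr an [ExpressionTable].
#' @param window numeric(2), inclusive bounds; default `c(50, 500)`.
#' @param scope `"group_means"` (default) applies the window to per-group
#'   means; `"samples"` applies it to every individual sample value.
#' @return character vector of retained gene symbols.
#' @export
abundanceFilter <- function(expr, window = c(50, 500),
                            scope = c("group_means", "samples")) {
  scope <- match.arg(scope)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (nrow(expr) == 0) return(character(0))
  if (scope == "samples") {
    m <- assay(expr, "abundance")
    ok <- rowSums(m < window[1] | m > window[2]) == 0
    return(rownames(expr)[ok])
  }
  st <- rbind(groupStats(expr, "organ"), groupStats(expr, "stage"))
  ok <- tapply(st$mean >= window[1] & st$mean <= window[2], st$gene, all)
  intersect(rownames(expr), names(ok)[ok])  # keep input order
}

#' Screen candidates by CV and MFC thresholds
#'
#' A (gene, group) cell passes when its CV and MFC, rounded to
#' `roundingDp` decimals, are `<=` the thresholds (the printed-precision
#' `<=` rule admits values published exactly at the threshold, e.g. an MFC
#' of 1.50). The candidate set is the genes passing in at least
#' `minGroups` groups; a user-supplied housekeeping panel can be exempted
#' from the screen entirely via `exclude`.
#'
#' @param stats data.frame with columns gene, group, cv_pct, mfc (from
#'   [groupStats()] or a published table loaded with [table1Fixture()]).
#' @param cvMax CV threshold in percent (default 20).
#' @param mfcMax MFC threshold (default 1.50).
#' @param minGroups minimum number of passing groups (default 1, the union
#'   rule over per-group listings).
#' @param roundingDp decimals used for the threshold comparison (default 2,
#'   matching published precision).
#' @param exclude gene symbols exempted from the screen (not eligible as
#'   candidates, typically because they are carried forward regardless).
#' @return a [ScreeningReport].
#' @export
screenCandidates <- function(stats, cvMax = 20.0, mfcMax = 1.50,
                             minGroups = 1L, roundingDp = 2L,
                             exclude = character()) {
  stopifnot(nrow(stats) > 0,
            all(c("gene", "group", "cv_pct", "mfc") %in% colnames(stats)))
  stats$pass <- round(stats$cv_pct, roundingDp) <= cvMax &
    round(stats$mfc, roundingDp) <= mfcMax
  eligible <- stats[!(stats$gene %in% exclude), , drop = FALSE]
  npass <- tapply(eligible$pass, eligible$gene, sum)
  cand <- names(npass)[npass >= minGroups]
  cand <- intersect(unique(stats$gene), cand)  # preserve input order
  new("ScreeningReport", stats = stats, candidates = cand,
      thresholds = list(cv_max = cvMax, mfc_max = mfcMax,
                        min_groups = as.integer(minGroups),
                        rounding_dp = as.integer(roundingDp)),
      excluded = as.character(exclude))
}

#' Write a screening report to TSV
#'
#' @param x a [ScreeningReport].
#' @param path output TSV (columns gene, group, mean, sd, cv_pct, mfc,
#'   pass; mean/sd omitted if absent from the stats).
#' @return `invisible(x)`.
#' @export
writeScreeningReport <- function(x, path) {
  cols <- intersect(c("gene", "group", "mean", "sd", "cv_pct", "mfc", "pass"),
                    colnames(x@stats))
  df <- x@stats[, cols, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(df[i, ], function(v)
      if (is.numeric(v)) format(v, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(v), character(1)), collapse = "\t"), character(1))
  writeLines(c(paste(cols, collapse = "\t"), fmt), con)
  invisible(x)
}

#' Published per-group screening statistics shipped with the package
#'
#' The per-gene, per-group mean / CV / MFC values of the 20-gene ginseng
#' candidate panel (10 classical housekeeping genes present in all 8
#' groups, 10 novel genes listed in the groups where they satisfied the
#' screen), as printed in the source study's screening table. `sd` is
#' back-computed from CV and mean.
#'
#' @return data.frame: gene, group, mean, sd, cv_pct, mfc, housekeeping.
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "screening_table1.tsv",
                      package = "qpcrStability", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$housekeeping <- as.logical(df$housekeeping)
  df$sd <- df$cv_pct / 100 * df$mean
  df[, c("gene", "group", "mean", "sd", "cv_pct", "mfc", "housekeeping")]
}
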