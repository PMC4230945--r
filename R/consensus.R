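## Side-by-side comparison of the three stability methods and a consensus
## order by rank aggregation (geometric mean of available ranks), plus the
## end-to-end pipeline over the study-style sample sets (total, one per
## organ, one per stage).

.genormRanks <- function(gn) {
  genes <- names(gn@stability)
  pos <- match(genes, gn@ranking)
  r <- pos
  r[pos <= 2] <- 1L  # the most stable pair shares rank 1
  setNames(as.integer(r), genes)
}

#' Combine per-method rankings into one table
#'
#' BestKeeper may have ranked only a capped subset; its missing ranks are
#' reported as NA.
#'
#' @param genorm a [GenormResult].
#' @param normfinder a [NormfinderResult] on the same gene universe.
#' @param bestkeeper a [BestkeeperResult] on the same universe or a
#'   subset of it (`NULL` to omit the method).
#' @return a [ComparativeRanking] (aggregate columns filled by
#'   [aggregateRanks()]).
#' @export
methodRankTable <- function(genorm, normfinder, bestkeeper = NULL) {
  genes <- names(genorm@stability)
  if (!setequal(genes, names(normfinder@stability)))
    stop("geNorm and NormFinder must be computed on the same gene universe")
  nf_rank <- setNames(match(genes, normfinder@ranking), genes)
  bk_rank <- setNames(rep(NA_integer_, length(genes)), genes)
  if (!is.null(bestkeeper)) {
    extra <- setdiff(bestkeeper@stats$gene, genes)
    if (length(extra) > 0)
      stop("BestKeeper gene(s) outside the universe: ",
           paste(extra, collapse = ", "))
    bk_rank[bestkeeper@stats$gene] <- bestkeeper@stats$rank
  }
  tab <- data.frame(gene = genes,
                    genorm = unname(.genormRanks(genorm)[genes]),
                    normfinder = as.integer(unname(nf_rank)),
                    bestkeeper = as.integer(unname(bk_rank)),
                    aggregate = NA_real_, final_rank = NA_integer_,
                    row.names = NULL)
  new("ComparativeRanking", table = tab, method = "none")
}

#' Aggregate the per-method ranks into a final order
#'
#' The aggregate is the geometric (or arithmetic) mean of the ranks the
#' gene received from the methods that ranked it; ties are broken by the
#' geNorm rank, then by input order. Improving one method's rank can
#' never worsen the aggregate.
#'
#' @param x a [ComparativeRanking] from [methodRankTable()].
#' @param method `"geometric_mean"` (default) or `"mean"`.
#' @return the [ComparativeRanking] with `aggregate` and `final_rank`
#'   filled in.
#' @export
aggregateRanks <- function(x, method = c("geometric_mean", "mean")) {
  method <- match.arg(method)
  tab <- x@table
  stopifnot(nrow(tab) > 0)
  ranks <- as.matrix(tab[, c("genorm", "normfinder", "bestkeeper")])
  if (any(rowSums(!is.na(ranks)) == 0))
    stop("gene(s) with no rank from any method: ",
         paste(tab$gene[rowSums(!is.na(ranks)) == 0], collapse = ", "))
  agg <- apply(ranks, 1, function(r) {
    r <- r[!is.na(r)]
    if (method == "geometric_mean") exp(mean(log(r))) else mean(r)
  })
  tab$aggregate <- agg
  ord <- order(agg, tab$genorm, seq_len(nrow(tab)))
  tab$final_rank[ord] <- seq_len(nrow(tab))
  new("ComparativeRanking", table = tab, method = method)
}

## ---- pipeline ------------------------------------------------------------

.runSet <- function(ct_set, set_name, groups, bestkeeperCap, cutoff,
                    aggregate, sdMethod) {
  wrap <- function(stage_name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s / %s] %s", set_name, stage_name, conditionMessage(e)),
         call. = FALSE))
  gn <- wrap("genorm", geNorm(ctToQuantity(ct_set), cutoff = cutoff))
  nf <- wrap("normfinder", normFinder(ct_set, groups = groups))
  bk_genes <- gn@ranking[seq_len(min(bestkeeperCap, length(gn@ranking)))]
  bk <- wrap("bestkeeper",
             bestKeeper(ct_set, genes = bk_genes, cap = bestkeeperCap,
                        sdMethod = sdMethod))
  cr <- wrap("rank", aggregateRanks(methodRankTable(gn, nf, bk),
                                    method = aggregate))
  list(genorm = gn, normfinder = nf, bestkeeper = bk, ranking = cr)
}

#' Run the full stability pipeline over the study-style sample sets
#'
#' Optionally screens candidates from an expression matrix, collapses the
#' Ct replicates, then runs geNorm, NormFinder and BestKeeper on each
#' sample set — the total set plus one set per organ and one per stage
#' (nine sets under a 3 organ x 5 stage design) — and aggregates the
#' ranks per set. The total set runs NormFinder grouped by organ (when
#' two or more organs are present); the single-organ / single-stage
#' subsets run ungrouped, their design cells holding one sample each.
#'
#' @param ct a [CtTable] (replicates are collapsed with `collapse`).
#' @param expr optional [ExpressionTable] for the screening stage.
#' @param hkGenes housekeeping genes exempted from the CV/MFC screen.
#' @param cvMax,mfcMax,minGroups screening thresholds, see
#'   [screenCandidates()].
#' @param collapse replicate collapse rule, see [collapseReplicates()].
#' @param bestkeeperCap BestKeeper gene limit; each set's BestKeeper runs
#'   on the top `bestkeeperCap` genes of that set's geNorm ranking.
#' @param cutoff geNorm V(n/n+1) cutoff.
#' @param aggregate rank aggregation rule, see [aggregateRanks()].
#' @param sdMethod BestKeeper dispersion convention.
#' @param outDir optional directory; when given, per-set rank tables, the
#'   screening report and a JSON summary are written there
#'   deterministically (identical inputs give byte-identical files).
#' @return list with elements `screening` (a [ScreeningReport] or NULL)
#'   and `sets` (named list; each entry holds `genorm`, `normfinder`,
#'   `bestkeeper`, `ranking`).
#' @export
runPipeline <- function(ct, expr = NULL, hkGenes = character(),
                        cvMax = 20.0, mfcMax = 1.50, minGroups = 1L,
                        collapse = c("mean", "median"),
                        bestkeeperCap = 10L, cutoff = 0.15,
                        aggregate = c("geometric_mean", "mean"),
                        sdMethod = c("mad", "classic"), outDir = NULL) {
  collapse <- match.arg(collapse)
  aggregate <- match.arg(aggregate)
  sdMethod <- match.arg(sdMethod)
  screening <- NULL
  if (!is.null(expr)) {
    screening <- tryCatch({
      st <- rbind(groupStats(expr, "organ"), groupStats(expr, "stage"))
      screenCandidates(st, cvMax = cvMax, mfcMax = mfcMax,
                       minGroups = minGroups, exclude = hkGenes)
    }, error = function(e)
      stop("[screening] ", conditionMessage(e), call. = FALSE))
  }
  sets <- list()
  if (!is.null(ct)) {
    ctc <- tryCatch(collapseReplicates(ct, collapse), error = function(e)
      stop("[collapse] ", conditionMessage(e), call. = FALSE))
    cd <- colData(ctc)
    organs <- unique(cd$organ)
    stages <- unique(cd$stage)
    total_groups <- if (length(organs) >= 2) "organ" else NULL
    sets$total <- .runSet(ctc, "total", total_groups, bestkeeperCap,
                          cutoff, aggregate, sdMethod)
    for (o in organs)
      sets[[o]] <- .runSet(ctc[, cd$organ == o], o, NULL, bestkeeperCap,
                           cutoff, aggregate, sdMethod)
    for (s in stages)
      sets[[s]] <- .runSet(ctc[, cd$stage == s], s, NULL, bestkeeperCap,
                           cutoff, aggregate, sdMethod)
  }
  out <- list(screening = screening, sets = sets)
  if (!is.null(outDir)) .writePipelineReports(out, outDir)
  out
}

.writeRankTSV <- function(cr, path) {
  tab <- cr@table
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%d", tab$gene, tab$genorm,
                   tab$normfinder, ifelse(is.na(tab$bestkeeper), "NA",
                                          tab$bestkeeper),
                   format(round(tab$aggregate, 6), trim = TRUE,
                          scientific = FALSE),
                   tab$final_rank)
  writeLines(c("gene\tgenorm\tnormfinder\tbestkeeper\taggregate\tfinal_rank",
               lines), con)
}

.writePipelineReports <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$screening))
    writeScreeningReport(res$screening, file.path(outDir, "screening.tsv"))
  summary <- list()
  for (nm in names(res$sets)) {
    s <- res$sets[[nm]]
    .writeRankTSV(s$ranking, file.path(outDir, paste0("ranking_", nm, ".tsv")))
    vs <- s$genorm@vSeries
    con <- file(file.path(outDir, paste0("vseries_", nm, ".tsv")), open = "wb")
    writeLines(c("n\tv", sprintf("%d\t%s", vs$n,
                                 format(round(vs$v, 6), trim = TRUE,
                                        scientific = FALSE))), con)
    close(con)
    summary[[nm]] <- list(
      stable_pair = s$genorm@stablePair,
      recommended_n = if (is.na(s$genorm@recommendedN)) "not achieved"
                      else s$genorm@recommendedN,
      top_gene = geneRanking(s$ranking)[1])
  }
  if (!is.null(res$screening))
    summary$candidates <- candidates(res$screening)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  invisible(res)
}
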