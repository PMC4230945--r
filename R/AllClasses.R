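#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats cor.test median pt quantile rnorm sd setNames var
#' @importFrom utils read.delim write.table
NULL

## ---- sample design -------------------------------------------------------

.checkDesign <- function(design) {
  need <- c("sample_id", "organ", "stage")
  miss <- setdiff(need, colnames(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (!"replicate" %in% colnames(design)) design$replicate <- 1L
  design$sample_id <- as.character(design$sample_id)
  design$organ <- as.character(design$organ)
  design$stage <- as.character(design$stage)
  design$replicate <- as.integer(design$replicate)
  if (any(design$replicate < 1L))
    stop("design replicate numbers must be >= 1")
  design
}

## ---- ExpressionTable -----------------------------------------------------

#' ExpressionTable: gene x sample abundance matrix with a sample design
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay
#' (`"abundance"`, RPKM-like units) whose columns are annotated with the
#' sample design (organ, growth stage, biological replicate).
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- assay(object, "abundance")
    if (any(is.finite(a) & a < 0))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if (!all(c("sample_id", "organ", "stage") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain sample_id, organ, stage")
  if (length(msg) > 0) msg else TRUE
})

#' Construct an ExpressionTable
#'
#' @param values numeric gene x sample matrix (non-negative, RPKM-like);
#'   rownames are gene symbols, colnames are sample ids.
#' @param design data.frame with columns `sample_id`, `organ`, `stage` and
#'   optionally `replicate`; every matrix column must appear in it.
#' @return an `ExpressionTable`.
#' @examples
#' d <- data.frame(sample_id = c("s1", "s2"), organ = "root",
#'                 stage = c("LP", "FS"))
#' m <- matrix(c(100, 110, 200, 190), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ExpressionTable(m, d)
#' @export
ExpressionTable <- function(values, design) {
  design <- .checkDesign(design)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("expression matrix needs sample ids as column names")
  missing_samples <- setdiff(colnames(values), design$sample_id)
  if (length(missing_samples) > 0)
    stop("sample(s) absent from design: ",
         paste(missing_samples, collapse = ", "))
  cd <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(cd, row.names = colnames(values)))
  new("ExpressionTable", se)
}

## ---- CtTable -------------------------------------------------------------

#' CtTable: gene x well cycle-threshold matrix with replicate structure
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assay `"ct"`
#' (cycles; `NA` marks missing wells), columns identifying wells as
#' (sample, technical replicate) pairs, and a per-gene amplification
#' efficiency in `rowData(x)$efficiency` (per-cycle amplification factor,
#' 2.0 = perfect doubling).
#'
#' @export
setClass("CtTable", contains = "SummarizedExperiment")

setValidity("CtTable", function(object) {
  msg <- character()
  if (!"ct" %in% assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  else {
    ct <- assay(object, "ct")
    bad <- which(!is.na(ct) & (ct <= 0 | ct >= 50), arr.ind = TRUE)
    if (nrow(bad) > 0)
      msg <- c(msg, sprintf(
        "Ct outside (0, 50) at gene '%s', well '%s'",
        rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]))
  }
  if (!"efficiency" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain per-gene 'efficiency'")
  else {
    e <- rowData(object)$efficiency
    if (any(!is.finite(e) | e <= 1 | e > 2.2))
      msg <- c(msg, "efficiency must lie in (1, 2.2]")
  }
  if (!all(c("sample_id", "replicate", "organ", "stage") %in%
             colnames(colData(object))))
    msg <- c(msg, "colData must contain sample_id, replicate, organ, stage")
  else if (anyDuplicated(paste(colData(object)$sample_id,
                               colData(object)$replicate)))
    msg <- c(msg, "duplicate (sample, replicate) wells")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if (length(msg) > 0) msg else TRUE
})

#' Construct a CtTable
#'
#' @param ct numeric gene x well matrix of Ct values (cycles); columns are
#'   wells named `"<sample_id>.<replicate>"`, or plain sample ids when there
#'   is a single replicate. `NA` marks missing wells.
#' @param design sample design data.frame (`sample_id`, `organ`, `stage`).
#' @param efficiency per-gene amplification factor in (1, 2.2]; a single
#'   number is recycled. Default 2.0 (perfect doubling).
#' @return a `CtTable`.
#' @export
CtTable <- function(ct, design, efficiency = 2.0) {
  design <- .checkDesign(design)
  ct <- as.matrix(ct)
  if (is.null(colnames(ct))) stop("Ct matrix needs well ids as column names")
  well <- .parseWellIds(colnames(ct))
  missing_samples <- setdiff(well$sample_id, design$sample_id)
  if (length(missing_samples) > 0)
    stop("sample(s) absent from design: ",
         paste(missing_samples, collapse = ", "))
  idx <- match(well$sample_id, design$sample_id)
  cd <- DataFrame(sample_id = well$sample_id,
                  replicate = well$replicate,
                  organ = design$organ[idx],
                  stage = design$stage[idx],
                  row.names = colnames(ct))
  if (length(efficiency) == 1) efficiency <- rep(efficiency, nrow(ct))
  if (length(efficiency) != nrow(ct))
    stop("efficiency must have one value per gene")
  se <- SummarizedExperiment(
    assays = list(ct = ct),
    colData = cd,
    rowData = DataFrame(efficiency = as.numeric(efficiency),
                        row.names = rownames(ct)))
  new("CtTable", se)
}

# split "sample.rep" well ids; bare ids become replicate 1
.parseWellIds <- function(ids) {
  has_rep <- grepl("\\.[0-9]+$", ids)
  sample_id <- ifelse(has_rep, sub("\\.[0-9]+$", "", ids), ids)
  replicate <- ifelse(has_rep, as.integer(sub("^.*\\.", "", ids)), 1L)
  list(sample_id = sample_id, replicate = as.integer(replicate))
}

## ---- simple result containers -------------------------------------------

#' Relative-quantity matrix for geNorm analysis
#'
#' Gene x sample matrix of relative quantities
#' `Q[g, s] = E_g ^ (minCt_g - Ct[g, s])`, so each gene's maximum (its
#' lowest-Ct sample) is exactly 1.
#'
#' @slot q numeric matrix in (0, 1].
#' @slot efficiency named numeric; the per-gene amplification factor used.
#' @export
setClass("QuantityMatrix",
         representation(q = "matrix", efficiency = "numeric"))

setValidity("QuantityMatrix", function(object) {
  q <- object@q
  if (any(q <= 0 | q > 1 + 1e-12))
    return("relative quantities must lie in (0, 1]")
  if (any(abs(apply(q, 1, max) - 1) > 1e-9))
    return("each gene must have at least one quantity equal to 1")
  TRUE
})

#' Candidate screening report
#'
#' Per-(gene, group) descriptive statistics with threshold decisions and the
#' resulting candidate set.
#'
#' @slot stats data.frame: gene, group, mean, sd, cv_pct, mfc, pass.
#' @slot candidates character; genes passing thresholds in enough groups.
#' @slot thresholds list: cv_max, mfc_max, min_groups, rounding_dp.
#' @slot excluded character; genes exempted from screening (e.g. the
#'   classical housekeeping panel carried forward regardless).
#' @export
setClass("ScreeningReport",
         representation(stats = "data.frame", candidates = "character",
                        thresholds = "list", excluded = "character"))

#' geNorm stability analysis result
#'
#' @slot stability named numeric; each gene's M value at the round of its
#'   elimination (the two final genes share their pair M).
#' @slot ranking character; genes from most to least stable (the first two
#'   form the most stable pair and share rank 1).
#' @slot exclusionOrder character; genes in the order they were removed.
#' @slot stablePair character(2).
#' @slot vSeries data.frame: n, v — pairwise variation V(n/n+1).
#' @slot recommendedN integer; smallest n with V < cutoff (NA when the
#'   cutoff is never reached).
#' @slot cutoff numeric.
#' @export
setClass("GenormResult",
         representation(stability = "numeric", ranking = "character",
                        exclusionOrder = "character", stablePair = "character",
                        vSeries = "data.frame", recommendedN = "integer",
                        cutoff = "numeric"))

#' NormFinder-style stability analysis result
#'
#' @slot mode "grouped" or "ungrouped".
#' @slot stability named numeric; per-gene stability value (log2 units,
#'   lower = more stable).
#' @slot ranking character, ascending stability.
#' @slot gamma2 gene x group matrix of intra-group variance estimates.
#' @slot dHat gene x group matrix of inter-group differences (zero-sum per
#'   gene); empty in ungrouped mode.
#' @slot dTilde shrunken version of `dHat`.
#' @slot groupSizes named integer.
#' @export
setClass("NormfinderResult",
         representation(mode = "character", stability = "numeric",
                        ranking = "character", gamma2 = "matrix",
                        dHat = "matrix", dTilde = "matrix",
                        groupSizes = "integer"))

#' BestKeeper-style stability analysis result
#'
#' @slot stats data.frame: gene, geo_mean, ar_mean, min, max, sd, cv_pct,
#'   r, p, rank (rank by CV then SD).
#' @slot index named numeric; per-sample geometric-mean Ct index.
#' @slot sdMethod "mad" (mean absolute deviation, the BestKeeper
#'   convention) or "classic" (n-1 standard deviation).
#' @export
setClass("BestkeeperResult",
         representation(stats = "data.frame", index = "numeric",
                        sdMethod = "character"))

#' Side-by-side method ranking with aggregate order
#'
#' @slot table data.frame: gene, genorm, normfinder, bestkeeper (NA when a
#'   gene was outside BestKeeper's capped input), aggregate, final_rank.
#' @slot method aggregation rule used.
#' @export
setClass("ComparativeRanking",
         representation(table = "data.frame", method = "character"))

#' Planted simulation truth
#'
#' Ground-truth parameters for the synthetic-data generator: per-gene
#' baselines and log2-scale residual SDs, organ/stage effects, sample and
#' replicate noise, amplification efficiency, and the factorial design.
#'
#' @slot genes character.
#' @slot baselineExpr named numeric; RPKM-like baseline abundance.
#' @slot baselineCt named numeric; baseline cycle threshold.
#' @slot log2SD named numeric; per-gene residual SD on the log2 scale.
#' @slot organEffects gene x organ matrix of log2 offsets.
#' @slot stageEffects gene x stage matrix of log2 offsets.
#' @slot sampleSD numeric; SD of the shared per-sample effect (log2).
#' @slot repSD numeric; technical replicate SD on the Ct scale (cycles).
#' @slot efficiency named numeric in (1, 2.2].
#' @slot organs,stages character; design levels.
#' @slot replicates integer; technical replicates per sample.
#' @slot seed integer; default RNG seed for the simulators.
#' @export
setClass("SimTruth",
         representation(genes = "character", baselineExpr = "numeric",
                        baselineCt = "numeric", log2SD = "numeric",
                        organEffects = "matrix", stageEffects = "matrix",
                        sampleSD = "numeric", repSD = "numeric",
                        efficiency = "numeric", organs = "character",
                        stages = "character", replicates = "integer",
                        seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character()
  g <- object@genes
  if (length(g) == 0 || anyDuplicated(g)) msg <- c(msg, "genes must be unique, nonempty")
  for (sl in c("baselineExpr", "baselineCt", "log2SD", "efficiency"))
    if (length(slot(object, sl)) != length(g))
      msg <- c(msg, sprintf("%s must have one value per gene", sl))
  if (any(object@log2SD < 0)) msg <- c(msg, "log2SD must be >= 0")
  if (object@sampleSD < 0 || object@repSD < 0)
    msg <- c(msg, "sampleSD and repSD must be >= 0")
  if (any(object@efficiency <= 1 | object@efficiency > 2.2))
    msg <- c(msg, "efficiency must lie in (1, 2.2]")
  if (!identical(dim(object@organEffects),
                 c(length(g), length(object@organs))))
    msg <- c(msg, "organEffects must be gene x organ")
  if (!identical(dim(object@stageEffects),
                 c(length(g), length(object@stages))))
    msg <- c(msg, "stageEffects must be gene x stage")
  if (length(object@organs) == 0 || length(object@stages) == 0 ||
      object@replicates < 1)
    msg <- c(msg, "design must be nonempty")
  if (length(msg) > 0) msg else TRUE
})
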