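## Synthetic expression / Ct data with planted stability structure. Noise
## is Gaussian on the log2 scale (equivalently on the Ct scale), the
## standard qPCR error model; organ and stage effects are additive log2
## offsets, so the generating truth defines an unambiguous expected
## stability order for recovery tests.

#' Construct a SimTruth (planted simulation parameters)
#'
#' @param genes gene symbols.
#' @param baselineExpr per-gene RPKM-like baseline abundance.
#' @param baselineCt per-gene baseline cycle threshold; default derived
#'   from the abundance baseline (`34 - 1.7 * log2(baselineExpr)`, placing
#'   typical genes in the 19-24 cycle range).
#' @param log2SD per-gene residual SD on the log2 scale (a single value is
#'   recycled).
#' @param organEffects,stageEffects gene x level matrices of log2 offsets
#'   (default all zero).
#' @param sampleSD SD of the shared per-sample effect (log2), default 0.05.
#' @param repSD technical replicate SD in cycles, default 0.15.
#' @param efficiency per-gene amplification factor, default 2.0.
#' @param organs,stages design levels; defaults mirror a 3 organ x
#'   5 stage factorial.
#' @param replicates technical replicates per sample, default 3.
#' @param seed default RNG seed used by the simulators.
#' @return a [SimTruth].
#' @export
simTruth <- function(genes, baselineExpr = 150, baselineCt = NULL,
                     log2SD = 0.1, organEffects = NULL, stageEffects = NULL,
                     sampleSD = 0.05, repSD = 0.15, efficiency = 2.0,
                     organs = c("root", "stem", "leaf"),
                     stages = c("LP", "FS", "GFS", "RFS", "RGS"),
                     replicates = 3L, seed = 1L) {
  G <- length(genes)
  rec <- function(x) setNames(rep_len(x, G), genes)
  baselineExpr <- rec(baselineExpr)
  if (is.null(baselineCt)) baselineCt <- 34 - 1.7 * log2(baselineExpr)
  baselineCt <- rec(baselineCt)
  zeros <- function(lev) matrix(0, G, length(lev),
                                dimnames = list(genes, lev))
  if (is.null(organEffects)) organEffects <- zeros(organs)
  if (is.null(stageEffects)) stageEffects <- zeros(stages)
  new("SimTruth", genes = genes, baselineExpr = baselineExpr,
      baselineCt = baselineCt, log2SD = rec(log2SD),
      organEffects = organEffects, stageEffects = stageEffects,
      sampleSD = sampleSD, repSD = repSD, efficiency = rec(efficiency),
      organs = organs, stages = stages,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Default study-style simulation truth
#'
#' A 20-gene panel (10 classical housekeeping genes, 10 low-variance novel
#' candidates) over 3 organs x 5 growth stages x 3 technical replicates,
#' emulating the structure of the original screening design: housekeeping
#' genes get larger residual SDs and organ/stage offsets, the ribosomal
#' RNA gene an abundance baseline in the thousands (so the 50-500
#' expression window excludes it), and the novel candidates stay within
#' the window with log2 SDs of 0.08-0.15.
#'
#' @param seed default RNG seed carried by the truth object.
#' @return a [SimTruth].
#' @export
defaultSimTruth <- function(seed = 1L) {
  hk <- c("ACT1", "GAPDH", "18S rRNA", "UBQ", "bTUB", "aTUB", "CYP",
          "eIF-5A", "F-box", "EF-1a")
  novel <- c("CDP", "6-PG", "30S RPS20", "60S RPL13", "V-ATP", "pol IIa",
             "ARF", "QCR", "SAR1", "TCTP")
  genes <- c(hk, novel)
  baseline <- c(230, 420, 2300, 350, 140, 220, 105, 430, 95, 370,
                140, 105, 105, 160, 160, 130, 105, 145, 130, 190)
  gamma <- c(0.45, 0.35, 0.90, 0.50, 0.60, 0.30, 0.40, 0.30, 0.55, 0.40,
             0.08, 0.15, 0.12, 0.10, 0.14, 0.12, 0.15, 0.12, 0.15, 0.10)
  tr <- simTruth(genes, baselineExpr = baseline, log2SD = gamma, seed = seed)
  # modest systematic organ/stage shifts for the housekeeping panel,
  # proportional to each gene's residual SD; novel candidates get none
  ge <- gamma[seq_along(hk)]
  tr@organEffects[hk, ] <- outer(ge, c(0, 0.3, -0.3))
  tr@stageEffects[hk, ] <- outer(ge, c(0, 0.2, -0.2, 0.3, -0.3)) * 0.5
  validObject(tr)
  tr
}

.designGrid <- function(truth) {
  g <- expand.grid(stage = truth@stages, organ = truth@organs,
                   stringsAsFactors = FALSE)[, c("organ", "stage")]
  g$sample_id <- paste(g$organ, g$stage, sep = "_")
  g$replicate <- 1L
  g
}

# per-(gene, sample) log2 deviation from baseline: fixed offsets + shared
# sample effect + gene residual
.log2Deviations <- function(truth, grid) {
  G <- length(truth@genes)
  S <- nrow(grid)
  off <- truth@organEffects[, grid$organ, drop = FALSE] +
    truth@stageEffects[, grid$stage, drop = FALSE]
  samp <- rnorm(S, 0, truth@sampleSD)
  resid <- matrix(rnorm(G * S, 0, truth@log2SD), G, S)
  dev <- off + rep(samp, each = G) + resid
  dimnames(dev) <- list(truth@genes, grid$sample_id)
  dev
}

#' Simulate an RPKM-like expression table from a SimTruth
#'
#' `value[g, s] = baseline_g * 2^(organ/stage offsets + sample effect +
#' N(0, log2SD_g))`; reproducible for a given seed.
#'
#' @param truth a [SimTruth].
#' @param seed RNG seed (default: the truth's own seed).
#' @return an [ExpressionTable].
#' @export
simulateExpression <- function(truth, seed = truth@seed) {
  set.seed(seed)
  grid <- .designGrid(truth)
  dev <- .log2Deviations(truth, grid)
  values <- truth@baselineExpr * 2^dev
  ExpressionTable(values, grid)
}

#' Simulate a replicate Ct table from a SimTruth
#'
#' `Ct[g, s, rep] = baselineCt_g - (organ/stage offsets + sample effect +
#' N(0, log2SD_g)) + N(0, repSD)`; the biological deviation is shared by
#' a sample's technical replicates, the last term is per well.
#'
#' @param truth a [SimTruth].
#' @param seed RNG seed (default: the truth's own seed).
#' @param tailProb probability that a well's technical noise comes from a
#'   5x-inflated SD (heavy-tail contamination for robustness tests);
#'   default 0.
#' @return a [CtTable] with `replicates` wells per sample.
#' @export
simulateCt <- function(truth, seed = truth@seed, tailProb = 0) {
  set.seed(seed)
  grid <- .designGrid(truth)
  dev <- .log2Deviations(truth, grid)
  G <- length(truth@genes)
  S <- nrow(grid)
  R <- truth@replicates
  ct <- matrix(NA_real_, G, S * R)
  wells <- character(S * R)
  for (r in seq_len(R)) {
    cols <- (r - 1) * S + seq_len(S)
    noise_sd <- matrix(truth@repSD, G, S)
    if (tailProb > 0) {
      heavy <- matrix(stats::runif(G * S) < tailProb, G, S)
      noise_sd[heavy] <- truth@repSD * 5
    }
    tech <- matrix(rnorm(G * S, 0, noise_sd), G, S)
    ct[, cols] <- truth@baselineCt - dev + tech
    wells[cols] <- paste(grid$sample_id, r, sep = ".")
  }
  ord <- order(rep(seq_len(S), R), rep(seq_len(R), each = S))
  ct <- ct[, ord, drop = FALSE]
  dimnames(ct) <- list(truth@genes, wells[ord])
  CtTable(ct, grid, efficiency = truth@efficiency)
}

#' Expected stability order implied by a SimTruth
#'
#' Total planted instability per gene is the residual variance
#' `log2SD^2` plus the population variance of the summed organ + stage
#' offsets across the design cells; genes are ranked ascending.
#' Parameter-identical genes tie (minimum rank).
#'
#' @param truth a [SimTruth].
#' @param grouped include the planted group offsets (default TRUE); with
#'   `FALSE` only the residual SDs order the genes.
#' @return data.frame: gene, instability, rank (ties share the minimum
#'   rank).
#' @export
truthRanking <- function(truth, grouped = TRUE) {
  grid <- .designGrid(truth)
  off <- truth@organEffects[, grid$organ, drop = FALSE] +
    truth@stageEffects[, grid$stage, drop = FALSE]
  offvar <- apply(off, 1, function(x) mean((x - mean(x))^2))
  inst <- truth@log2SD^2 + if (grouped) offvar else 0
  data.frame(gene = truth@genes, instability = unname(inst),
             rank = rank(inst, ties.method = "min"), row.names = NULL)
}
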