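## NormFinder-style model-based stability. Expression on a log2 scale is
## decomposed, after centering each sample across genes, into inter-group
## differences and intra-group variances; the stability value combines the
## (shrunken) absolute inter-group difference with the intra-group standard
## error. Lower = more stable.
##
## Because the per-sample centering mixes every gene's noise into every
## centered value, the naive within-group variance of a centered row is
## biased; the estimator below inverts that bias exactly:
##   E[v_ig] = gamma2_ig (1 - 2/n) + (1/n^2) sum_k gamma2_kg
## giving the closed-form correction implemented in intragroupVariances().

#' Center a log-scale matrix per sample
#'
#' Subtracts from each column its mean over genes, so every column of the
#' result sums to zero. Needs at least 3 genes (the centering-bias
#' correction downstream is undefined at n = 2).
#'
#' @param y numeric gene x sample matrix on a log2 scale (e.g. `-Ct`).
#' @return centered matrix of the same shape.
#' @export
sampleCenter <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 3) stop("need at least 3 genes")
  if (anyNA(y)) stop("matrix must be complete")
  sweep(y, 2, colMeans(y))
}

.groupFactor <- function(groups, n_samples) {
  f <- as.factor(groups)
  if (length(f) != n_samples)
    stop("groups must assign every sample to a group")
  f
}

#' Bias-corrected intra-group variance estimates
#'
#' With `v_ig` the sample variance of gene i's centered values within
#' group g, the estimate is
#' `gamma2_ig = max(0, (v_ig - sum_k v_kg / (n (n - 1))) / (1 - 2/n))`
#' with n the number of genes; unbiased for the generating model before
#' the flooring at zero.
#'
#' @param z centered matrix from [sampleCenter()].
#' @param groups group label per sample (each group needs >= 2 samples).
#' @param floor floor the estimates at zero (default TRUE). The corrected
#'   estimator is unbiased only before flooring; set `FALSE` when studying
#'   its sampling behaviour.
#' @return gene x group matrix of variance estimates (log2^2 units), with
#'   attribute `"n_floored"` counting the cells clipped at zero.
#' @export
intragroupVariances <- function(z, groups, floor = TRUE) {
  n <- nrow(z)
  if (n < 3) stop("need at least 3 genes (correction denominator 1 - 2/n)")
  f <- .groupFactor(groups, ncol(z))
  out <- vapply(levels(f), function(g) {
    cols <- which(f == g)
    if (length(cols) < 2)
      stop(sprintf("group '%s' has fewer than 2 samples", g))
    v <- apply(z[, cols, drop = FALSE], 1, var)
    (v - sum(v) / (n * (n - 1))) / (1 - 2 / n)
  }, numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(rownames(z), levels(f)))
  if (floor) {
    n_floored <- sum(out < 0)
    out <- pmax(out, 0)
    attr(out, "n_floored") <- n_floored
  }
  out
}

#' Inter-group differences with variance shrinkage
#'
#' `d_ig` is gene i's group-g mean of centered values minus the mean of
#' its group means (zero-sum across groups per gene). The shrunken
#' `d~_ig = d_ig * tau2_i / (tau2_i + gamma2_ig / K_g)` pulls noisy
#' differences toward zero, with `tau2_i` the (floored) excess variance of
#' the observed d's over their sampling noise.
#'
#' @param z centered matrix from [sampleCenter()].
#' @param groups group label per sample; at least 2 groups.
#' @param gamma2 optional precomputed result of [intragroupVariances()].
#' @return list: `d_hat`, `d_tilde` (gene x group), `tau2` (per gene).
#' @export
intergroupVariation <- function(z, groups, gamma2 = NULL) {
  f <- .groupFactor(groups, ncol(z))
  if (nlevels(f) < 2) stop("need at least 2 groups (use ungrouped mode)")
  if (is.null(gamma2)) gamma2 <- intragroupVariances(z, f)
  attr(gamma2, "n_floored") <- NULL
  K <- table(f)
  gm <- vapply(levels(f), function(g)
    rowMeans(z[, f == g, drop = FALSE]), numeric(nrow(z)))
  gm <- matrix(gm, nrow = nrow(z), dimnames = list(rownames(z), levels(f)))
  d_hat <- gm - rowMeans(gm)
  noise <- sweep(gamma2, 2, as.numeric(K[colnames(gamma2)]), "/")
  tau2 <- pmax(0, apply(d_hat, 1, var) - rowMeans(noise))
  shrink <- tau2 / (tau2 + noise)
  shrink[tau2 == 0, ] <- 0
  list(d_hat = d_hat, d_tilde = d_hat * shrink, tau2 = tau2)
}

#' NormFinder-style stability values
#'
#' Grouped mode: `rho_i` is the mean over groups of
#' `|d~_ig| + sqrt(gamma2_ig / K_g)` — shrunken inter-group difference
#' plus intra-group standard error. Ungrouped mode treats all samples as
#' one group and reports `rho_i = sqrt(gamma2_i)`. Ranking is ascending
#' in `rho` (most stable first).
#'
#' @param x a collapsed [CtTable], or a numeric gene x sample matrix
#'   already on a log2 scale.
#' @param groups `NULL` for ungrouped mode; for a `CtTable` the name of a
#'   design column (`"organ"` or `"stage"`), for a matrix a vector of
#'   group labels per sample.
#' @param input for a `CtTable`: `"negct"` (default; y = -Ct, exact when
#'   all efficiencies are 2) or `"log2q"` (efficiency-corrected,
#'   y = log2 of the relative quantities).
#' @return a [NormfinderResult].
#' @export
normFinder <- function(x, groups = NULL, input = c("negct", "log2q")) {
  input <- match.arg(input)
  if (is(x, "CtTable")) {
    cd <- colData(x)
    if (anyDuplicated(cd$sample_id))
      stop("collapse technical replicates first (collapseReplicates)")
    if (!is.null(groups)) {
      if (!(is.character(groups) && length(groups) == 1 &&
            groups %in% colnames(cd)))
        stop("groups must name a design column of the CtTable")
      groups <- cd[[groups]]
    }
    y <- if (input == "negct") {
      m <- -assay(x, "ct"); colnames(m) <- cd$sample_id; m
    } else {
      log2(quantities(ctToQuantity(x)))
    }
  } else {
    y <- as.matrix(x)
  }
  if (anyNA(y)) stop("matrix must be complete")
  z <- sampleCenter(y)
  if (is.null(groups)) {
    gamma2 <- intragroupVariances(z, rep("all", ncol(z)))
    rho <- sqrt(gamma2[, 1])
    res <- new("NormfinderResult", mode = "ungrouped",
               stability = rho,
               ranking = names(rho)[order(rho, seq_along(rho))],
               gamma2 = gamma2,
               dHat = matrix(numeric(0), 0, 0),
               dTilde = matrix(numeric(0), 0, 0),
               groupSizes = setNames(as.integer(ncol(z)), "all"))
    return(res)
  }
  f <- .groupFactor(groups, ncol(z))
  gamma2 <- intragroupVariances(z, f)
  ig <- intergroupVariation(z, f, gamma2)
  K <- table(f)
  se <- sqrt(sweep(gamma2, 2, as.numeric(K[colnames(gamma2)]), "/"))
  rho <- rowMeans(abs(ig$d_tilde) + se)
  new("NormfinderResult", mode = "grouped", stability = rho,
      ranking = names(rho)[order(rho, seq_along(rho))], gamma2 = gamma2,
      dHat = ig$d_hat, dTilde = ig$d_tilde,
      groupSizes = setNames(as.integer(K), names(K)))
}
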