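# Small builders and independent brute-force oracles used across the suite.
# The oracles recompute every quantity directly from its definition with
# plain loops, sharing no code with the package internals.

tiny_design <- function(n, organ = "root", stage = "LP") {
  data.frame(sample_id = paste0("s", seq_len(n)),
             organ = rep_len(organ, n), stage = rep_len(stage, n),
             replicate = 1L)
}

# CtTable from a plain gene x sample matrix (one well per sample)
make_ct <- function(m, design = NULL, efficiency = 2) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(design)) design <- tiny_design(ncol(m))
  design$sample_id <- colnames(m)
  CtTable(m, design, efficiency = efficiency)
}

# QuantityMatrix encoding the per-gene ratios of a positive matrix
# (each row rescaled to max 1, as the Ct transform would produce)
make_q <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  ctToQuantity(make_ct(25 - log2(m)))
}

# --- brute-force oracles ---------------------------------------------------

oracle_sd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1))
}

# mean pairwise log-ratio SD of each active gene
oracle_m_values <- function(Q, active = rownames(Q)) {
  out <- numeric(length(active))
  names(out) <- active
  for (j in active) {
    acc <- 0
    for (k in setdiff(active, j))
      acc <- acc + oracle_sd(log2(Q[j, ] / Q[k, ]))
    out[j] <- acc / (length(active) - 1)
  }
  out
}

# geometric-mean normalization factor over a gene set
oracle_nf <- function(Q, genes) {
  genes <- unique(genes)
  out <- numeric(ncol(Q))
  for (s in seq_len(ncol(Q)))
    out[s] <- prod(Q[genes, s])^(1 / length(genes))
  out
}

# V(n/n+1) series for a given stability ranking
oracle_v_series <- function(Q, ranking) {
  G <- length(ranking)
  v <- numeric(G - 2)
  for (n in 2:(G - 1)) {
    nf1 <- oracle_nf(Q, ranking[1:n])
    nf2 <- oracle_nf(Q, ranking[1:(n + 1)])
    v[n - 1] <- oracle_sd(log2(nf1 / nf2))
  }
  v
}

# full stepwise exclusion by repeated worst-M removal (ties: later input
# order removed first), independent of the package implementation
oracle_stepwise <- function(Q) {
  genes <- rownames(Q)
  active <- genes
  excluded <- character(0)
  while (length(active) > 2) {
    M <- oracle_m_values(Q, active)
    worst <- max(M)
    cand <- active[abs(M - worst) <= 1e-15]
    drop <- cand[length(cand)]  # active keeps input order
    excluded <- c(excluded, drop)
    active <- setdiff(active, drop)
  }
  list(excluded = excluded, pair = active)
}

oracle_cv_mfc <- function(x) {
  mu <- sum(x) / length(x)
  c(cv = 100 * oracle_sd(x) / mu, mfc = max(x) / min(x))
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

study_hk_genes <- c("ACT1", "GAPDH", "18S rRNA", "UBQ", "bTUB", "aTUB",
                    "CYP", "eIF-5A", "F-box", "EF-1a")
study_novel_genes <- c("CDP", "6-PG", "30S RPS20", "60S RPL13", "V-ATP",
                       "pol IIa", "ARF", "QCR", "SAR1", "TCTP")
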