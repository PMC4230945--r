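## Reading, writing and replicate handling for the expression / Ct tables.
## Wide matrices are TSV or CSV: first column the gene symbol, header row the
## sample (or well) ids. Missing Ct is an empty field or "NA", never 0/40.

.readMatrixFile <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) stop("no genes in '", path, "'")
  if (ncol(df) < 2) stop("no sample columns in '", path, "'")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicate gene symbol(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "),
         " (first at row ", which(duplicated(genes))[1] + 1L, ")")
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(genes, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- trimws(vals[[j]])
    x[x == ""] <- NA
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num) & x != "NA")
    if (length(bad) > 0)
      stop(sprintf("non-numeric value '%s' in '%s' at row %d (gene '%s'), column '%s'",
                   x[bad[1]], path, bad[1] + 1L, genes[bad[1]],
                   colnames(vals)[j]))
    m[, j] <- num
  }
  m
}

.readDesignFile <- function(path) {
  design <- read.delim(path, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE)
  .checkDesign(design)
}

#' Read an expression matrix and its sample design
#'
#' @param matrix_path TSV/CSV file: first column gene symbols, header row
#'   sample ids, cells RPKM-like abundances.
#' @param design_path TSV file with columns `sample_id`, `organ`, `stage`
#'   and optionally `replicate`.
#' @return an [ExpressionTable].
#' @seealso [readCtTable()], [writeExpressionTable()]
#' @export
readExpressionTable <- function(matrix_path, design_path) {
  m <- .readMatrixFile(matrix_path)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing abundance at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  ExpressionTable(m, .readDesignFile(design_path))
}

#' Read a Ct table (wide or long layout) and its sample design
#'
#' Wide layout: first column gene, remaining columns wells named
#' `"<sample_id>.<replicate>"`. Long layout: columns `gene`, `sample_id`,
#' `replicate`, `ct`. Missing Ct is an empty cell or `NA`; values outside
#' (0, 50) are rejected with their coordinates.
#'
#' @param matrix_path Ct file as above (TSV or CSV).
#' @param design_path sample design TSV.
#' @param efficiency_path optional TSV with columns `gene`, `efficiency`;
#'   genes not listed get the default per-cycle amplification factor 2.0.
#' @return a [CtTable].
#' @export
readCtTable <- function(matrix_path, design_path, efficiency_path = NULL) {
  first <- readLines(matrix_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- tolower(trimws(strsplit(first, sep, fixed = TRUE)[[1]]))
  design <- .readDesignFile(design_path)
  if (all(c("gene", "ct") %in% header)) {
    long <- read.delim(matrix_path, sep = sep, check.names = FALSE,
                       stringsAsFactors = FALSE)
    colnames(long) <- tolower(colnames(long))
    if (!"sample_id" %in% colnames(long) && "sample" %in% colnames(long))
      colnames(long)[colnames(long) == "sample"] <- "sample_id"
    if (!"replicate" %in% colnames(long)) long$replicate <- 1L
    key <- paste(long$gene, long$sample_id, long$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      d <- long[duplicated(key), ][1, ]
      stop(sprintf("duplicate well: gene '%s', sample '%s', replicate %s",
                   d$gene, d$sample_id, format(d$replicate)))
    }
    genes <- unique(long$gene)
    wells <- unique(paste(long$sample_id, long$replicate, sep = "."))
    m <- matrix(NA_real_, length(genes), length(wells),
                dimnames = list(genes, wells))
    m[cbind(match(long$gene, genes),
            match(paste(long$sample_id, long$replicate, sep = "."), wells))] <-
      long$ct
  } else {
    m <- .readMatrixFile(matrix_path)
  }
  bad <- which(!is.na(m) & (m <= 0 | m >= 50), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("Ct value %.3g outside (0, 50) at gene '%s', well '%s'",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]]))
  eff <- rep(2.0, nrow(m))
  names(eff) <- rownames(m)
  if (!is.null(efficiency_path)) {
    et <- read.delim(efficiency_path, sep = "\t", stringsAsFactors = FALSE)
    unknown <- setdiff(et$gene, rownames(m))
    if (length(unknown) > 0)
      stop("efficiency file names unknown gene(s): ",
           paste(unknown, collapse = ", "))
    eff[et$gene] <- et$efficiency
  }
  CtTable(m, design, efficiency = eff)
}

#' Write an ExpressionTable (matrix + design) to TSV
#'
#' @param x an [ExpressionTable].
#' @param matrix_path,design_path output paths; `design_path = NULL` skips
#'   the design file.
#' @return `invisible(x)`.
#' @export
writeExpressionTable <- function(x, matrix_path, design_path = NULL) {
  .writeMatrixTSV(assay(x, "abundance"), "gene", matrix_path)
  if (!is.null(design_path)) .writeDesignTSV(designTable(x), design_path)
  invisible(x)
}

#' Write a CtTable (matrix + design, optionally efficiencies) to TSV
#'
#' @param x a [CtTable].
#' @param matrix_path,design_path,efficiency_path output paths; the design
#'   and efficiency files are skipped when `NULL`.
#' @return `invisible(x)`.
#' @export
writeCtTable <- function(x, matrix_path, design_path = NULL,
                         efficiency_path = NULL) {
  .writeMatrixTSV(assay(x, "ct"), "gene", matrix_path)
  if (!is.null(design_path)) {
    d <- unique(designTable(x)[, c("sample_id", "organ", "stage")])
    d$replicate <- 1L
    .writeDesignTSV(d, design_path)
  }
  if (!is.null(efficiency_path)) {
    e <- data.frame(gene = rownames(x), efficiency = efficiencies(x))
    con <- file(efficiency_path, open = "wb")
    on.exit(close(con))
    writeLines(c("gene\tefficiency",
                 sprintf("%s\t%s", e$gene, format(e$efficiency, digits = 15))),
               con)
  }
  invisible(x)
}

.writeMatrixTSV <- function(m, id_col, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- vapply(seq_len(nrow(m)), function(i) {
    vals <- ifelse(is.na(m[i, ]), "NA", format(m[i, ], digits = 15,
                                               trim = TRUE, scientific = FALSE))
    paste(c(rownames(m)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c(id_col, colnames(m)), collapse = "\t"), body), con)
}

.writeDesignTSV <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\torgan\tstage\treplicate",
               sprintf("%s\t%s\t%s\t%d", d$sample_id, d$organ, d$stage,
                       d$replicate)), con)
}

#' Collapse technical replicates of a CtTable
#'
#' One Ct per (gene, sample); cells whose replicates are all missing stay
#' missing. Collapsing an already collapsed table is the identity.
#'
#' @param ct a [CtTable].
#' @param method `"mean"` (default, arithmetic mean of Ct) or `"median"`.
#' @return a [CtTable] with one well per sample (replicate 1).
#' @export
collapseReplicates <- function(ct, method = c("mean", "median")) {
  method <- match.arg(method)
  fun <- if (method == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  }
  cd <- colData(ct)
  samples <- unique(cd$sample_id)
  m <- assay(ct, "ct")
  out <- vapply(samples, function(s) {
    cols <- which(cd$sample_id == s)
    apply(m[, cols, drop = FALSE], 1, fun)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), samples))
  d <- unique(as.data.frame(cd)[, c("sample_id", "organ", "stage")])
  d$replicate <- 1L
  CtTable(out, d, efficiency = efficiencies(ct))
}
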