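#' Wilcoxon rank-sum differential expression between ROIs
#'
#' For every gene, compares normalized expression between ROI1 and ROI2
#' spots with a two-sided Wilcoxon rank-sum test using the normal
#' approximation with tie correction and no continuity correction, the
#' convention of the standard single-cell gene-ranking implementations.
#' P-values are Benjamini-Hochberg adjusted over all tested genes.
#'
#' The fold change is computed on the de-logged scale:
#' \deqn{logFC = \log_2\frac{\mathrm{mean}_{ROI1}(e^{x}-1) + \epsilon}
#'                          {\mathrm{mean}_{ROI2}(e^{x}-1) + \epsilon}}
#' with pseudocount \eqn{\epsilon} (default 1e-9); positive values are up
#' in ROI1. A gene with no signal in either group gets p = 1 and
#' logFC = 0.
#'
#' @param ds a \code{stroi_dataset} with a normalized matrix, or a plain
#'   spots x genes matrix of normalized expression.
#' @param labels a labeled \code{\link{build_roi}} assignment, or a
#'   character/factor vector with values \code{"ROI1"}/\code{"ROI2"} (other
#'   values ignored).
#' @param pseudocount added to both group means before the log ratio.
#' @return A \code{stroi_deg} data.frame: gene, log_fc, p_value, p_adj,
#'   mean_roi1, mean_roi2, group (all \code{"ns"} until
#'   \code{\link{classify_degs}}).
#' @export
wilcoxon_deg <- function(ds, labels, pseudocount = 1e-9) {
  if (inherits(ds, "stroi_dataset")) {
    if (is.null(ds$normalized))
      stopf("dataset has no normalized matrix; run lognormalize first")
    X <- ds$normalized
    genes <- ds$gene_ids
  } else {
    X <- ds
    genes <- colnames(X) %||% paste0("gene", seq_len(ncol(X)))
  }
  lab <- if (inherits(labels, "stroi_assignment")) as.character(labels$label)
         else as.character(labels)
  i1 <- which(lab == "ROI1"); i2 <- which(lab == "ROI2")
  if (length(i1) < 2 || length(i2) < 2)
    stopf("each ROI needs at least 2 spots (ROI1: %d, ROI2: %d)",
          length(i1), length(i2))

  x1 <- as.matrix(X[i1, , drop = FALSE])
  x2 <- as.matrix(X[i2, , drop = FALSE])
  ht <- rank_sum_test(x1, x2)

  m1 <- colMeans(expm1(x1))
  m2 <- colMeans(expm1(x2))
  # written as a difference of logs so swapping the ROIs negates it exactly
  log_fc <- log2(m1 + pseudocount) - log2(m2 + pseudocount)

  res <- data.frame(
    gene = genes,
    log_fc = log_fc,
    p_value = ht$p,
    p_adj = stats::p.adjust(ht$p, method = "BH"),
    mean_roi1 = m1,
    mean_roi2 = m2,
    group = "ns",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(res) <- c("stroi_deg", "data.frame")
  attr(res, "n_roi1") <- length(i1)
  attr(res, "n_roi2") <- length(i2)
  res
}

# Column-wise two-sided rank-sum test, normal approximation with tie
# correction, continuity correction off. Degenerate columns (zero
# variance, i.e. all values tied) get p = 1.
rank_sum_test <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2); n <- n1 + n2
  G <- ncol(x1)
  p <- numeric(G)
  mu <- n1 * (n + 1) / 2
  base_var <- n1 * n2 / 12
  for (j in seq_len(G)) {
    v <- c(x1[, j], x2[, j])
    r <- rank(v)
    R1 <- sum(r[seq_len(n1)])
    ties <- tabulate(match(v, unique(v)))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- base_var * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p[j] <- 1
    } else {
      z <- (R1 - mu) / sqrt(sigma2)
      p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(p = p)
}

#' Classify genes by fold-change and significance cutoffs
#'
#' The standard volcano partition: \code{up_roi1} when
#' \code{log_fc > logfc_cutoff} and \code{p_adj < padj_cutoff},
#' \code{up_roi2} when \code{log_fc < -logfc_cutoff} and
#' \code{p_adj < padj_cutoff}, otherwise \code{ns}. Both inequalities are
#' strict, so a gene exactly at a cutoff stays \code{ns}.
#'
#' @param table a \code{\link{wilcoxon_deg}} result.
#' @param logfc_cutoff non-negative log2 fold-change cutoff (default 1).
#' @param padj_cutoff non-negative adjusted-p cutoff (default 0.05).
#' @return The table with \code{group} filled.
#' @export
classify_degs <- function(table, logfc_cutoff = 1, padj_cutoff = 0.05) {
  if (logfc_cutoff < 0 || padj_cutoff < 0)
    stopf("cutoffs must be non-negative")
  grp <- rep("ns", nrow(table))
  sig <- table$p_adj < padj_cutoff
  grp[sig & table$log_fc > logfc_cutoff] <- "up_roi1"
  grp[sig & table$log_fc < -logfc_cutoff] <- "up_roi2"
  table$group <- grp
  attr(table, "logfc_cutoff") <- logfc_cutoff
  attr(table, "padj_cutoff") <- padj_cutoff
  table
}

#' Top differential genes by fold change
#'
#' The genes up in the chosen ROI, sorted by |log fold change| descending
#' (ties broken by smaller adjusted p, then gene id), truncated to
#' \code{n} (default 10, the usual display depth).
#'
#' @param table a classified DEG table.
#' @param n how many genes (fewer are returned if fewer qualify).
#' @param roi 1 or 2: which ROI's up-genes to rank.
#' @return Character vector of gene ids.
#' @export
top_degs <- function(table, n = 10, roi = 1) {
  want <- if (roi == 1) "up_roi1" else "up_roi2"
  sub <- table[table$group == want, , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  key <- if (roi == 1) -sub$log_fc else sub$log_fc
  ord <- order(key, sub$p_adj, sub$gene)
  utils::head(sub$gene[ord], n)
}

# Upper-tail hypergeometric probability P(X >= k) of drawing k or more
# marked genes when n genes are drawn from a universe of N containing K
# marked ones.
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Hypergeometric (one-sided, upper-tail) test of the overlap between the
#' query genes and each term of a gene-set library, within a fixed
#' universe. For each term with \eqn{K} universe genes, query size
#' \eqn{n} and overlap \eqn{k} in a universe of \eqn{N}:
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).}
#' Matching is case-insensitive (symbols are uppercased). Terms with no
#' universe genes are skipped; p-values are BH-adjusted over the tested
#' terms and rows with \code{p_adj < padj_keep} are flagged
#' \code{reported}. All tested rows are retained.
#'
#' @param query_genes character vector (e.g. the up-regulated DEGs of one
#'   ROI).
#' @param library a \code{\link{gene_set_library}}.
#' @param universe_genes the gene universe; conventionally every gene that
#'   survived preprocessing.
#' @param padj_keep reporting cutoff on the adjusted p (default 0.05).
#' @return A \code{stroi_ora} data.frame: term, k, K, n, N, p_value,
#'   p_adj, reported; sorted by p_value.
#' @export
ora <- function(query_genes, library, universe_genes, padj_keep = 0.05) {
  universe <- unique(toupper(universe_genes))
  query <- intersect(unique(toupper(query_genes)), universe)
  if (length(query) == 0L)
    stopf(paste0("no query genes found in the universe; check gene id ",
                 "conventions (symbols are matched case-insensitively, ",
                 "but identifiers must be of the same type)"))
  N <- length(universe)
  n <- length(query)

  rows <- lapply(names(library$terms), function(term) {
    tg <- intersect(library$terms[[term]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, tg))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows))
    stopf("no library term overlaps the universe")
  rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
  rows$reported <- rows$p_adj < padj_keep
  rows <- rows[order(rows$p_value, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("stroi_ora", "data.frame")
  rows
}

#' Compare cell-type composition between ROIs
#'
#' Averages externally computed per-spot deconvolution fractions (e.g.
#' from CellDART) within each ROI, the quantity behind the per-ROI
#' cell-type bar chart.
#'
#' @param fractions spots x cell-types numeric matrix or data.frame with
#'   row names (or a \code{barcode} column) identifying spots; values in
#'   \code{[0, 1]}.
#' @param labels labeled assignment (or character vector) as in
#'   \code{\link{wilcoxon_deg}}.
#' @param barcodes spot barcodes aligned with \code{labels}; required when
#'   \code{fractions} rows must be matched by barcode.
#' @return A \code{stroi_proportions} list: \code{roi_means} (2 x
#'   cell-types matrix), \code{n_spots} (per-ROI counts), and the matched
#'   \code{fractions}.
#' @export
celltype_proportions <- function(fractions, labels, barcodes = NULL) {
  if (is.data.frame(fractions)) {
    if ("barcode" %in% names(fractions)) {
      rownames(fractions) <- fractions$barcode
      fractions$barcode <- NULL
    }
    fractions <- as.matrix(fractions)
  }
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9))
    stopf("fractions must lie in [0, 1]")
  lab <- if (inherits(labels, "stroi_assignment")) as.character(labels$label)
         else as.character(labels)
  if (!is.null(barcodes)) {
    missing <- setdiff(barcodes[lab %in% c("ROI1", "ROI2")],
                       rownames(fractions))
    if (length(missing))
      stopf("fractions are missing %d ROI barcode(s) (e.g. %s)",
            length(missing), paste(utils::head(missing, 3), collapse = ", "))
    fractions <- fractions[match(barcodes, rownames(fractions)), ,
                           drop = FALSE]
  } else if (nrow(fractions) != length(lab)) {
    stopf("fractions rows (%d) do not align with labels (%d); pass barcodes",
          nrow(fractions), length(lab))
  }
  roi_means <- rbind(
    ROI1 = colMeans(fractions[lab == "ROI1", , drop = FALSE]),
    ROI2 = colMeans(fractions[lab == "ROI2", , drop = FALSE])
  )
  structure(
    list(roi_means = roi_means,
         n_spots = c(ROI1 = sum(lab == "ROI1"), ROI2 = sum(lab == "ROI2")),
         fractions = fractions),
    class = "stroi_proportions"
  )
}

#' @export
print.stroi_proportions <- function(x, ...) {
  cat(sprintf("<stroi_proportions> %d cell types; ROI1 n=%d, ROI2 n=%d\n",
              ncol(x$roi_means), x$n_spots[1], x$n_spots[2]))
  print(round(x$roi_means, 3))
  invisible(x)
}
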