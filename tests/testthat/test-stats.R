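# Build a minimal "normalized" matrix + labels pair for the DEG test.
deg_input <- function(x1, x2) {
  X <- rbind(x1, x2)
  labels <- c(rep("ROI1", nrow(x1)), rep("ROI2", nrow(x2)))
  list(X = X, labels = labels)
}

test_that("identical groups give p = 1 and logFC = 0 for every gene", {
  block <- matrix(rep(c(1, 2, 3, 4), 5), nrow = 4)
  d <- deg_input(block, block)
  res <- wilcoxon_deg(d$X, d$labels)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$log_fc == 0))
  # a gene zero in both groups also falls back to p = 1, logFC = 0
  d0 <- deg_input(cbind(0, matrix(runif(8), 4)), cbind(0, matrix(runif(8), 4)))
  res0 <- wilcoxon_deg(d0$X, d0$labels)
  expect_identical(res0$p_value[1], 1)
  expect_identical(res0$log_fc[1], 0)
  expect_error(wilcoxon_deg(d$X, c("ROI1", rep("ROI2", 7))), "at least 2")
})

test_that("rank-sum p-values track the exact permutation oracle", {
  # complete separation at n1 = n2 = 4: the exact two-sided p is 2/70
  x1 <- matrix(c(5, 6, 7, 8)); x2 <- matrix(c(1, 2, 3, 4))
  expect_equal(perm_ranksum_p(x1[, 1], x2[, 1]), 2 / 70)
  d <- deg_input(x1, x2)
  res <- wilcoxon_deg(d$X, d$labels)
  expect_lt(abs(res$p_value[1] - 2 / 70), 0.02)

  # Seeded continuous genes at small group sizes. Without continuity
  # correction (the convention of the single-cell rank-genes tools) the
  # normal approximation tracks the inclusive exact p closely in the
  # significance tail and within ~0.07 over the whole range, and never
  # ranks a pair of genes in the opposite order.
  for (sizes in list(c(6, 6), c(5, 8))) {
    set.seed(sum(sizes))
    n1 <- sizes[1]; n2 <- sizes[2]; G <- 100
    X <- matrix(rexp((n1 + n2) * G), n1 + n2, G)
    labels <- c(rep("ROI1", n1), rep("ROI2", n2))
    res <- wilcoxon_deg(X, labels)
    oracle <- vapply(seq_len(G), function(j)
      perm_ranksum_p(X[labels == "ROI1", j], X[labels == "ROI2", j]), 0)
    expect_lt(max(abs(res$p_value - oracle)), 0.08)
    tail_genes <- oracle < 0.1
    if (any(tail_genes))
      expect_lt(max(abs(res$p_value - oracle)[tail_genes]), 0.02)
    inversions <- outer(res$p_value, res$p_value, `<`) &
      outer(oracle, oracle, `>`)
    expect_identical(sum(inversions), 0L)
  }
})

test_that("the type-I error rate is controlled under a global null", {
  set.seed(2024)
  X <- matrix(rexp(100 * 500), 100, 500)
  labels <- rep(c("ROI1", "ROI2"), each = 50)
  res <- wilcoxon_deg(X, labels)
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment equals an independent step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(6)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_identical(stats::p.adjust(p, "BH"), bh_stepup(p))
  }
  # step-up output is monotone in the raw p order
  p <- runif(50)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= 0))
  # adjusted never below raw (table invariant)
  d <- deg_input(matrix(rexp(60), 6), matrix(rexp(60), 6))
  res <- wilcoxon_deg(d$X, d$labels)
  expect_true(all(res$p_adj >= res$p_value))
})

test_that("swapping the ROIs negates logFC and preserves p-values", {
  set.seed(9)
  X <- matrix(rexp(30 * 80), 30, 80)
  labels <- c(rep("ROI1", 14), rep("ROI2", 16))
  swapped <- c(rep("ROI2", 14), rep("ROI1", 16))
  a <- wilcoxon_deg(X, labels)
  b <- wilcoxon_deg(X, swapped)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$log_fc, -b$log_fc, tolerance = 1e-12)
})

test_that("DEG classification uses strict cutoffs on both axes", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log_fc = c(2, -2, 1, 0.5, 3),
    p_value = 0.001, p_adj = c(0.001, 0.001, 0.001, 0.001, 0.05),
    mean_roi1 = 1, mean_roi2 = 1, group = "ns"
  )
  out <- classify_degs(tab, logfc_cutoff = 1, padj_cutoff = 0.05)
  expect_identical(out$group,
                   c("up_roi1", "up_roi2", "ns", "ns", "ns"))
  expect_error(classify_degs(tab, -1, 0.05), "non-negative")
})

test_that("top genes are ordered by fold change with documented ties", {
  tab <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    log_fc = c(2, 3, 3, 1.5),
    p_value = 0.001, p_adj = c(0.01, 0.02, 0.001, 0.01),
    mean_roi1 = 1, mean_roi2 = 1,
    group = c("up_roi1", "up_roi1", "up_roi1", "up_roi2")
  )
  expect_identical(top_degs(tab, n = 10), c("g3", "g2", "g1"))  # tie by p_adj
  expect_identical(top_degs(tab, n = 1), "g3")
  expect_identical(top_degs(tab, n = 10, roi = 2), "g4")

  set.seed(12)
  big <- data.frame(
    gene = sprintf("G%03d", 1:200),
    log_fc = round(rnorm(200), 1),
    p_value = 0.001, p_adj = round(runif(200), 2),
    mean_roi1 = 1, mean_roi2 = 1, group = sample(c("up_roi1", "ns"), 200, TRUE)
  )
  got <- top_degs(big, n = 10)
  sub <- big[big$group == "up_roi1", ]
  oracle <- sub$gene[order(-sub$log_fc, sub$p_adj, sub$gene)][1:10]
  expect_identical(got, oracle)
})

test_that("hypergeometric ORA matches closed form and enumeration", {
  # complete overlap: N = 20, K = n = k = 5 has p = 1 / C(20, 5)
  lib <- gene_set_library(list(FULL = sprintf("g%02d", 1:5)))
  universe <- sprintf("g%02d", 1:20)
  res <- ora(sprintf("g%02d", 1:5), lib, universe, padj_keep = 0.05)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 5L, K = 5L, n = 5L, N = 20L),
               ignore_attr = TRUE)

  # zero overlap is never significant: P(X >= 0) = 1
  res0 <- ora("g20", gene_set_library(list(T1 = c("g01", "g02"))), universe)
  expect_identical(res0$p_value, 1)

  # exhaustive enumeration over every (N <= 12, K, n, k)
  for (N in c(5, 8, 12)) for (K in 0:N) for (n in c(0:min(3, N), N)) {
    for (k in 0:min(K, n)) {
      expect_equal(stroi:::hypergeom_upper_tail(k, K, n, N),
                   hyper_tail_enum(k, K, n, N), tolerance = 1e-12,
                   label = sprintf("tail(k=%d,K=%d,n=%d,N=%d)", k, K, n, N))
    }
  }

  # monotone non-increasing in k for fixed (N, K, n)
  tails <- vapply(0:5, stroi:::hypergeom_upper_tail, 0, K = 5, n = 6, N = 15)
  expect_true(all(diff(tails) <= 0))

  # per-term K is computed inside the universe, BH over tested terms
  lib2 <- gene_set_library(list(A = c("g01", "g02", "g03"),
                                B = c("g01", "zzz"),
                                OUT = c("yyy", "zzz")))
  res2 <- ora(c("g01", "g02"), lib2, universe)
  expect_identical(sort(res2$term), c("A", "B"))   # OUT skipped (K = 0)
  expect_identical(res2$K[res2$term == "B"], 1L)   # zzz outside universe
  expect_identical(res2$p_adj, stats::p.adjust(res2$p_value, "BH"))

  expect_error(ora("nope", lib, universe), "universe")
})

test_that("cell-type proportions average fractions per ROI", {
  fr <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1),
              c(0.3, 0.3, 0.4), c(0.25, 0.5, 0.25))
  colnames(fr) <- c("T", "B", "Mono")
  rownames(fr) <- sprintf("S%d", 1:4)
  labels <- c("ROI1", "ROI2", "OTHER", "ROI2")

  # one spot in ROI1: its mean is that spot's row
  pr <- celltype_proportions(fr, labels, barcodes = rownames(fr))
  expect_equal(pr$roi_means["ROI1", ], fr[1, ])
  expect_equal(pr$roi_means["ROI2", ], colMeans(fr[c(2, 4), ]))
  # rows sum to one, so ROI means do too
  expect_equal(unname(rowSums(pr$roi_means)), c(1, 1), tolerance = 1e-6)
  expect_identical(unname(pr$n_spots), c(1L, 2L))

  # random fixture vs group-by oracle
  set.seed(14)
  n <- 60
  frx <- t(apply(matrix(rgamma(n * 4, 1), n), 1, function(r) r / sum(r)))
  colnames(frx) <- paste0("CT", 1:4)
  rownames(frx) <- sprintf("B%02d", 1:n)
  lab <- sample(c("ROI1", "ROI2", "OTHER"), n, TRUE)
  got <- celltype_proportions(frx, lab, barcodes = rownames(frx))
  expect_equal(got$roi_means["ROI1", ], colMeans(frx[lab == "ROI1", ]))

  expect_error(celltype_proportions(fr[1:3, ], labels,
                                    barcodes = rownames(fr)), "missing")
  expect_error(celltype_proportions(fr * 2, labels,
                                    barcodes = rownames(fr)), "\\[0, 1\\]")
})
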