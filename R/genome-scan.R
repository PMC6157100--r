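# Genome-wide gene scan: CpG-to-gene mapping, per-gene adaptive tests,
# multiple-testing adjustment and calibration diagnostics.

#' Map CpGs to genes by genomic interval
#'
#' A CpG belongs to a gene iff it lies on the same chromosome and
#' `start <= pos < end` (0-based half-open, the BED convention). A CpG inside
#' two overlapping genes is assigned to both; genes with no CpGs are retained
#' (and later flagged untestable).
#'
#' @param manifest data.frame with `cpg_id`, `chrom`, `pos`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return named list: for each gene_id, the integer indices of its CpGs in
#'   manifest order (possibly empty).
#' @export
map_cpgs_to_genes <- function(manifest, genes) {
  if (length(intersect(unique(manifest$chrom), unique(genes$chrom))) == 0)
    stop_arg(paste0(
      "no chromosome names shared between manifest and genes; ",
      "manifest has {%s}, genes have {%s}"),
      paste(unique(manifest$chrom), collapse = ","),
      paste(unique(genes$chrom), collapse = ","))
  # convert 0-based half-open [start, end) and 0-based positions to the
  # 1-based closed coordinates GRanges uses
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_cpgs <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_cpgs, gr_genes)
  out <- stats::setNames(rep(list(integer(0)), nrow(genes)), genes$gene_id)
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (k in names(by_gene))
    out[[as.integer(k)]] <- sort(unname(by_gene[[k]]))
  out
}

#' Run the adaptive gene-based scan
#'
#' Fits the null linear mixed model once (variance components do not depend
#' on the gene), then for each annotated gene extracts the score vector and
#' covariance for its CpGs and computes SPUw/aSPUw Monte Carlo p-values.
#' Per-gene seeds are derived deterministically from the master seed and the
#' gene ID, so results are invariant to gene order. A failing gene is
#' recorded in its row, never aborts the scan.
#'
#' @param samples a [sample_frame()].
#' @param methylation a [methylation_matrix()] aligned to the samples.
#' @param psis a [variance_components()] (e.g. GRM + family blocks).
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param weight,gammas,B,B_max per-gene test configuration, see
#'   [aspuw_test()].
#' @param seed master seed.
#' @param alpha family-wise error target for the Bonferroni threshold.
#' @param fit optionally, a precomputed [fit_null_lmm()] for these samples.
#' @param verbose print progress every 50 genes.
#' @return An object of class `aspuw_scan`: `results` (one data.frame row per
#'   gene: interval, `n_cpgs`, per-power p-value columns `p_spuw_*`,
#'   `p_aspuw`, `B`, `testable`, `note`), `metadata` (configuration,
#'   threshold, genomic-control lambda), and the null `fit`.
#' @export
run_scan <- function(samples, methylation, psis, genes,
                     weight = c("inverse_sd", "constant"),
                     gammas = c(1:6, Inf), B = 1000, B_max = B,
                     seed = 1, alpha = 0.05, fit = NULL, verbose = FALSE) {
  weight <- match.arg(weight)
  stopifnot(inherits(samples, "sample_frame"),
            inherits(methylation, "methylation_matrix"))
  if (!identical(rownames(methylation$values), samples$data$sample_id))
    stop_arg("methylation rows are not aligned to the samples table")
  if (is.null(fit)) fit <- fit_null_lmm(samples, psis = psis)
  mapping <- map_cpgs_to_genes(methylation$manifest, genes)

  labs <- gamma_labels(gammas)
  pcols <- paste0("p_spuw_", labs)
  ng <- nrow(genes)
  empty_ps <- stats::setNames(rep(NA_real_, length(labs)), pcols)
  rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    gid <- genes$gene_id[g]
    idx <- mapping[[gid]]
    row <- c(list(gene_id = gid, chrom = genes$chrom[g],
                  start = genes$start[g], end = genes$end[g],
                  n_cpgs = length(idx)),
             as.list(empty_ps),
             list(p_aspuw = NA_real_, B = NA_integer_,
                  testable = FALSE, note = ""))
    if (length(idx) == 0L) {
      row$note <- "no CpGs in interval"
    } else {
      G <- methylation$values[, idx, drop = FALSE]
      res <- tryCatch(
        withCallingHandlers(
          aspuw_test(fit, G, weight = weight, gammas = gammas, B = B,
                     B_max = B_max, seed = derive_seed(seed, gid)),
          warning = function(w) {
            if (grepl("zero-variance", conditionMessage(w)))
              invokeRestart("muffleWarning")
          }),
        error = function(e) e)
      if (inherits(res, "aspuwscan_empty_gene")) {
        row$note <- "all CpGs zero-variance"
      } else if (inherits(res, "error")) {
        row$note <- paste("error:", conditionMessage(res))
      } else {
        row[pcols] <- as.list(res$table$p_value)
        row$p_aspuw <- res$p_aspuw
        row$B <- res$B
        row$testable <- TRUE
        if (length(res$dropped))
          row$note <- sprintf("dropped %d zero-variance CpG(s)",
                              length(res$dropped))
      }
    }
    rows[[g]] <- as.data.frame(row, stringsAsFactors = FALSE)
    if (verbose && g %% 50 == 0)
      message(sprintf("scan: %d/%d genes", g, ng))
  }
  results <- do.call(rbind, rows)
  n_testable <- sum(results$testable)
  if (n_testable == 0L) warning("scan produced no testable genes", call. = FALSE)
  lambda <- if (n_testable > 0)
    genomic_lambda(results$p_aspuw[results$testable]) else NA_real_
  structure(list(
    results = results,
    metadata = list(weight = weight, gammas = gammas, B = B, B_max = B_max,
                    seed = seed, alpha = alpha,
                    n_genes = ng, n_testable = n_testable,
                    threshold = if (n_testable > 0)
                      bonferroni_threshold(alpha, n_testable) else NA_real_,
                    lambda = lambda),
    fit = fit), class = "aspuw_scan")
}

#' @export
print.aspuw_scan <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<aspuw_scan> %d genes (%d testable), weights: %s, B = %d\n",
              m$n_genes, m$n_testable, m$weight, m$B))
  cat(sprintf("  Bonferroni threshold %.3g (alpha = %g); genomic lambda %.3f\n",
              m$threshold, m$alpha, m$lambda))
  sig <- x$results[x$results$testable & x$results$p_aspuw <= m$threshold, ]
  if (nrow(sig)) {
    cat("  significant genes:\n")
    print(sig[, c("gene_id", "chrom", "n_cpgs", "p_aspuw")], row.names = FALSE)
  } else cat("  no gene passes the threshold\n")
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of (testable) genes.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 15731) # ~3e-6
bonferroni_threshold <- function(alpha, n_tests) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_arg("alpha must lie in (0, 1)")
  if (length(n_tests) != 1 || n_tests < 1)
    stop_arg("n_tests must be a positive count")
  alpha / n_tests
}

#' Genomic-control lambda
#'
#' Median of the one-degree-of-freedom chi-square quantiles of the observed
#' p-values, divided by the null median (`qchisq(0.5, 1)`, about 0.455).
#' Values near 1 indicate calibrated tests; below 1, conservative ones.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_lambda <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (length(p) == 0) stop_arg("no finite p-values supplied")
  if (any(p <= 0 | p > 1)) stop_arg("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Manhattan plotting table
#'
#' Deterministic table (one row per testable gene, sorted by chromosome then
#' midpoint) of `-log10` aSPUw p-values for plotting.
#'
#' @param scan an `aspuw_scan`.
#' @return data.frame: `gene_id`, `chrom`, `midpoint`, `neg_log10_p`.
#' @export
manhattan_table <- function(scan) {
  r <- scan$results[scan$results$testable, , drop = FALSE]
  out <- data.frame(gene_id = r$gene_id, chrom = r$chrom,
                    midpoint = (r$start + r$end) / 2,
                    neg_log10_p = -log10(r$p_aspuw),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$midpoint), , drop = FALSE]
}

#' Manhattan plot of a gene scan
#'
#' Thin ggplot2 wrapper around [manhattan_table()]; the table is the tested
#' artifact.
#'
#' @param scan an `aspuw_scan`.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(scan) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_arg("plot_manhattan needs the ggplot2 package")
  tab <- manhattan_table(scan)
  thr <- scan$metadata$threshold
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$midpoint,
                                    y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::labs(x = "position", y = expression(-log[10](p[aSPUw])))
}
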