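# Punch-level label-free proteomics: abundance container, QC filtering,
# imputation, fold change, differential-expression calling, Welch tests
# and correlation clustering.

#' Protein abundance matrix with sample metadata
#'
#' @param intensities numeric matrix, proteins x samples; `NA` marks a
#'   missing (unquantified) value, present values must be positive.
#' @param samples data.frame of per-sample metadata with at least
#'   `sample_id` matching `colnames(intensities)`; typical columns are
#'   `genotype`, `age`, `region`, `mouse`, `batch`, `is_pooled_qc`.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(intensities, samples) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_invalid("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop_invalid("'intensities' needs protein rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    stop_invalid("protein identifiers must be unique")
  if (anyDuplicated(colnames(intensities)))
    stop_invalid("sample identifiers must be unique")
  if (any(intensities <= 0, na.rm = TRUE))
    stop_invalid("present intensities must be positive")
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples))
    stop_invalid("'samples' needs a sample_id column")
  if (!setequal(samples$sample_id, colnames(intensities)))
    stop_invalid("sample metadata must cover every sample exactly")
  samples <- samples[match(colnames(intensities), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(samples$is_pooled_qc)) samples$is_pooled_qc <- FALSE
  structure(list(intensities = intensities, samples = samples),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d proteins x %d samples (%d pooled QC), %.1f%% missing\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$samples$is_pooled_qc),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$intensities)

subset_samples <- function(am, keep) {
  abundance_matrix(am$intensities[, keep, drop = FALSE],
                   am$samples[match(colnames(am$intensities)[keep],
                                    am$samples$sample_id), , drop = FALSE])
}

#' Quality-control filter for punch samples
#'
#' Drops samples whose number of quantified proteins falls below
#' `min_proteins`, and summarizes instrument stability as the per-protein
#' coefficient of variation (SD/mean of raw intensities) across the
#' pooled-QC samples.  The CV summary is a batch-stability check (its
#' median is compared against `cv_max`), not a per-protein filter.
#'
#' @param am an [abundance_matrix()].
#' @param min_proteins minimum number of quantified proteins per sample
#'   (default 1464).
#' @param cv_max acceptable median pooled-sample CV (default 0.15).
#' @return list with `matrix` (the filtered [abundance_matrix()]) and
#'   `report` (class `qc_report`): per-sample protein counts, excluded
#'   samples with reasons, per-protein pooled CVs, `median_cv` and
#'   `cv_pass`.
#' @export
qc_filter <- function(am, min_proteins = 1464, cv_max = 0.15) {
  stopifnot(inherits(am, "abundance_matrix"))
  check_number(min_proteins, "min_proteins", lower = 0)
  counts <- colSums(!is.na(am$intensities))
  excluded <- names(counts)[counts < min_proteins]
  if (length(excluded) == ncol(am$intensities))
    stop_invalid("all samples excluded by the protein-count threshold; pipeline halted")
  pooled <- am$samples$sample_id[am$samples$is_pooled_qc]
  cv <- rep(NA_real_, nrow(am$intensities))
  names(cv) <- rownames(am$intensities)
  if (length(pooled) >= 2L) {
    sub <- am$intensities[, pooled, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, sd, na.rm = TRUE)
    cv <- ifelse(n_ok >= 2L, s / mu, NA_real_)
  }
  median_cv <- median(cv, na.rm = TRUE)
  report <- structure(list(
    protein_counts = counts,
    excluded = data.frame(
      sample_id = excluded,
      reason = if (length(excluded))
        sprintf("fewer than %d protein identifications", min_proteins)
      else character(0)),
    pooled_cv = cv,
    median_cv = median_cv,
    cv_max = cv_max,
    cv_pass = is.na(median_cv) || median_cv < cv_max,
    n_pooled = length(pooled)
  ), class = "qc_report")
  keep <- !colnames(am$intensities) %in% excluded
  list(matrix = subset_samples(am, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d samples, %d excluded (< protein-count threshold)\n",
              length(x$protein_counts), nrow(x$excluded)))
  if (nrow(x$excluded)) cat("  excluded:", paste(x$excluded$sample_id, collapse = ", "), "\n")
  if (x$n_pooled >= 2L)
    cat(sprintf("  pooled-sample median CV = %.3g (%s %g): %s\n",
                x$median_cv, "bound", x$cv_max,
                if (x$cv_pass) "PASS" else "FAIL"))
  else cat("  pooled-sample CV not evaluated (< 2 pooled QC samples)\n")
  invisible(x)
}

#' Impute missing values by the 0.8 x global-minimum rule
#'
#' Every missing entry is replaced by 0.8 times the smallest observed
#' intensity in the whole matrix; observed entries are untouched.  This
#' imputation is intended for embedding/visualization paths only; fold
#' changes and tests omit missing values instead.
#'
#' @param am an [abundance_matrix()].
#' @return an [abundance_matrix()] without missing values.
#' @export
impute_missing <- function(am) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (all(is.na(am$intensities)))
    stop_invalid("cannot impute a fully missing matrix")
  fill <- 0.8 * min(am$intensities, na.rm = TRUE)
  out <- am$intensities
  out[is.na(out)] <- fill
  abundance_matrix(out, am$samples)
}

resolve_group <- function(am, group) {
  ids <- colnames(am$intensities)
  if (is.logical(group)) ids[group]
  else if (is.numeric(group)) ids[group]
  else intersect(as.character(group), ids)
}

#' Per-protein fold change between two sample groups
#'
#' Group means are taken over the non-missing values only (missing values
#' are omitted, not imputed); the fold change is `mean_a / mean_b`.
#' Proteins quantified in only one group get an infinite (or zero) fold
#' change and are flagged, not dropped; proteins absent from both groups
#' are flagged `undefined`.
#'
#' @param am an [abundance_matrix()].
#' @param group_a,group_b sample id vectors (or logical/numeric column
#'   selectors); both non-empty.
#' @return data.frame with `protein`, `mean_a`, `mean_b`, `fc`,
#'   `log2fc`, `n_a`, `n_b`, `flag` (`"ok"`, `"absent_in_a"`,
#'   `"absent_in_b"`, `"undefined"`).
#' @export
fold_change <- function(am, group_a, group_b) {
  stopifnot(inherits(am, "abundance_matrix"))
  a <- resolve_group(am, group_a); b <- resolve_group(am, group_b)
  if (!length(a) || !length(b)) stop_invalid("both groups must be non-empty")
  ma <- am$intensities[, a, drop = FALSE]
  mb <- am$intensities[, b, drop = FALSE]
  n_a <- rowSums(!is.na(ma)); n_b <- rowSums(!is.na(mb))
  mean_a <- ifelse(n_a > 0, rowMeans(ma, na.rm = TRUE), NA_real_)
  mean_b <- ifelse(n_b > 0, rowMeans(mb, na.rm = TRUE), NA_real_)
  fc <- mean_a / mean_b
  flag <- rep("ok", nrow(ma))
  flag[n_a == 0 & n_b > 0] <- "absent_in_a"
  flag[n_b == 0 & n_a > 0] <- "absent_in_b"
  flag[n_a == 0 & n_b == 0] <- "undefined"
  fc[flag == "absent_in_a"] <- 0
  fc[flag == "absent_in_b"] <- Inf
  fc[flag == "undefined"] <- NA_real_
  data.frame(protein = rownames(ma), mean_a = mean_a, mean_b = mean_b,
             fc = fc, log2fc = log2(fc), n_a = n_a, n_b = n_b,
             flag = flag, row.names = NULL)
}

#' Call differentially expressed proteins between two groups
#'
#' Per-protein two-tailed two-sample t-test on log2-transformed
#' intensities (Student's pooled-variance test by default, as used for
#' group comparisons in the punch pipeline; set `var_equal = FALSE` for
#' Welch), Benjamini--Hochberg adjustment across the tested proteins, and
#' significance calling at `adjusted p < alpha` together with a two-sided
#' fold-change threshold (`fc > fc_threshold` or `fc < 1/fc_threshold`).
#' Fold changes are computed on the raw intensities with missing values
#' omitted ([fold_change()]); proteins with fewer than two observed
#' values in either group are reported as untested.
#'
#' @param am an [abundance_matrix()].
#' @param group_a,group_b sample selectors as in [fold_change()].
#' @param alpha adjusted-p significance level (default 0.05).
#' @param fc_threshold fold-change threshold (default 2, applied two-sided).
#' @param var_equal pooled-variance t-test if `TRUE` (default).
#' @param bh_family `"tested"` (default) adjusts across tested proteins
#'   only; `"all"` uses the full protein count as the family size.
#' @return data.frame of class `dep_table`: per protein `fc`, `log2fc`,
#'   `p`, `padj`, `tested`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`), plus group sizes and flags.
#' @export
call_deps <- function(am, group_a, group_b, alpha = 0.05, fc_threshold = 2,
                      var_equal = TRUE, bh_family = c("tested", "all")) {
  bh_family <- match.arg(bh_family)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(fc_threshold, "fc_threshold", lower = 1)
  fc <- fold_change(am, group_a, group_b)
  a <- resolve_group(am, group_a); b <- resolve_group(am, group_b)
  la <- log2(am$intensities[, a, drop = FALSE])
  lb <- log2(am$intensities[, b, drop = FALSE])
  tested <- fc$n_a >= 2L & fc$n_b >= 2L
  p <- rep(NA_real_, nrow(fc))
  for (i in which(tested)) {
    va <- la[i, !is.na(la[i, ])]
    vb <- lb[i, !is.na(lb[i, ])]
    if (var(va) == 0 && var(vb) == 0) {
      p[i] <- if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0
    } else {
      p[i] <- t.test(va, vb, var.equal = var_equal)$p.value
    }
  }
  padj <- rep(NA_real_, length(p))
  n_family <- if (bh_family == "all") length(p) else sum(tested)
  padj[tested] <- p.adjust(p[tested], method = "BH", n = n_family)
  sig <- tested & padj < alpha &
    (fc$fc > fc_threshold | fc$fc < 1 / fc_threshold)
  sig[is.na(sig)] <- FALSE
  direction <- ifelse(!sig, "none", ifelse(fc$fc > 1, "up", "down"))
  out <- cbind(fc, p = p, padj = padj, tested = tested,
               significant = sig, direction = direction)
  structure(out, alpha = alpha, fc_threshold = fc_threshold,
            class = c("dep_table", "data.frame"))
}

#' @export
print.dep_table <- function(x, ...) {
  cat(sprintf(
    "DEP table: %d proteins, %d tested, %d significant (padj < %g & FC > %g or < %g)\n",
    nrow(x), sum(x$tested), sum(x$significant), attr(x, "alpha"),
    attr(x, "fc_threshold"), 1 / attr(x, "fc_threshold")))
  up <- sum(x$direction == "up"); dn <- sum(x$direction == "down")
  cat(sprintf("  up-regulated %d, down-regulated %d\n", up, dn))
  invisible(x)
}

#' Two-sided Welch's t-test between two value vectors
#'
#' Unequal-variance t-test with Welch--Satterthwaite degrees of freedom
#' (via [stats::t.test()]).  When both groups have zero variance the test
#' statistic is undefined; by convention this returns p = 1 for equal
#' means and p = 0 otherwise.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @return list with `statistic` (t), `df`, `p.value`.
#' @export
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_invalid("each group needs at least 2 values")
  if (var(values_a) == 0 && var(values_b) == 0) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p.value = if (eq) 1 else 0))
  }
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' monotone in the raw p-values, never smaller than them, capped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Clustered sample-correlation heatmap
#'
#' Pairwise Pearson correlation between samples over a protein subset
#' (pairwise-complete observations), z-score scaling of the correlation
#' matrix, and average-linkage hierarchical clustering on the
#' `1 - correlation` distance.  The heatmap (via \pkg{pheatmap}) carries
#' metadata colour bars for genotype/age/region when present.
#'
#' @param am an [abundance_matrix()].
#' @param proteins character vector of protein ids to correlate over
#'   (non-empty; e.g. a DEP panel).
#' @param file optional PNG path; when given the heatmap is written there.
#' @return (invisibly) list with `correlation`, `zscore`, `hclust`, and
#'   `undefined_pairs` (sample pairs with undefined correlation, if any).
#' @export
correlation_clustermap <- function(am, proteins, file = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  proteins <- intersect(proteins, rownames(am$intensities))
  if (!length(proteins)) stop_invalid("protein subset is empty")
  if (ncol(am$intensities) < 2L) stop_invalid("need >= 2 samples")
  sub <- log2(am$intensities[proteins, , drop = FALSE])
  C <- suppressWarnings(cor(sub, use = "pairwise.complete.obs",
                            method = "pearson"))
  und <- which(is.na(C) & upper.tri(C), arr.ind = TRUE)
  undefined_pairs <- if (nrow(und))
    data.frame(sample_a = rownames(C)[und[, 1]],
               sample_b = colnames(C)[und[, 2]])
  else data.frame(sample_a = character(0), sample_b = character(0))
  if (nrow(und))
    warning(sprintf("%d sample pairs have undefined correlation (constant or disjoint profiles)",
                    nrow(und)))
  Cd <- C; Cd[is.na(Cd)] <- 0
  hc <- hclust(as.dist(1 - Cd), method = "average")
  z <- (Cd - mean(Cd)) / sd(Cd)
  if (!is.null(file)) {
    ann <- am$samples[, intersect(c("genotype", "age", "region"),
                                  names(am$samples)), drop = FALSE]
    rownames(ann) <- am$samples$sample_id
    if (!ncol(ann)) ann <- NA
    pheatmap::pheatmap(
      z, cluster_rows = hc, cluster_cols = hc,
      annotation_col = if (is.data.frame(ann)) ann else NA,
      silent = TRUE, main = "z-scored Pearson correlation",
      filename = file)
  }
  invisible(list(correlation = C, zscore = z, hclust = hc,
                 undefined_pairs = undefined_pairs))
}
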