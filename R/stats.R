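# Quantitative comparison layer: per-ROI counts, proportional regression
# with intercept test, Pearson/Spearman/top-k Spearman, voxelwise Pearson,
# false-positive/negative classification, streamline sensitivity, and
# connectivity backbone export.

#' Per-ROI totals of a surface density map
#'
#' Sums densities over each ROI's interface voxels. Density on interface
#' voxels outside all ROIs is reported in the `outside` attribute.
#'
#' @param sddm a [surface_ddm()].
#' @param roi_map integer 3D array of ROI ids (0 = none).
#' @return named numeric vector of per-ROI totals (names = ROI ids), with
#'   attribute `outside`.
#' @export
regional_counts <- function(sddm, roi_map) {
  stopifnot(inherits(sddm, "surface_ddm"))
  ids <- roi_map[lin_index(sddm$interface$voxels, sddm$interface$dims)]
  rois <- sort(setdiff(unique(as.vector(roi_map)), 0L))
  tot <- vapply(rois, function(r) sum(sddm$values[ids == r]), numeric(1))
  names(tot) <- rois
  attr(tot, "outside") <- sum(sddm$values[ids == 0])
  tot
}

#' Proportional regression of streamline on fiber counts
#'
#' Fits `N_D = a + b N_B + e` by ordinary least squares; if 0 lies within the
#' t-based 95% confidence interval of the intercept, refits through the
#' origin (`N_D = b N_B + e`, the "second tier" proportional model) and
#' reports that slope. Pearson r and its p-value are always computed on the
#' raw pairs.
#'
#' @param N_B,N_D aligned nonnegative vectors (>= 3 ROIs).
#' @param log_scale if `TRUE`, fit on log10(1 + counts) instead of raw counts.
#' @return object of class `proportional_fit`: `a`, `b`, `ci_a`, `residuals`,
#'   `r`, `p`, `model_used` (1 = with intercept, 2 = through origin).
#' @export
fit_proportional <- function(N_B, N_D, log_scale = FALSE) {
  stopifnot(length(N_B) == length(N_D), length(N_B) >= 3)
  if (stats::var(N_B) == 0) stop("N_B has zero variance; slope is undefined")
  x <- if (log_scale) log10(1 + N_B) else N_B
  y <- if (log_scale) log10(1 + N_D) else N_D
  m1 <- stats::lm(y ~ x)
  ci <- stats::confint(m1, level = 0.95)[1, ]
  ct <- stats::cor.test(x, y, method = "pearson")
  # numerically perfect fits give an intercept CI of floating-point width;
  # test origin inclusion at a scale-relative tolerance
  tol <- 1e-8 * max(stats::sd(y), .Machine$double.eps)
  if (ci[1] <= tol && ci[2] >= -tol) {
    m2 <- stats::lm(y ~ 0 + x)
    structure(list(a = 0, b = unname(stats::coef(m2)[1]), ci_a = unname(ci),
                   residuals = unname(stats::residuals(m2)),
                   r = unname(ct$estimate), p = ct$p.value, model_used = 2L,
                   log_scale = log_scale),
              class = "proportional_fit")
  } else {
    structure(list(a = unname(stats::coef(m1)[1]), b = unname(stats::coef(m1)[2]),
                   ci_a = unname(ci), residuals = unname(stats::residuals(m1)),
                   r = unname(ct$estimate), p = ct$p.value, model_used = 1L,
                   log_scale = log_scale),
              class = "proportional_fit")
  }
}

#' @export
print.proportional_fit <- function(x, ...) {
  cat(sprintf("proportional fit (model %d%s): a = %.4g, b = %.4g, r = %.3f (p = %.3g)\n",
              x$model_used, if (x$model_used == 2) ", through origin" else "",
              x$a, x$b, x$r, x$p))
  invisible(x)
}

# two-sided p-value for a correlation coefficient via the t transform
cor_p_t <- function(r, n) {
  if (is.na(r) || n < 3) return(1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Correlation with zero-variance handling
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) with a two-sided p-value from the t transform; optionally a
#' permutation p-value (exact enumeration for n <= 7, 10000 random
#' permutations otherwise). If either vector has zero variance the
#' coefficient is undefined and reported as `NA` with the sentinel p = 1.
#'
#' @param x,y equal-length vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @param p_method `"t"` or `"permutation"`.
#' @return list with `estimate`, `p`, `n`, `method`, `defined`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      p_method = c("t", "permutation")) {
  method <- match.arg(method); p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(estimate = NA_real_, p = 1, n = n, method = method,
                defined = FALSE))
  xs <- if (method == "spearman") rank(x) else x
  ys <- if (method == "spearman") rank(y) else y
  r <- stats::cor(xs, ys)
  if (p_method == "t") {
    p <- cor_p_t(r, n)
  } else {
    stat <- function(perm) stats::cor(xs, ys[perm])
    if (n <= 7) {
      perms <- permutations_all(n)
      null <- apply(perms, 1, stat)
      p <- mean(abs(null) >= abs(r) - 1e-12)
    } else {
      null <- vapply(seq_len(10000), function(i) stat(sample.int(n)), numeric(1))
      p <- (sum(abs(null) >= abs(r) - 1e-12) + 1) / (10001)
    }
  }
  list(estimate = r, p = p, n = n, method = method, defined = TRUE)
}

# all permutations of 1..n as a matrix (n! x n); n <= 7 keeps this small
permutations_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

#' Spearman correlation on the strongest connections
#'
#' Restricts the ROI set either to those with `N_B > threshold` (the study
#' used 100 tracer-labeled fibers) or to the `k` ROIs with the largest
#' `N_B`, then computes the Spearman rank correlation on the subset.
#'
#' @param N_B,N_D aligned vectors.
#' @param rule `"threshold"` or `"k_largest"`.
#' @param threshold N_B cutoff for `rule = "threshold"`.
#' @param k subset size for `rule = "k_largest"`.
#' @return as [correlate()], plus `k_used` and `selected` indices.
#' @export
topk_spearman <- function(N_B, N_D, rule = c("threshold", "k_largest"),
                          threshold = 100, k = 10) {
  rule <- match.arg(rule)
  sel <- if (rule == "threshold") which(N_B > threshold)
         else order(N_B, decreasing = TRUE)[seq_len(min(k, length(N_B)))]
  if (length(sel) < 3)
    stop("fewer than 3 ROIs survive the selection rule")
  out <- correlate(N_B[sel], N_D[sel], method = "spearman")
  out$k_used <- length(sel); out$selected <- sel
  out
}

#' Voxelwise Pearson correlation within one ROI
#'
#' Pearson correlation between histological and tractographic densities over
#' the interface voxels directly underneath one projection region. With zero
#' variance in either vector the coefficient is undefined and flagged
#' (estimate `NA`, sentinel p = 1).
#'
#' @param B,D aligned per-voxel density vectors (same voxel ordering, n >= 2).
#' @return list with `r_p`, `p`, `n`, `defined`.
#' @export
voxelwise_pearson <- function(B, D) {
  stopifnot(length(B) == length(D), length(B) >= 2)
  n <- length(B)
  if (stats::var(B) == 0 || stats::var(D) == 0)
    return(list(r_p = NA_real_, p = 1, n = n, defined = FALSE))
  r <- stats::cor(B, D)
  list(r_p = r, p = cor_p_t(r, n), n = n, defined = TRUE)
}

#' Classify false negative and false positive connections
#'
#' A false negative ROI has tracer-labeled fibers but no streamlines
#' (N_B > 0, N_D = 0); a false positive ROI has streamlines but no labeled
#' fibers (N_B = 0, N_D > 0).
#'
#' @param table data.frame with columns `roi`, `N_B`, `N_D`.
#' @return list with `false_negative` and `false_positive` ROI id vectors.
#' @export
classify_fp_fn <- function(table) {
  stopifnot(all(c("roi", "N_B", "N_D") %in% names(table)))
  list(false_negative = table$roi[table$N_B > 0 & table$N_D == 0],
       false_positive = table$roi[table$N_B == 0 & table$N_D > 0])
}

#' Fraction of streamlines reaching true positive ROIs
#'
#' Among streamlines that reach any projection ROI, the fraction reaching a
#' true positive ROI (one with a ground-truth connection). The study reports
#' 75-98% across its nine tracking strategies.
#'
#' @param streamlines a `streamline_set`.
#' @param true_positive_rois ROI ids with ground-truth connections.
#' @param roi_map integer 3D array of ROI ids.
#' @return list with `sensitivity` (`NA` if no streamline reaches any ROI),
#'   `n_reaching`, `n_true`.
#' @export
streamline_sensitivity <- function(streamlines, true_positive_rois, roi_map) {
  stopifnot(inherits(streamlines, "streamline_set"), length(true_positive_rois) > 0)
  rv <- as.vector(roi_map)
  reached <- lapply(streamlines$visited, function(v) setdiff(unique(rv[v]), 0L))
  any_roi <- vapply(reached, function(r) length(r) > 0, logical(1))
  tp <- vapply(reached, function(r) any(r %in% true_positive_rois), logical(1))
  n_reach <- sum(any_roi)
  if (n_reach == 0)
    return(list(sensitivity = NA_real_, n_reaching = 0L, n_true = 0L))
  list(sensitivity = sum(tp) / n_reach, n_reaching = n_reach, n_true = sum(tp))
}

#' Export an inter-regional connectivity backbone graph
#'
#' Builds a star graph from the injection region to every ROI with nonzero
#' connection strength. Node size is proportional to the square root of the
#' region volume, edge weight is the logarithmic connection strength, and
#' the `connection_weight` edge attribute is strength divided by ROI volume.
#'
#' @param table data.frame with columns `roi`, `strength`.
#' @param roi_volumes named vector of ROI volumes (same ids).
#' @param injection_volume volume of the injection region.
#' @return an [igraph::graph_from_data_frame()] graph.
#' @export
export_backbone <- function(table, roi_volumes, injection_volume = 1) {
  stopifnot(all(table$strength >= 0))
  keep <- table$strength > 0
  edges <- data.frame(from = "injection", to = paste0("roi", table$roi[keep]),
                      weight = log10(1 + table$strength[keep]),
                      strength = table$strength[keep],
                      connection_weight = table$strength[keep] /
                        roi_volumes[as.character(table$roi[keep])])
  nodes <- data.frame(name = c("injection", paste0("roi", table$roi)),
                      size = sqrt(c(injection_volume,
                                    roi_volumes[as.character(table$roi)])))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' One-way ANOVA of voxelwise correlations across seed depths
#'
#' F-test of per-ROI voxelwise correlation coefficients grouped by the seed
#' extension depth d_w.
#'
#' @param r_p numeric vector of voxelwise correlation coefficients.
#' @param d_w factor/vector of seed depths (same length).
#' @return list with `F`, `p`, `df`.
#' @export
anova_seed_depth <- function(r_p, d_w) {
  ok <- is.finite(r_p)
  fit <- stats::aov(r_p[ok] ~ factor(d_w[ok]))
  s <- summary(fit)[[1]]
  list(F = s[1, "F value"], p = s[1, "Pr(>F)"], df = s[, "Df"])
}
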