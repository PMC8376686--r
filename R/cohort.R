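#' Z-score CSF biomarkers against a control cohort
#'
#' Builds the six-dimensional CSF profile per patient — raw amyloid-beta,
#' tau, phosphorylated tau (pg/ml) and the ratios abeta/tau, abeta/ptau,
#' ptau/tau — and standardizes each dimension against the control cohort
#' (sample mean and n-1 standard deviation). Patients missing any of the
#' three raw biomarkers are dropped as incomplete cases and counted.
#'
#' @param patients data.frame with columns `subject_id`, `abeta`, `tau`,
#'   `ptau`.
#' @param controls data.frame with the same biomarker columns (at least 2
#'   complete control subjects).
#' @return list with `z` (complete-case matrix of 6 z-scored biomarkers,
#'   rownames = subject ids), `raw` (the complete-case 6-biomarker values),
#'   `n_dropped` (incomplete patients), `control_mean`, `control_sd`.
#' @export
zscore_biomarkers <- function(patients, controls) {
  req <- c("abeta", "tau", "ptau")
  for (nm in req) {
    if (!nm %in% names(patients)) stop("patients table missing column: ", nm)
    if (!nm %in% names(controls)) stop("controls table missing column: ", nm)
  }
  expand6 <- function(tab) {
    cbind(abeta = tab$abeta, tau = tab$tau, ptau = tab$ptau,
          abeta_tau = tab$abeta / tab$tau,
          abeta_ptau = tab$abeta / tab$ptau,
          ptau_tau = tab$ptau / tab$tau)
  }
  ctrl <- expand6(controls)
  ctrl <- ctrl[stats::complete.cases(ctrl), , drop = FALSE]
  if (nrow(ctrl) < 2) stop("need at least 2 complete control subjects")
  mu <- colMeans(ctrl)
  sdev <- apply(ctrl, 2, stats::sd)
  if (any(sdev <= 0)) {
    stop("zero control standard deviation for: ",
         paste(colnames(ctrl)[sdev <= 0], collapse = ", "))
  }
  pat <- expand6(patients)
  complete <- stats::complete.cases(pat)
  n_dropped <- sum(!complete)
  pat <- pat[complete, , drop = FALSE]
  ids <- as.character(patients$subject_id[complete])
  z <- sweep(sweep(pat, 2, mu, "-"), 2, sdev, "/")
  rownames(z) <- ids
  rownames(pat) <- ids
  list(z = z, raw = pat, n_dropped = n_dropped,
       control_mean = mu, control_sd = sdev)
}

#' Calinski-Harabasz variance-ratio index
#'
#' `CH(k) = [B / (k - 1)] / [W / (n - k)]` where `B` and `W` are the
#' between- and within-cluster sums of squared Euclidean distances to the
#' respective centroids.
#'
#' @param x numeric matrix, observations in rows.
#' @param labels integer cluster assignment.
#' @return the CH score (`Inf` when `W` is exactly 0 and `B > 0`; `NaN` when
#'   both vanish).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
  grand <- colMeans(x)
  W <- 0
  B <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    W <- W + sum(sweep(xg, 2, cg, "-")^2)
    B <- B + nrow(xg) * sum((cg - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Hierarchical clustering with Calinski-Harabasz model selection
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance by default)
#' cut at each candidate number of clusters; the variance-ratio
#' (Calinski-Harabasz) score selects `k`, ties resolving to the smaller `k`.
#' Degenerate geometry (total scatter numerically zero) returns the smallest
#' candidate without attempting the variance ratio.
#'
#' @param z_matrix numeric matrix of features, one row per subject.
#' @param k_candidates integer vector of candidate cluster counts
#'   (default `2:10`).
#' @param linkage one of `"ward"`, `"average"`, `"complete"`.
#' @return an object of class `cluster_result` with `labels`, `k_selected`,
#'   `ch_curve` (named by k), `linkage_method`.
#' @export
hierarchical_cluster <- function(z_matrix, k_candidates = 2:10,
                                 linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  z_matrix <- as.matrix(z_matrix)
  if (any(!is.finite(z_matrix))) stop("non-finite values in clustering input")
  n <- nrow(z_matrix)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 2)) stop("candidate k must be >= 2")
  if (n < max(k_candidates) + 1) {
    stop("need at least max(k_candidates) + 1 = ", max(k_candidates) + 1,
         " subjects, got ", n)
  }
  hc_method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  hc <- stats::hclust(stats::dist(z_matrix), method = hc_method)
  cuts <- stats::cutree(hc, k = k_candidates)
  if (length(k_candidates) == 1) cuts <- matrix(cuts, ncol = 1)
  total_scatter <- sum(sweep(z_matrix, 2, colMeans(z_matrix), "-")^2)
  ch <- rep(NA_real_, length(k_candidates))
  names(ch) <- k_candidates
  if (total_scatter > 1e-10 * n) {
    for (j in seq_along(k_candidates)) {
      ch[j] <- calinski_harabasz(z_matrix, cuts[, j])
    }
    best <- which.max(ch)     # first maximum -> smallest k on ties
  } else {
    best <- 1L                # degenerate geometry: smallest candidate
  }
  structure(list(labels = unname(cuts[, best]),
                 k_selected = k_candidates[best],
                 ch_curve = ch, linkage_method = hc_method,
                 hclust = hc, cuts = cuts),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage_method, "): selected k = ",
      x$k_selected, "\n", sep = "")
  cat("  cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  cat("  CH curve:\n")
  print(round(x$ch_curve, 2))
  invisible(x)
}

#' Non-parametric and frequency group comparisons
#'
#' Thin wrappers over the standard tests used for cohort contrasts:
#' Kruskal-Wallis rank ANOVA for 2+ groups, Wilcoxon rank-sum for two
#' groups, and the chi-square test on a contingency table. P-values are
#' two-sided and deliberately uncorrected for multiple comparisons; an
#' optional Benjamini-Hochberg adjustment across a batch of p-values is
#' available via [stats::p.adjust()] by the caller.
#'
#' @param values numeric vector (for rank tests) or contingency matrix/table
#'   (for `chi_square`, with `labels` ignored).
#' @param labels group labels for rank tests.
#' @param test one of `"kruskal_wallis"`, `"wilcoxon_ranksum"`, `"chi_square"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(values, labels = NULL,
                           test = c("kruskal_wallis", "wilcoxon_ranksum", "chi_square")) {
  test <- match.arg(test)
  if (test == "chi_square") {
    tab <- as.matrix(values)
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(statistic = unname(res$statistic), p_value = res$p.value, test = test))
  }
  labels <- as.factor(labels)
  if (length(values) != length(labels)) stop("values and labels must have equal length")
  if (any(table(labels) == 0) || nlevels(labels) < 2) stop("need >= 2 non-empty groups")
  if (test == "kruskal_wallis") {
    res <- stats::kruskal.test(values, labels)
  } else {
    if (nlevels(labels) != 2) stop("wilcoxon_ranksum requires exactly 2 groups")
    res <- suppressWarnings(
      stats::wilcox.test(values[labels == levels(labels)[1]],
                         values[labels == levels(labels)[2]], exact = FALSE))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value, test = test)
}

#' Select the most atrophied regions by independent t-tests
#'
#' Per-region two-sample pooled-variance t-statistics of case versus control
#' volumes; the `k` regions with the most negative statistic (greatest
#' volume deficit in cases) are returned, ties resolving in label order.
#'
#' @param case_volumes numeric matrix of case regional volumes (subjects in
#'   rows, regions in columns, column names = region labels).
#' @param control_volumes matrix with identical region columns.
#' @param k number of regions to select (default 10); clamped to the number
#'   of regions with a warning when larger.
#' @return character vector of selected region labels, plus attributes
#'   `t_statistics` (named, all regions).
#' @export
select_atrophy_regions <- function(case_volumes, control_volumes, k = 10) {
  case_volumes <- as.matrix(case_volumes)
  control_volumes <- as.matrix(control_volumes)
  if (!identical(colnames(case_volumes), colnames(control_volumes))) {
    stop("case and control tables must cover identical regions in the same order")
  }
  if (nrow(case_volumes) < 2 || nrow(control_volumes) < 2) {
    stop("need at least 2 subjects per arm")
  }
  n1 <- nrow(case_volumes); n2 <- nrow(control_volumes)
  m1 <- colMeans(case_volumes); m2 <- colMeans(control_volumes)
  v1 <- apply(case_volumes, 2, stats::var)
  v2 <- apply(control_volumes, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (any(sp2 <= 0)) {
    bad <- colnames(case_volumes)[sp2 <= 0]
    stop("zero pooled variance in region(s): ", paste(bad, collapse = ", "))
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  labs <- colnames(case_volumes)
  if (is.null(labs)) labs <- paste0("R", seq_along(tstat))
  names(tstat) <- labs
  if (k > length(tstat)) {
    warning("k = ", k, " exceeds region count ", length(tstat), "; returning all")
    k <- length(tstat)
  }
  ord <- order(tstat, seq_along(tstat))   # most negative first; ties by label order
  sel <- labs[ord[seq_len(k)]]
  attr(sel, "t_statistics") <- tstat
  sel
}

#' Multivariate baseline regression predicting the progression rate
#'
#' Ordinary least squares of an outcome (the fitted diffusivity `beta`, or
#' any other progression measure such as the global atrophy rate) on a set
#' of baseline predictors — canonically the 10 most atrophied regional
#' volumes plus 3 CSF biomarkers. Complete cases only; a rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param features data.frame or matrix of predictors (one column each).
#' @param outcome numeric outcome vector, same length as `nrow(features)`.
#' @return an object of class `regression_report` with `r_squared`,
#'   `coefficients` (estimate, p_value per term incl. intercept), `n_used`.
#' @export
predict_ppr_baseline <- function(features, outcome) {
  features <- as.data.frame(features)
  if (nrow(features) != length(outcome)) stop("outcome length must match feature rows")
  complete <- stats::complete.cases(features) & is.finite(outcome)
  features <- features[complete, , drop = FALSE]
  outcome <- outcome[complete]
  p <- ncol(features)
  if (nrow(features) <= p + 1) {
    stop("need more complete cases (", nrow(features), ") than predictors + 1 (", p + 1, ")")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    # name the columns they collide with: those whose removal restores full rank
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(outcome ~ ., data = features)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, "Estimate"],
                      p_value = sm$coefficients[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(r_squared = sm$r.squared, coefficients = coefs,
                 n_used = length(outcome), lm_fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("Baseline regression: R-squared =", round(x$r_squared, 4),
      "on", x$n_used, "complete cases\n")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}

#' Regional atrophy from volumes via control z-scoring
#'
#' Reference recipe converting regional volumes to the nonnegative atrophy
#' statistic the fitting consumes: the volume deficit z-score relative to a
#' control cohort, floored at 0. A region smaller than the control mean by
#' `z` control standard deviations gets atrophy `z`; regions at or above
#' the control mean get 0.
#'
#' @param volumes numeric matrix of regional volumes (subjects x regions).
#' @param control_volumes control cohort volumes, identical region columns.
#' @return matrix of nonnegative atrophy values, same shape as `volumes`.
#' @export
atrophy_from_volumes <- function(volumes, control_volumes) {
  volumes <- as.matrix(volumes)
  control_volumes <- as.matrix(control_volumes)
  if (!identical(colnames(volumes), colnames(control_volumes))) {
    stop("volume tables must cover identical regions in the same order")
  }
  mu <- colMeans(control_volumes)
  sdev <- apply(control_volumes, 2, stats::sd)
  if (any(sdev <= 0)) stop("zero control variance in region(s): ",
                           paste(colnames(volumes)[sdev <= 0], collapse = ", "))
  z <- sweep(sweep(volumes, 2, mu, "-"), 2, sdev, "/")
  pmax(-z, 0)
}
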