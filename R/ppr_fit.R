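#' Build a longitudinal atrophy trajectory
#'
#' @param subject_id subject identifier.
#' @param t_long numeric vector of years since baseline; strictly increasing,
#'   first entry 0, length at least 2.
#' @param phi matrix of regional atrophy, one row per visit (rows follow
#'   `t_long`), one column per region.
#' @param region_labels ordered region names matching the connectome.
#' @return an object of class `atrophy_trajectory`.
#' @export
atrophy_trajectory <- function(subject_id, t_long, phi, region_labels) {
  phi <- as.matrix(phi)
  if (length(t_long) < 2) stop("need at least 2 visits (nt >= 2)")
  if (any(diff(t_long) <= 0)) stop("t_long must be strictly increasing")
  if (abs(t_long[1]) > 1e-12) stop("t_long must start at 0 (years since baseline)")
  if (nrow(phi) != length(t_long)) stop("phi must have one row per visit")
  if (ncol(phi) != length(region_labels)) stop("phi column count must match region_labels")
  if (any(phi < -1e-12)) stop("atrophy values must be nonnegative")
  structure(list(subject_id = as.character(subject_id),
                 t_long = as.numeric(t_long), phi = phi,
                 region_labels = as.character(region_labels)),
            class = "atrophy_trajectory")
}

#' Per-region atrophy slopes by ordinary least squares
#'
#' Each region's longitudinal atrophy is regressed on time with an intercept
#' (design `[1, t_long]`, solved via the pseudoinverse). Negative slopes are
#' set to 0 and counted: cortical thickening is treated as measurement error
#' in a neurodegenerative cohort.
#'
#' @param traj an [atrophy_trajectory()].
#' @return a list of class `slope_estimate` with `slopes` (clipped at 0),
#'   `intercepts`, and `n_clipped`.
#' @export
fit_slopes <- function(traj) {
  stopifnot(inherits(traj, "atrophy_trajectory"))
  t_long <- traj$t_long
  if (max(t_long) - min(t_long) <= 0) stop("all timestamps identical; slopes undefined")
  X <- cbind(1, t_long)
  # pseudoinverse solve of the shared design for all regions at once
  coefs <- qr.coef(qr(X), traj$phi)
  intercepts <- coefs[1, ]
  slopes <- coefs[2, ]
  slopes[abs(slopes) < 1e-12] <- 0   # solver noise on flat trajectories
  n_clipped <- sum(slopes < 0)
  slopes[slopes < 0] <- 0
  structure(list(slopes = unname(slopes), intercepts = unname(intercepts),
                 n_clipped = n_clipped, region_labels = traj$region_labels),
            class = "slope_estimate")
}

#' Default onset-time search grid
#'
#' @param t_min,t_max grid bounds in years.
#' @param step grid spacing in years.
#' @return numeric vector of candidate `t_base` values.
#' @export
tbase_grid <- function(t_min = 0.25, t_max = 50, step = 0.25) {
  if (t_min <= 0 || step <= 0 || t_max < t_min) stop("invalid t_base grid")
  seq(t_min, t_max, by = step)
}

#' Estimate the onset-to-baseline time by correlation grid search
#'
#' With the diffusivity pinned at a reference value `beta0`, scans a grid of
#' candidate onset times and returns the one maximizing the Pearson
#' correlation between the model-predicted slope pattern
#' `beta0 * Htilde(beta0 t) * phi_base` and the observed regional slopes.
#' Because `Htilde` depends on `beta` and `t` only through their product, the
#' identified quantity is `beta0 * tbase_hat` (an estimate of the true
#' `beta * t_base`); `tbase_hat` itself is a nuisance. Ties, including a flat
#' correlation curve, resolve to the smallest grid point.
#'
#' @param phi_base numeric vector of baseline regional atrophy.
#' @param slopes numeric vector of observed regional atrophy slopes.
#' @param L a [build_laplacian()] object (connected graph).
#' @param beta0 reference diffusivity in 1/year (default 0.05).
#' @param grid increasing vector of positive candidate `t_base` values.
#' @return list with `tbase_hat`, `peak_correlation`, and `correlations`
#'   (the full curve; `NA` where undefined).
#' @export
estimate_tbase <- function(phi_base, slopes, L, beta0 = 0.05, grid = tbase_grid()) {
  if (any(grid <= 0) || any(diff(grid) <= 0)) stop("grid must be positive and increasing")
  if (beta0 <= 0) stop("beta0 must be positive")
  .check_single_zero_mode(L)
  n <- length(L$lambdas)
  if (length(phi_base) != n || length(slopes) != n) {
    stop("phi_base and slopes must match the Laplacian dimension")
  }
  w <- drop(crossprod(L$U, phi_base))
  # predicted-slope vectors for all grid points in one matrix product
  D <- vapply(grid, function(tt) .htilde_diag(L, beta0 * tt) * w, numeric(n))
  V <- beta0 * (L$U %*% D)          # n x length(grid)
  sd_s <- stats::sd(slopes)
  cors <- rep(NA_real_, length(grid))
  if (sd_s > 0) {
    keep <- apply(V, 2, stats::sd) > 0
    if (any(keep)) {
      cors[keep] <- drop(stats::cor(slopes, V[, keep, drop = FALSE]))
    }
  }
  if (all(is.na(cors))) {
    return(list(tbase_hat = grid[1], peak_correlation = NA_real_,
                correlations = cors, degenerate = TRUE))
  }
  best <- which.max(cors)           # first maximum -> smallest t on ties
  list(tbase_hat = grid[best], peak_correlation = cors[best],
       correlations = cors, degenerate = FALSE)
}

#' Estimate the diffusivity by scalar least squares
#'
#' Given the onset-time estimate, solves the one-parameter linear system
#' `slopes = beta * v` with `v = Htilde(beta0 tbase_hat) * phi_base` by the
#' pseudoinverse, `beta_hat = <v, slopes> / <v, v>`, clipped at 0 (negative
#' diffusivity is meaningless under the diffusion model).
#'
#' @inheritParams estimate_tbase
#' @param tbase_hat onset-time estimate in years, positive.
#' @return scalar `beta_hat` in 1/year.
#' @export
estimate_beta <- function(phi_base, slopes, L, beta0 = 0.05, tbase_hat) {
  if (tbase_hat <= 0) stop("tbase_hat must be positive")
  .check_single_zero_mode(L)
  d <- .htilde_diag(L, beta0 * tbase_hat)
  w <- drop(crossprod(L$U, phi_base))
  v <- drop(L$U %*% (d * w))
  vv <- sum(v * v)
  if (vv == 0) stop("degenerate baseline pattern: predicted slope vector is zero")
  max(0, sum(v * slopes) / vv)
}

#' Fit the Pathology Progression Rate for one subject
#'
#' Composes the three estimation steps exactly once: (1) per-region OLS
#' atrophy slopes with negative clipping; (2) onset-time grid search by
#' Pearson correlation at the reference diffusivity `beta0`; (3) scalar
#' least-squares diffusivity. The baseline atrophy vector is the observed
#' pattern at the first visit. Subjects whose slopes are all zero are
#' returned with `beta_hat = 0` and flagged `"non-progressor"`; fits at
#' either grid boundary are flagged `"grid-boundary"`.
#'
#' @param traj an [atrophy_trajectory()].
#' @param L a [build_laplacian()] object; labels must match the trajectory.
#' @param beta0 reference diffusivity in 1/year.
#' @param grid onset-time search grid (see [tbase_grid()]).
#' @param iterate if `TRUE`, repeat the onset/diffusivity steps once more
#'   with `beta0` replaced by the first-pass `beta_hat`. Off by default:
#'   one pass is sufficient in practice.
#' @return an object of class `ppr_fit` with `beta_hat`, `tbase_hat`,
#'   `peak_correlation`, `beta0`, `grid`, `n_clipped`, `flags`, `is_outlier`.
#' @export
fit_ppr <- function(traj, L, beta0 = 0.05, grid = tbase_grid(), iterate = FALSE) {
  stopifnot(inherits(traj, "atrophy_trajectory"), inherits(L, "laplacian"))
  if (!identical(traj$region_labels, L$labels)) {
    bad <- setdiff(traj$region_labels, L$labels)
    stop("region labels do not match the connectome",
         if (length(bad)) paste0("; unknown: ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  se <- fit_slopes(traj)
  phi_base <- traj$phi[1, ]
  flags <- character(0)
  if (all(se$slopes == 0)) {
    fit <- list(beta_hat = 0, tbase_hat = NA_real_, peak_correlation = NA_real_,
                beta0 = beta0, grid = grid, n_clipped = se$n_clipped,
                flags = "non-progressor", is_outlier = FALSE,
                subject_id = traj$subject_id)
    class(fit) <- "ppr_fit"
    return(fit)
  }
  tb <- estimate_tbase(phi_base, se$slopes, L, beta0 = beta0, grid = grid)
  if (isTRUE(tb$degenerate)) {
    beta_hat <- 0
    flags <- c(flags, "degenerate-correlation")
  } else {
    beta_hat <- estimate_beta(phi_base, se$slopes, L, beta0 = beta0,
                              tbase_hat = tb$tbase_hat)
    if (iterate && beta_hat > 0) {
      tb <- estimate_tbase(phi_base, se$slopes, L, beta0 = beta_hat, grid = grid)
      beta_hat <- estimate_beta(phi_base, se$slopes, L, beta0 = beta_hat,
                                tbase_hat = tb$tbase_hat)
      flags <- c(flags, "iterated")
    }
  }
  if (!is.na(tb$tbase_hat) &&
      (tb$tbase_hat <= grid[1] || tb$tbase_hat >= grid[length(grid)])) {
    flags <- c(flags, "grid-boundary")
  }
  structure(list(beta_hat = beta_hat, tbase_hat = tb$tbase_hat,
                 peak_correlation = tb$peak_correlation, beta0 = beta0,
                 grid = grid, n_clipped = se$n_clipped, flags = flags,
                 is_outlier = FALSE, subject_id = traj$subject_id),
            class = "ppr_fit")
}

#' @export
print.ppr_fit <- function(x, ...) {
  cat("PPR fit for subject", x$subject_id, "\n")
  cat("  beta_hat:", signif(x$beta_hat, 5), "per year\n")
  cat("  tbase_hat:", signif(x$tbase_hat, 5), "years (nuisance; beta0 *",
      "tbase_hat identifies beta * t_base)\n")
  cat("  peak correlation:", signif(x$peak_correlation, 4), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit PPR for every subject in a cohort and flag outliers
#'
#' @param trajectories list of [atrophy_trajectory()] objects.
#' @param L a [build_laplacian()] object.
#' @param groups optional per-subject group labels (e.g. diagnosis) used for
#'   group-wise outlier fencing; a single group when omitted.
#' @inheritParams fit_ppr
#' @return data.frame with one row per subject: `subject_id`, `beta_hat`,
#'   `tbase_hat`, `peak_correlation`, `n_clipped`, `is_outlier`, `flags`.
#' @export
fit_ppr_cohort <- function(trajectories, L, beta0 = 0.05, grid = tbase_grid(),
                           groups = NULL) {
  fits <- lapply(trajectories, fit_ppr, L = L, beta0 = beta0, grid = grid)
  out <- data.frame(
    subject_id = vapply(fits, `[[`, character(1), "subject_id"),
    beta_hat = vapply(fits, `[[`, numeric(1), "beta_hat"),
    tbase_hat = vapply(fits, `[[`, numeric(1), "tbase_hat"),
    peak_correlation = vapply(fits, `[[`, numeric(1), "peak_correlation"),
    n_clipped = vapply(fits, function(f) as.integer(f$n_clipped), integer(1)),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  if (is.null(groups)) groups <- rep("all", nrow(out))
  out$is_outlier <- flag_outliers(out$beta_hat, groups)
  out
}

#' Tukey-fence outlier flags within groups
#'
#' Within each group, values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are
#' flagged. Quartiles use linear interpolation of order statistics at index
#' `(n - 1) p` (the convention of [stats::quantile()] type 7). Groups with
#' fewer than 4 values are left unflagged with a warning, since quartile
#' fences are not meaningful there.
#'
#' @param values finite numeric vector.
#' @param groups group labels, same length as `values`.
#' @param k fence multiplier (default 1.5).
#' @return logical vector, `TRUE` where a value is an outlier in its group.
#' @export
flag_outliers <- function(values, groups, k = 1.5) {
  if (length(values) != length(groups)) stop("values and groups must have equal length")
  if (any(!is.finite(values))) stop("values must be finite")
  out <- logical(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 4) {
      warning("group '", g, "' has fewer than 4 values; no outliers flagged")
      next
    }
    q <- stats::quantile(values[idx], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out[idx] <- values[idx] < q[1] - k * iqr | values[idx] > q[2] + k * iqr
  }
  out
}
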