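#' Region labels for an 86-region whole-brain parcellation
#'
#' The canonical 68 cortical (34 per hemisphere) plus 18 subcortical region
#' names used as default labels for synthetic connectomes, so that seeding
#' by anatomical name (entorhinal cortex, hippocampus) works out of the box.
#'
#' @return character vector of 86 region labels.
#' @export
dk86_labels <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
                   "amygdala", "accumbens", "ventraldc", "cerebellum")
  c(paste0("ctx-lh-", cortical), paste0("ctx-rh-", cortical),
    paste0("lh-", subcortical), paste0("rh-", subcortical))
}

#' Generate a synthetic structural connectome
#'
#' Emulates the topology of tractography-derived connectomes: symmetric,
#' nonnegative, weighted, connected, and sparse (default 85% of off-diagonal
#' entries zero). Connectivity is guaranteed by first laying down a random
#' spanning tree, then adding random extra edges up to the edge budget
#' implied by the target sparsity; weights are log-normal, mimicking the
#' heavy-tailed streamline-count distribution.
#'
#' @param n_regions number of regions (default 86).
#' @param target_sparsity requested off-diagonal zero fraction (default 0.85).
#' @param seed integer RNG seed; same seed reproduces the same matrix.
#' @param labels region labels; defaults to [dk86_labels()] when
#'   `n_regions == 86`, generic `"R1..Rn"` otherwise.
#' @return a [connectome()].
#' @export
synth_connectome <- function(n_regions = 86, target_sparsity = 0.85,
                             seed = NULL, labels = NULL) {
  if (n_regions < 2) stop("need at least 2 regions")
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_regions * (n_regions - 1) / 2
  m <- round((1 - target_sparsity) * n_pairs)
  if (m < n_regions - 1) {
    stop("target sparsity ", target_sparsity, " leaves ", m,
         " edges; a connected graph on ", n_regions, " regions needs at least ",
         n_regions - 1)
  }
  # random spanning tree: attach each node to a uniformly chosen earlier node
  perm <- sample.int(n_regions)
  edges <- matrix(0L, nrow = m, ncol = 2)
  for (i in 2:n_regions) {
    j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    edges[i - 1L, ] <- c(perm[j], perm[i])
  }
  n_tree <- n_regions - 1L
  if (m > n_tree) {
    # sample extra distinct pairs not already in the tree
    pair_id <- function(a, b) {
      lo <- pmin(a, b); hi <- pmax(a, b)
      (lo - 1) * n_regions + hi
    }
    used <- pair_id(edges[seq_len(n_tree), 1], edges[seq_len(n_tree), 2])
    all_lo <- rep(seq_len(n_regions - 1), times = (n_regions - 1):1)
    all_hi <- unlist(lapply(seq_len(n_regions - 1), function(i) (i + 1):n_regions))
    free <- which(!(pair_id(all_lo, all_hi) %in% used))
    extra <- sample(free, m - n_tree)
    edges[(n_tree + 1):m, ] <- cbind(all_lo[extra], all_hi[extra])
  }
  w <- stats::rlnorm(m, meanlog = 0, sdlog = 1)
  C <- matrix(0, n_regions, n_regions)
  C[edges] <- w
  C[edges[, 2:1, drop = FALSE]] <- w
  if (is.null(labels)) {
    labels <- if (n_regions == 86) dk86_labels() else paste0("R", seq_len(n_regions))
  }
  connectome(C / sum(C), labels = labels)   # total-weight normalized, as canonical
}

#' Default pathology seeding pattern
#'
#' Unit pathology split across the canonical early-disease seed regions
#' (bilateral entorhinal cortex and hippocampus when present among the
#' labels), or across an explicit region set.
#'
#' @param labels connectome region labels.
#' @param seed_regions character vector of region names to seed; defaults to
#'   any label containing "entorhinal" or "hippocampus", falling back to the
#'   first region when none match.
#' @return numeric vector summing to 1 over the seeded regions.
#' @export
seed_pattern <- function(labels, seed_regions = NULL) {
  if (is.null(seed_regions)) {
    hit <- grepl("entorhinal|hippocampus", labels, ignore.case = TRUE)
    if (!any(hit)) hit <- seq_along(labels) == 1
  } else {
    hit <- labels %in% seed_regions
    if (!any(hit)) stop("no seed regions found among labels: ",
                        paste(seed_regions, collapse = ", "))
  }
  x0 <- as.numeric(hit)
  x0 / sum(x0)
}

#' Simulate one subject's longitudinal atrophy trajectory
#'
#' Forward-simulates the diffusion-and-accumulation model from a seeded
#' pathology pattern: observed atrophy at visit `j` is
#' `Phi(t_base + t_long[j])` plus additive Gaussian measurement noise with
#' standard deviation `noise_sd` times the root-mean-square of the noiseless
#' signal, floored at 0. The ground truth is returned alongside.
#'
#' @param L a [build_laplacian()] object.
#' @param beta true diffusivity in 1/year, positive.
#' @param t_base true years from pathology onset to baseline, positive.
#' @param visits numeric vector of visit times in years since baseline
#'   (first must be 0), or a single integer count n meaning `0:(n-1)` years.
#' @param noise_sd observation noise as a fraction of signal RMS (>= 0).
#' @param seed optional RNG seed.
#' @param x0 seeding pattern; defaults to [seed_pattern()] on the
#'   Laplacian's labels.
#' @param subject_id identifier for the trajectory.
#' @return list with `trajectory` (an [atrophy_trajectory()]) and `truth`
#'   (list of `beta`, `t_base`, `x0`).
#' @export
synth_subject <- function(L, beta, t_base, visits = 4, noise_sd = 0,
                          seed = NULL, x0 = NULL, subject_id = "S1") {
  if (beta <= 0 || t_base <= 0) stop("beta and t_base must be positive")
  if (length(visits) == 1 && visits >= 2) visits <- seq(0, visits - 1)
  if (length(visits) < 2) stop("need at least 2 visits")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- seed_pattern(L$labels)
  phi <- t(vapply(visits, function(tv) ndm_accumulate(L, x0, beta, t_base + tv),
                  numeric(length(x0))))
  if (noise_sd > 0) {
    rms <- sqrt(mean(phi^2))
    phi <- phi + stats::rnorm(length(phi), sd = noise_sd * rms)
    phi <- pmax(phi, 0)
  }
  list(trajectory = atrophy_trajectory(subject_id, visits, phi, L$labels),
       truth = list(beta = beta, t_base = t_base, x0 = x0))
}

#' Specification of a synthetic cohort
#'
#' Bundles the generator's study conditions: group sizes, per-group log-normal
#' diffusivity distributions, onset-time range, visit schedule, seeding,
#' observation noise, and the raw CSF cluster centroids.
#'
#' Default diffusivity medians 0.05 / 0.10 / 0.15 per year for the
#' EMCI / LMCI / AD-like groups (log-normal, sdlog 0.3) produce ordered,
#' separable groups at desk scale. CSF centroids are raw
#' (abeta, tau, ptau) triples in pg/ml ordered from least to most
#' pathogenic: the third cluster has low amyloid-beta and high tau/pTau,
#' the Alzheimer-type signature; ratios are derived from the raws so the
#' six-dimensional profile stays internally consistent.
#'
#' @param n_per_group subjects per diagnostic group.
#' @param groups group names, ordered by severity.
#' @param beta_medians per-group median diffusivity (1/year).
#' @param beta_sdlog log-normal dispersion of diffusivity.
#' @param t_base_range uniform range (years) for onset-to-baseline times.
#' @param visits visit times in years since baseline.
#' @param noise_sd observation noise fraction (of signal RMS).
#' @param seed_regions region names seeded with initial pathology (`NULL` =
#'   entorhinal + hippocampus).
#' @param csf_centroids 3 x 3 matrix, one row per cluster: raw abeta, tau,
#'   ptau centroids (pg/ml), least to most pathogenic.
#' @param csf_within_sd within-cluster standard deviations for the 3 raw
#'   biomarkers.
#' @param csf_control_mean,csf_control_sd control-cohort CSF distribution.
#' @param n_controls control subjects generated for z-scoring and volumes.
#' @param seed RNG seed for the whole cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(EMCI = 40, LMCI = 40, AD = 40),
                        groups = names(n_per_group),
                        beta_medians = c(0.05, 0.10, 0.15),
                        beta_sdlog = 0.3,
                        t_base_range = c(5, 20),
                        visits = c(0, 1, 2, 3),
                        noise_sd = 0.05,
                        seed_regions = NULL,
                        csf_centroids = rbind(c(190, 72, 35),
                                              c(160, 100, 47),
                                              c(130, 135, 60)),
                        csf_within_sd = c(10, 8, 4),
                        csf_control_mean = c(198, 68, 33),
                        csf_control_sd = c(30, 12, 6),
                        n_controls = 60,
                        seed = 1L) {
  if (is.null(groups)) groups <- paste0("G", seq_along(n_per_group))
  stopifnot(length(beta_medians) == length(n_per_group),
            all(n_per_group >= 1), beta_sdlog >= 0, noise_sd >= 0,
            length(t_base_range) == 2, t_base_range[1] > 0,
            nrow(csf_centroids) >= 1, ncol(csf_centroids) == 3)
  if (is.unsorted(beta_medians)) {
    stop("beta_medians must be ordered by group severity")
  }
  structure(list(n_per_group = n_per_group, groups = groups,
                 beta_medians = beta_medians, beta_sdlog = beta_sdlog,
                 t_base_range = t_base_range, visits = visits,
                 noise_sd = noise_sd, seed_regions = seed_regions,
                 csf_centroids = csf_centroids, csf_within_sd = csf_within_sd,
                 csf_control_mean = csf_control_mean,
                 csf_control_sd = csf_control_sd,
                 n_controls = n_controls, seed = seed),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws per-group diffusivities, forward-simulates every subject's
#' longitudinal atrophy on the given (or a freshly generated) connectome,
#' assigns each subject a CSF cluster and draws the raw biomarkers around
#' its centroid, and produces covariates whose distributions track the
#' diffusivity (APOE4 allele count probabilities increase with the subject's
#' diffusivity rank; MMSE decreases and FAQ increases with it). Everything
#' is deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param conn optional [connectome()]; generated via [synth_connectome()]
#'   from the spec seed when omitted.
#' @param laplacian_kind Laplacian normalization for the forward model.
#' @return list with `connectome`, `laplacian`, `trajectories` (list of
#'   [atrophy_trajectory()]), `atrophy_long` (long-format data.frame),
#'   `csf` (patients), `csf_controls`, `covariates`, `volumes`,
#'   `control_volumes`, `ground_truth`, `spec`.
#' @export
synth_cohort <- function(spec = cohort_spec(), conn = NULL,
                         laplacian_kind = "normalized") {
  set.seed(spec$seed)
  if (is.null(conn)) {
    conn <- synth_connectome(seed = spec$seed)
  }
  L <- build_laplacian(conn, kind = laplacian_kind)
  x0 <- seed_pattern(conn$labels, spec$seed_regions)
  n_groups <- length(spec$n_per_group)
  n_total <- sum(spec$n_per_group)
  group <- rep(spec$groups, times = spec$n_per_group)
  ids <- sprintf("SUBJ%04d", seq_len(n_total))

  beta_true <- unlist(lapply(seq_len(n_groups), function(g) {
    stats::rlnorm(spec$n_per_group[g],
                  meanlog = log(spec$beta_medians[g]), sdlog = spec$beta_sdlog)
  }))
  tbase_true <- stats::runif(n_total, spec$t_base_range[1], spec$t_base_range[2])

  trajectories <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    trajectories[[i]] <- synth_subject(L, beta_true[i], tbase_true[i],
                                       visits = spec$visits,
                                       noise_sd = spec$noise_sd, x0 = x0,
                                       subject_id = ids[i])$trajectory
  }
  names(trajectories) <- ids
  atrophy_long <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(subject_id = tr$subject_id,
               region = rep(tr$region_labels, each = length(tr$t_long)),
               t_years = rep(tr$t_long, times = length(tr$region_labels)),
               atrophy = as.vector(tr$phi),
               stringsAsFactors = FALSE)
  }))
  rownames(atrophy_long) <- NULL

  # CSF: cluster assignment independent of diagnosis, raw triples around
  # the assigned centroid, ratios derived downstream
  k <- nrow(spec$csf_centroids)
  csf_cluster <- sample.int(k, n_total, replace = TRUE)
  raw <- spec$csf_centroids[csf_cluster, , drop = FALSE] +
    matrix(stats::rnorm(n_total * 3), n_total, 3) %*% diag(spec$csf_within_sd)
  raw <- pmax(raw, 1)   # concentrations stay positive
  csf <- data.frame(subject_id = ids, abeta = raw[, 1], tau = raw[, 2],
                    ptau = raw[, 3], stringsAsFactors = FALSE)
  ctrl_raw <- matrix(stats::rnorm(spec$n_controls * 3), spec$n_controls, 3) %*%
    diag(spec$csf_control_sd) +
    matrix(spec$csf_control_mean, spec$n_controls, 3, byrow = TRUE)
  ctrl_raw <- pmax(ctrl_raw, 1)
  csf_controls <- data.frame(subject_id = sprintf("CON%04d", seq_len(spec$n_controls)),
                             abeta = ctrl_raw[, 1], tau = ctrl_raw[, 2],
                             ptau = ctrl_raw[, 3], stringsAsFactors = FALSE)

  # covariates: APOE4 count, MMSE, FAQ all tied to the diffusivity rank
  r <- (rank(beta_true) - 0.5) / n_total
  p2 <- 0.03 + 0.22 * r
  p1 <- 0.20 + 0.20 * r
  u <- stats::runif(n_total)
  apoe4 <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  mmse <- pmin(30, pmax(0, round(29 - 28 * beta_true + stats::rnorm(n_total, sd = 1.5))))
  faq <- pmin(30, pmax(0, round(60 * beta_true + stats::rnorm(n_total, sd = 2))))
  covariates <- data.frame(subject_id = ids, diagnosis = group,
                           apoe4_count = apoe4, mmse = mmse, faq = faq,
                           stringsAsFactors = FALSE)

  # baseline regional volumes: control-like scale minus deficit per unit atrophy
  base_atrophy <- t(vapply(trajectories, function(tr) tr$phi[1, ],
                           numeric(conn$n_regions)))
  base_scaled <- base_atrophy / max(mean(base_atrophy), 1e-12)
  volumes <- 100 - 5 * base_scaled +
    matrix(stats::rnorm(n_total * conn$n_regions, sd = 2), n_total)
  colnames(volumes) <- conn$labels
  rownames(volumes) <- ids
  control_volumes <- matrix(stats::rnorm(spec$n_controls * conn$n_regions,
                                         mean = 100, sd = 2), spec$n_controls)
  colnames(control_volumes) <- conn$labels
  rownames(control_volumes) <- csf_controls$subject_id

  ground_truth <- data.frame(subject_id = ids, group = group,
                             beta_true = beta_true, t_base_true = tbase_true,
                             csf_cluster_true = csf_cluster,
                             stringsAsFactors = FALSE)
  list(connectome = conn, laplacian = L, trajectories = trajectories,
       atrophy_long = atrophy_long, csf = csf, csf_controls = csf_controls,
       covariates = covariates, volumes = volumes,
       control_volumes = control_volumes, ground_truth = ground_truth,
       spec = spec)
}

#' Rebuild trajectory objects from a long-format atrophy table
#'
#' @param df data.frame with columns `subject_id`, `region`, `t_years`,
#'   `atrophy`.
#' @param region_labels connectome region ordering the trajectories must
#'   follow; unknown regions in `df` are an error.
#' @return named list of [atrophy_trajectory()] objects.
#' @export
trajectories_from_long <- function(df, region_labels) {
  need <- c("subject_id", "region", "t_years", "atrophy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atrophy table missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$region), region_labels)
  if (length(unknown)) {
    stop("unknown region label(s) not in connectome: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    tl <- sort(unique(d$t_years))
    phi <- matrix(NA_real_, length(tl), length(region_labels))
    ri <- match(d$region, region_labels)
    ti <- match(d$t_years, tl)
    phi[cbind(ti, ri)] <- d$atrophy
    if (anyNA(phi)) {
      stop("subject ", d$subject_id[1], ": incomplete region x visit grid")
    }
    atrophy_trajectory(d$subject_id[1], tl, phi, region_labels)
  })
  out[unique(df$subject_id)]
}
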