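#' Construct a connectome object
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal region-by-region
#' structural connectivity matrix together with an ordered vector of region
#' labels. All diffusion computations in the package are defined on this
#' object. Asymmetric input (e.g. raw streamline counts where the i-to-j and
#' j-to-i counts differ) is symmetrized by averaging with its transpose, with
#' a warning.
#'
#' @param C square numeric matrix of nonnegative connectivity weights.
#' @param labels character vector of region names, one per row of `C`.
#'   Defaults to rownames of `C`, or `"R1".."Rn"` when absent.
#' @param symmetrize_tol asymmetry above this (max absolute difference from
#'   the transpose) triggers symmetrization with a warning.
#' @return an object of class `connectome` with fields `C`, `labels`,
#'   `n_regions`.
#' @export
connectome <- function(C, labels = NULL, symmetrize_tol = 1e-10) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) {
    stop("connectivity matrix must be square, got ", nrow(C), " x ", ncol(C))
  }
  if (!is.numeric(C) || anyNA(C)) stop("connectivity matrix must be numeric with no NA")
  if (any(C < 0)) stop("connectivity weights must be nonnegative")
  n <- nrow(C)
  if (is.null(labels)) labels <- rownames(C)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") does not match matrix dimension (", n, ")")
  }
  asym <- max(abs(C - t(C)))
  if (asym > symmetrize_tol) {
    warning("asymmetric connectivity (max |C - t(C)| = ", signif(asym, 3),
            "); symmetrizing as (C + t(C))/2")
    C <- (C + t(C)) / 2
  } else {
    C <- (C + t(C)) / 2   # remove numerical residue
  }
  diag(C) <- 0
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, labels = labels, n_regions = n), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome:", x$n_regions, "regions\n")
  cat("  sparsity (off-diagonal zero fraction):",
      round(connectome_sparsity(x), 4), "\n")
  cat("  total weight:", signif(sum(x$C), 6), "\n")
  invisible(x)
}

#' Off-diagonal zero fraction of a connectome
#'
#' @param conn a `connectome`.
#' @return fraction of off-diagonal entries equal to zero.
#' @export
connectome_sparsity <- function(conn) {
  n <- conn$n_regions
  off <- conn$C[row(conn$C) != col(conn$C)]
  sum(off == 0) / (n * (n - 1))
}

#' Average a set of connectivity matrices into a canonical connectome
#'
#' Each subject matrix is first normalized by its total weighted streamline
#' count (the sum of all entries), removing inter-subject variance in total
#' fibre count, then the entrywise mean is taken and the result symmetrized.
#'
#' @param matrices list of square nonnegative numeric matrices, all of the
#'   same dimension.
#' @param labels optional region labels for the result.
#' @return a `connectome`.
#' @export
average_connectomes <- function(matrices, labels = NULL) {
  if (!is.list(matrices) || length(matrices) == 0) {
    stop("need a non-empty list of matrices")
  }
  dims <- vapply(matrices, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[1, 1])) stop("all matrices must be square with identical dimension")
  n <- dims[1, 1]
  acc <- matrix(0, n, n)
  for (m in matrices) {
    m <- as.matrix(m)
    if (any(m < 0)) stop("connectivity weights must be nonnegative")
    w <- sum(m)
    if (w <= 0) stop("matrix with zero total weight cannot be normalized")
    acc <- acc + m / w
  }
  M <- acc / length(matrices)
  M <- (M + t(M)) / 2
  if (is.null(labels) && !is.null(rownames(matrices[[1]]))) {
    labels <- rownames(matrices[[1]])
  }
  connectome(M, labels = labels)
}

#' Threshold a connectome to a target sparsity
#'
#' Zeroes the smallest off-diagonal weights (symmetrically, both `(i,j)` and
#' `(j,i)`) until the fraction of zero off-diagonal entries is at least
#' `target_sparsity`, using the smallest threshold that achieves it. Warns,
#' but does not fail, if the thresholded graph becomes disconnected.
#'
#' @param conn a `connectome`.
#' @param target_sparsity requested off-diagonal zero fraction in `[0, 1]`.
#' @return a new `connectome`.
#' @export
threshold_connectome <- function(conn, target_sparsity) {
  stopifnot(inherits(conn, "connectome"))
  if (!is.numeric(target_sparsity) || length(target_sparsity) != 1 ||
      target_sparsity < 0 || target_sparsity > 1) {
    stop("target_sparsity must be a single number in [0, 1]")
  }
  C <- conn$C
  n <- conn$n_regions
  if (target_sparsity == 0) return(conn)
  # work on the upper triangle; each zeroed pair removes 2 off-diagonal entries
  ut <- upper.tri(C)
  w <- C[ut]
  n_off_pairs <- length(w)
  n_zero_needed <- ceiling(target_sparsity * n_off_pairs)
  n_zero_now <- sum(w == 0)
  if (n_zero_now < n_zero_needed) {
    pos <- sort(w[w > 0])
    cut <- pos[n_zero_needed - n_zero_now]   # smallest threshold reaching target
    C[C <= cut & row(C) != col(C)] <- 0
  }
  out <- connectome(C, labels = conn$labels)
  if (.n_components(out$C) > 1) {
    warning("thresholding to sparsity ", target_sparsity,
            " disconnected the graph (", .n_components(out$C), " components)")
  }
  out
}

# connected components by breadth-first traversal on the nonzero pattern
.n_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  k
}

#' Read a connectome from delimited text
#'
#' Accepts a square numeric matrix in comma- or tab-delimited text, with an
#' optional header row of region labels, and an optional separate labels file
#' (one label per line). Lines starting with `#` are ignored.
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to a one-label-per-line file.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return a `connectome`.
#' @export
read_connectome <- function(path, labels_path = NULL, sep = NULL) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (is.null(sep)) sep <- .detect_sep(lines[1])
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  labels <- NULL
  if (has_header) {
    labels <- trimws(first)
    lines <- lines[-1]
  }
  rows <- strsplit(lines, sep, fixed = TRUE)
  n <- length(rows)
  first_field_label <- FALSE
  if (length(rows[[1]]) == n + 1) {
    # row-name column present
    first_field_label <- TRUE
    if (has_header && length(labels) == n + 1) labels <- labels[-1]
  }
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (first_field_label) f <- f[-1]
    if (length(f) != n) stop("row ", i, " has ", length(f), " fields; expected ", n)
    C[i, ] <- as.numeric(f)
  }
  if (anyNA(C)) stop("non-numeric entries in connectome matrix")
  if (!is.null(labels_path)) {
    labels <- trimws(readLines(labels_path))
    labels <- labels[nzchar(labels)]
  }
  connectome(C, labels = labels)
}

#' Write a connectome as delimited text
#'
#' @param conn a `connectome`.
#' @param path output path.
#' @param sep field delimiter.
#' @param header_comments optional character vector written as `#` comments.
#' @export
write_connectome <- function(conn, path, sep = ",", header_comments = NULL) {
  stopifnot(inherits(conn, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) writeLines(paste0("# ", header_comments), con)
  writeLines(paste(conn$labels, collapse = sep), con)
  apply_rows <- apply(conn$C, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                                   collapse = sep))
  writeLines(apply_rows, con)
  invisible(path)
}

.detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))) "\t" else ","
}
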