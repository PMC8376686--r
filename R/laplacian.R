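#' Build a graph Laplacian with cached eigendecomposition
#'
#' Constructs the network Laplacian `H` from a connectome, either
#' unnormalized (`H = D - C`) or symmetric-normalized
#' (`H = I - D^(-1/2) C D^(-1/2)`), where `D = diag(row sums of C)`.
#' The full eigendecomposition `H = U diag(lambda) U'` is computed once and
#' cached; all diffusion operators in the package work spectrally from this
#' single decomposition. Eigenvalues are clipped at 0 from below and sorted
#' ascending; an eigenvalue is counted as a zero mode when it is below
#' `zero_tol` times the largest eigenvalue.
#'
#' @param conn a [connectome()].
#' @param kind `"normalized"` (symmetric-normalized, the default) or
#'   `"unnormalized"`.
#' @param zero_tol relative tolerance below which an eigenvalue counts as a
#'   zero mode.
#' @return an object of class `laplacian` with fields `H`, `kind`, `U`,
#'   `lambdas`, `n_zero_modes`, `labels`.
#' @export
build_laplacian <- function(conn, kind = c("normalized", "unnormalized"),
                            zero_tol = 1e-8) {
  stopifnot(inherits(conn, "connectome"))
  kind <- match.arg(kind)
  C <- conn$C
  deg <- rowSums(C)
  if (kind == "unnormalized") {
    H <- diag(deg) - C
  } else {
    isolated <- which(deg <= 0)
    if (length(isolated)) {
      stop("isolated region(s) with zero degree under normalized Laplacian: ",
           paste(conn$labels[isolated], collapse = ", "))
    }
    dinv <- 1 / sqrt(deg)
    H <- diag(conn$n_regions) - (dinv * C) %*% diag(dinv)
  }
  H <- (H + t(H)) / 2
  dimnames(H) <- list(conn$labels, conn$labels)
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  lambdas <- pmax(e$values[ord], 0)
  U <- e$vectors[, ord, drop = FALSE]
  lmax <- max(lambdas)
  nz <- if (lmax > 0) sum(lambdas < zero_tol * lmax) else length(lambdas)
  structure(list(H = H, kind = kind, U = U, lambdas = lambdas,
                 n_zero_modes = nz, zero_tol = zero_tol,
                 labels = conn$labels),
            class = "laplacian")
}

#' @export
print.laplacian <- function(x, ...) {
  cat("Graph Laplacian (", x$kind, "): ", length(x$lambdas), " regions\n", sep = "")
  cat("  eigenvalue range: [", signif(min(x$lambdas), 4), ", ",
      signif(max(x$lambdas), 4), "]\n", sep = "")
  cat("  zero modes:", x$n_zero_modes, "\n")
  invisible(x)
}

.check_single_zero_mode <- function(L) {
  if (L$n_zero_modes != 1L) {
    stop("operation requires a connected graph (exactly one Laplacian zero mode); ",
         "found ", L$n_zero_modes)
  }
}
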