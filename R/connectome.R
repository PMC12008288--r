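#' Construct a structural connectome object
#'
#' Wraps a weighted, symmetric, nonnegative adjacency matrix (typically
#' normalized streamline counts between parcels) together with region labels
#' and a network assignment (seven canonical cortical networks plus a
#' subcortical compartment).
#'
#' @param weights N x N numeric matrix; nonnegative, zero diagonal. Small
#'   asymmetries (max abs difference <= 1e-8) are averaged away; larger
#'   asymmetries are an error.
#' @param region_labels character vector of length N.
#' @param network_assignment character vector of length N mapping each region
#'   to a network name (e.g. one of the seven Yeo networks or "Subcortex").
#'   Defaults to a single "whole-brain" network.
#' @return An object of class `structural_connectome` with elements
#'   `weights`, `region_labels`, `network_assignment`.
#' @export
structural_connectome <- function(weights, region_labels = NULL,
                                  network_assignment = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome matrix must be square, got ", nrow(weights), " x ",
         ncol(weights))
  }
  n <- nrow(weights)
  if (n < 2) stop("connectome needs at least 2 regions")
  storage.mode(weights) <- "double"
  if (any(!is.finite(weights))) stop("connectome contains non-finite weights")
  if (any(weights < 0)) stop("negative weight in connectome matrix")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8) {
    stop("connectome asymmetry ", format(asym),
         " exceeds tolerance 1e-8; refusing to symmetrize silently")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- if (!is.null(rownames(weights))) rownames(weights)
                     else sprintf("region%03d", seq_len(n))
  }
  if (length(region_labels) != n) {
    stop("label/matrix size mismatch: ", length(region_labels),
         " labels for ", n, " regions")
  }
  if (is.null(network_assignment)) {
    network_assignment <- rep("whole-brain", n)
  }
  if (length(network_assignment) != n) {
    stop("network assignment length mismatch")
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(
    list(weights = weights,
         region_labels = as.character(region_labels),
         network_assignment = as.character(network_assignment)),
    class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nets <- table(x$network_assignment)
  cat("structural_connectome:", n, "regions,",
      sum(x$weights[upper.tri(x$weights)] > 0), "nonzero edges\n")
  cat("networks:", paste(names(nets), nets, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Load a structural connectome from delimited text files
#'
#' The matrix file may be tab- or comma-delimited, with or without a header
#' row; the dialect is auto-detected. The labels file is a delimited table
#' with columns `region` and `network`.
#'
#' @param path path to square numeric matrix file.
#' @param labels_path optional path to a region/network table.
#' @return `structural_connectome`
#' @export
load_connectome <- function(path, labels_path = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  # header present iff first row fails to parse as all-numeric
  toks <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(toks))))
  m <- utils::read.table(path, sep = sep, header = header,
                         row.names = NULL, check.names = FALSE)
  if (!is.numeric(as.matrix(m[, vapply(m, is.numeric, logical(1))])) ||
      !all(vapply(m, is.numeric, logical(1)))) {
    # allow a leading label column
    if (!is.numeric(m[[1]])) {
      rn <- m[[1]]
      m <- m[, -1, drop = FALSE]
      rownames(m) <- rn
    }
  }
  w <- as.matrix(m)
  if (nrow(w) != ncol(w)) stop("non-square matrix in ", path)
  labels <- NULL; networks <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("region", "network") %in% names(lab))) {
      stop("labels file must have columns 'region' and 'network'")
    }
    if (nrow(lab) != nrow(w)) {
      stop("label/matrix size mismatch: ", nrow(lab), " vs ", nrow(w))
    }
    labels <- lab$region
    networks <- lab$network
  }
  structural_connectome(w, region_labels = labels,
                        network_assignment = networks)
}

#' Stabilize a connectome into a continuous-time dynamics operator
#'
#' Builds the system matrix `A_s = W / (lambda_max(W) + c) - I`, which is
#' Hurwitz-stable for any `c > 0` (all eigenvalues have strictly negative
#' real part). This normalization is the standard one in the continuous-time
#' network-control literature; `c` controls the decay rate of the slowest
#' mode, `-c / (lambda_max + c)`.
#'
#' @param sc `structural_connectome` (or a bare symmetric nonnegative matrix).
#' @param c positive stabilization constant (default 1).
#' @return object of class `system_matrix` with elements `A` (the stabilized
#'   operator), `c`, `lambda_max`, and eigendecomposition `evalues`,
#'   `evectors` (used internally for fast matrix-exponential propagation).
#' @export
stabilize <- function(sc, c = 1) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("c must be > 0")
  w <- if (inherits(sc, "structural_connectome")) sc$weights else as.matrix(sc)
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  if (any(w < 0)) stop("weights must be nonnegative")
  eig <- eigen(w, symmetric = TRUE)
  lmax <- eig$values[1]
  A <- w / (lmax + c) - diag(nrow(w))
  structure(
    list(A = A, c = c, lambda_max = lmax,
         evalues = eig$values / (lmax + c) - 1,
         evectors = eig$vectors),
    class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat("system_matrix:", nrow(x$A), "x", ncol(x$A),
      "| eigenvalues in [", format(min(x$evalues), digits = 4), ",",
      format(max(x$evalues), digits = 4), "] | c =", x$c, "\n")
  invisible(x)
}
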