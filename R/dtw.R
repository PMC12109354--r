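as_seq <- function(x) {
  if (inherits(x, "signal_trace")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) < 1L) stop("sequence must have length >= 1")
  if (anyNA(x)) stop("sequence contains missing values")
  x
}

#' Pointwise squared-difference cost matrix
#'
#' Entry `(i, j)` is `(x[i] - y[j])^2`, the local alignment cost of the
#' warping recursion. (The squared difference is used throughout; summed
#' along a path it is a squared Euclidean alignment cost.)
#'
#' @param x,y numeric sequences (or [signal_trace]s) of length >= 1.
#' @return An `n x m` numeric matrix.
#' @examples
#' cost_matrix(c(1, 2), c(2, 4))
#' @export
cost_matrix <- function(x, y) {
  x <- as_seq(x)
  y <- as_seq(y)
  outer(x, y, function(a, b) (a - b)^2)
}

#' Cumulative alignment-cost matrix
#'
#' Dynamic-programming accumulation of a cost matrix:
#' `C(i,j) = D(i,j) + min(C(i-1,j), C(i,j-1), C(i-1,j-1))` with
#' `C(1,1) = D(1,1)`; the first row and column accumulate along their only
#' admissible predecessor.
#'
#' @param d a cost matrix as from [cost_matrix()].
#' @return A matrix of the same shape; every entry is finite and at least
#'   the corresponding cost entry.
#' @export
cumulative_matrix <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("cost matrix must be finite")
  n <- nrow(d); m <- ncol(d)
  C <- matrix(0, n, m)
  C[1, ] <- cumsum(d[1, ])
  if (n > 1) C[, 1] <- cumsum(d[, 1])
  if (n > 1 && m > 1)
    for (i in 2:n)
      for (j in 2:m)
        C[i, j] <- d[i, j] + min(C[i - 1, j], C[i, j - 1], C[i - 1, j - 1])
  C
}

#' Dynamic time warping distance between two sequences
#'
#' Classic unconstrained DTW with squared-difference local cost: finds the
#' monotone alignment path from `(1, 1)` to `(n, m)` minimizing the summed
#' cost, tolerating temporal distortion that a rigid pointwise comparison
#' would penalize. No warping window and no step weights are applied.
#'
#' For long inputs the optimal path matrix would be large; by default the
#' path is backtraced only when `n * m <= max_path_cells` and the result's
#' `path` is `NULL` otherwise (the distance is always exact).
#'
#' @param x,y numeric sequences or [signal_trace]s, length >= 1.
#' @param keep_path logical; force path backtracing on or off. Default
#'   (`NA`) keeps the path when `n * m <= max_path_cells`.
#' @param max_path_cells cell budget for the full cumulative matrix
#'   (default 4e6).
#' @return An object of class `dtw_result`: `distance` (summed squared
#'   differences along the optimal path), `norm_distance` (see
#'   [normalize_distance()]), `path` (two-column 1-based index matrix or
#'   `NULL`), `n`, `m`.
#' @examples
#' r <- dtw_distance(c(1, 2), c(2, 4))
#' r$distance        # 5
#' r$norm_distance   # 5 / (2 * 2)
#' @export
dtw_distance <- function(x, y, keep_path = NA, max_path_cells = 4e6) {
  x <- as_seq(x)
  y <- as_seq(y)
  n <- length(x); m <- length(y)
  want_path <- if (is.na(keep_path)) (as.double(n) * m) <= max_path_cells
               else isTRUE(keep_path)
  if (want_path) {
    if (as.double(n) * m > 2.5e8)
      stop("path backtracing on ", n, " x ", m,
           " cells exceeds the memory budget; use keep_path = FALSE")
    full <- dtw_full_cpp(x, y)
    res <- list(distance = full$distance,
                path = cbind(a = full$a, b = full$b), n = n, m = m)
  } else {
    res <- list(distance = dtw_cost_cpp(x, y), path = NULL, n = n, m = m)
  }
  res$norm_distance <- res$distance / (n + m)
  class(res) <- "dtw_result"
  res
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> n = %d, m = %d: distance = %g, normalized = %g%s\n",
              x$n, x$m, x$distance, x$norm_distance,
              if (is.null(x$path)) " (path not kept)"
              else sprintf(", path length %d", nrow(x$path))))
  invisible(x)
}

#' Length-normalize a DTW distance
#'
#' For the usual equal-length case this is `distance / (2n)`; for unequal
#' lengths the divisor generalizes to `n + m`, which degenerates to `2n`
#' when `n == m`. Normalization makes distances comparable across epoch
#' lengths.
#'
#' @param r a `dtw_result` from [dtw_distance()].
#' @return The normalized distance (non-negative scalar).
#' @export
normalize_distance <- function(r) {
  stopifnot(inherits(r, "dtw_result"))
  r$distance / (r$n + r$m)
}

#' Brute-force DTW by exhaustive path enumeration
#'
#' Recursively enumerates every monotone alignment path and returns the
#' minimum summed cost. Exponential in `n + m`; guarded at `n + m <= 20`.
#' Serves as an independent oracle for [dtw_distance()] in the test suite.
#'
#' @param x,y numeric sequences, with `length(x) + length(y) <= 20`.
#' @return The minimum cumulative squared-difference cost (scalar).
#' @export
brute_force_dtw <- function(x, y) {
  x <- as_seq(x)
  y <- as_seq(y)
  if (length(x) + length(y) > 20L)
    stop("brute-force enumeration is exponential; use dtw_distance() for ",
         "sequences with n + m > 20")
  brute_force_dtw_cpp(x, y)
}

#' Dump DTW matrices and path as delimited text (debugging aid)
#'
#' @param x,y numeric sequences (small).
#' @param dir output directory; created if needed.
#' @return Invisibly, the paths written (`cost.tsv`, `cumulative.tsv`,
#'   `path.tsv`).
#' @export
dump_dtw <- function(x, y, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- cost_matrix(x, y)
  C <- cumulative_matrix(d)
  r <- dtw_distance(x, y, keep_path = TRUE)
  paths <- file.path(dir, c("cost.tsv", "cumulative.tsv", "path.tsv"))
  write.table(d, paths[1], sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(C, paths[2], sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(r$path, paths[3], sep = "\t", row.names = FALSE,
              col.names = c("a", "b"))
  invisible(paths)
}
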