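#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr mutate select filter arrange group_by summarise ungroup
#'   bind_rows left_join across all_of row_number n pull rename
#' @importFrom purrr map map2 map_dbl map2_dbl imap pmap walk
#' @importFrom rlang abort warn .data
#' @importFrom stats cor quantile sd var prcomp lm coef t.test rnorm runif
#'   pt qt setNames
#' @importFrom utils head tail
NULL

# ---- symmetry / SPD checks ------------------------------------------------

#' Test a matrix for numerical symmetry
#'
#' Symmetry is judged relative to the largest magnitude entry:
#' `max |M - t(M)| <= tol * max|M|`.
#'
#' @param M A square numeric matrix.
#' @param tol Relative tolerance (default `1e-10`).
#' @return `TRUE` or `FALSE`.
#' @export
is_symmetric_matrix <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M)) return(FALSE)
  if (!all(is.finite(M))) return(FALSE)
  scale <- max(abs(M))
  if (scale == 0) return(TRUE)
  max(abs(M - t(M))) <= tol * scale
}

assert_symmetric <- function(M, arg = "M", tol = 1e-10) {
  if (!is.matrix(M) || !is.numeric(M)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(M) != ncol(M)) {
    abort(sprintf("`%s` must be square (got %d x %d).", arg, nrow(M), ncol(M)))
  }
  if (!all(is.finite(M))) {
    abort(sprintf("`%s` contains non-finite entries.", arg))
  }
  if (!is_symmetric_matrix(M, tol)) {
    abort(sprintf(
      "`%s` is not symmetric: max |M - t(M)| = %.3e exceeds %.1e * max|M|.",
      arg, max(abs(M - t(M))), tol
    ))
  }
  invisible(M)
}

symmetrize <- function(M) (M + t(M)) / 2

#' Test / assert positive definiteness
#'
#' A symmetric matrix is accepted as SPD when its smallest eigenvalue exceeds
#' `tol` times its largest eigenvalue (relative floor `1e-12`), so that
#' near-singular matrices are flagged rather than silently accepted.
#'
#' @param M A symmetric numeric matrix.
#' @param tol Relative eigenvalue tolerance.
#' @return `is_spd()` returns `TRUE`/`FALSE`; `assert_spd()` returns the
#'   matrix invisibly or signals an error naming the smallest eigenvalue.
#' @export
is_spd <- function(M, tol = 1e-12) {
  if (!is_symmetric_matrix(M)) return(FALSE)
  ev <- eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

#' @rdname is_spd
#' @param arg Argument name used in error messages.
#' @export
assert_spd <- function(M, arg = "M", tol = 1e-12) {
  assert_symmetric(M, arg)
  ev <- eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    abort(sprintf(
      "`%s` is not positive definite: smallest eigenvalue %.6e (largest %.6e). Regularize first, e.g. regularize(%s, lambda).",
      arg, min(ev), max(ev), arg
    ))
  }
  invisible(M)
}

# ---- regularization -------------------------------------------------------

#' Diagonal regularization of a covariance/correlation matrix
#'
#' Adds `lambda` to every main-diagonal entry, shifting all eigenvalues up by
#' `lambda`. This is the standard remedy for singular correlation matrices
#' (e.g. when a parcellation has more regions than time points) before any
#' manifold operation that requires strict positive definiteness.
#'
#' @param C A symmetric positive semidefinite matrix.
#' @param lambda Nonnegative scalar added to the diagonal.
#' @return The regularized matrix `C + lambda * I`, checked to be SPD.
#' @examples
#' regularize(diag(2), 1)          # diag(2, 2)
#' @export
regularize <- function(C, lambda) {
  assert_symmetric(C, "C")
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) || lambda < 0) {
    abort("`lambda` must be a single nonnegative finite number.")
  }
  out <- symmetrize(C) + diag(lambda, nrow(C))
  ev_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-12 * max(abs(diag(out)))) {
    abort(sprintf(
      "Regularized matrix is still singular (smallest eigenvalue %.6e); increase `lambda` (got %g).",
      ev_min, lambda
    ))
  }
  out
}

# ---- matrix functions on the SPD cone -------------------------------------

#' Matrix functions of an SPD matrix by eigendecomposition
#'
#' Computes `log`, `sqrt`, `inv_sqrt` or `exp` of a symmetric matrix through
#' its eigendecomposition `S = Q diag(d) t(Q)`, applying the scalar function
#' to the eigenvalues and recomposing. The result is explicitly symmetrized
#' (`(X + t(X))/2`) to bound floating-point asymmetry drift across chained
#' operations. For `log`, `sqrt` and `inv_sqrt` a nonpositive eigenvalue is an
#' error — eigenvalues are never clipped.
#'
#' @param S A symmetric matrix; SPD required except for `fn = "exp"`.
#' @param fn One of `"log"`, `"sqrt"`, `"inv_sqrt"`, `"exp"`.
#' @return A symmetric matrix of the same dimension.
#' @examples
#' spd_matfun(diag(c(4, 9)), "sqrt")   # diag(2, 3)
#' spd_matfun(diag(2), "log")          # zero matrix
#' @export
spd_matfun <- function(S, fn = c("log", "sqrt", "inv_sqrt", "exp")) {
  fn <- match.arg(fn)
  assert_symmetric(S, "S")
  eg <- eigen(symmetrize(S), symmetric = TRUE)
  d <- eg$values
  if (fn != "exp" && min(d) <= 0) {
    abort(sprintf(
      "spd_matfun(fn = \"%s\") requires positive eigenvalues; smallest is %.6e. Regularize the input instead of clipping.",
      fn, min(d)
    ))
  }
  fd <- switch(fn,
    log = log(d),
    sqrt = sqrt(d),
    inv_sqrt = 1 / sqrt(d),
    exp = exp(d)
  )
  symmetrize(eg$vectors %*% (fd * t(eg$vectors)))
}

spd_log <- function(S) spd_matfun(S, "log")
spd_sqrt <- function(S) spd_matfun(S, "sqrt")
spd_invsqrt <- function(S) spd_matfun(S, "inv_sqrt")
sym_exp <- function(S) spd_matfun(S, "exp")

# ---- AIRM geodesic distance -----------------------------------------------

#' Affine-invariant Riemannian (geodesic) distance between SPD matrices
#'
#' \deqn{d_G(A, B) = \| \log(A^{-1/2} B A^{-1/2}) \|_F}
#' equivalently `sqrt(sum(log(eigenvalues(solve(A) %*% B))^2))`. The metric is
#' symmetric in its arguments and invariant under congruence transformations
#' `M A t(M)` for any invertible `M`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @examples
#' geodesic_distance(diag(2), diag(c(exp(1), exp(1))))  # sqrt(2)
#' @export
geodesic_distance <- function(A, B) {
  assert_spd(A, "A")
  assert_spd(B, "B")
  if (!all(dim(A) == dim(B))) {
    abort(sprintf("Dimension mismatch: A is %d x %d, B is %d x %d.",
                  nrow(A), ncol(A), nrow(B), ncol(B)))
  }
  W <- spd_invsqrt(A)
  L <- spd_log(symmetrize(W %*% B %*% W))
  sqrt(sum(L^2))
}

# ---- tangent projection / retraction --------------------------------------

#' Project an SPD matrix onto the tangent space at a reference
#'
#' The whitened log map
#' \deqn{\hat S = \log(C_{ref}^{-1/2} \, S \, C_{ref}^{-1/2})}
#' sends an SPD functional connectome `S` to the Euclidean tangent space at
#' `C_ref`; the reference itself maps to the zero matrix. In these
#' coordinates the AIRM inner product at the reference is the ordinary
#' Frobenius one, so Euclidean distances between tangent images approximate
#' geodesic distances for matrices near the reference.
#'
#' @param S An SPD matrix (e.g. a regularized functional connectome).
#' @param C_ref The SPD reference matrix (e.g. a Karcher mean).
#' @param reference_id Optional identifier recorded on the output; defaults
#'   to a content-derived fingerprint of `C_ref` so that tangent matrices
#'   projected at different references are never silently compared.
#' @return A symmetric matrix with attribute `reference_id`.
#' @seealso [tangent_retract()] for the inverse map, [riemann_mean()].
#' @export
tangent_project <- function(S, C_ref, reference_id = NULL) {
  assert_spd(S, "S")
  assert_spd(C_ref, "C_ref")
  if (!all(dim(S) == dim(C_ref))) {
    abort("`S` and `C_ref` must have the same dimension.")
  }
  W <- spd_invsqrt(C_ref)
  out <- spd_log(symmetrize(W %*% S %*% W))
  attr(out, "reference_id") <- reference_id %||% reference_fingerprint(C_ref)
  out
}

#' Retract a tangent matrix back to the SPD manifold
#'
#' Inverse of [tangent_project()]:
#' \deqn{S = C_{ref}^{1/2} \exp(T) \, C_{ref}^{1/2}.}
#' `tangent_retract(tangent_project(S, C), C)` recovers `S` up to round-off.
#'
#' @param T_mat A symmetric tangent matrix.
#' @param C_ref The SPD reference at which `T_mat` lives.
#' @return An SPD matrix.
#' @export
tangent_retract <- function(T_mat, C_ref) {
  assert_symmetric(T_mat, "T_mat")
  assert_spd(C_ref, "C_ref")
  H <- spd_sqrt(C_ref)
  symmetrize(H %*% sym_exp(T_mat) %*% H)
}

reference_fingerprint <- function(C) {
  sprintf("spd-%dx%d-%s", nrow(C), ncol(C),
          format(sum(C) + sum(C * C) * 1e-3, digits = 17))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Karcher / Riemann mean -----------------------------------------------

#' Riemannian (Karcher) mean of SPD matrices
#'
#' Finds the SPD matrix minimizing the sum of squared AIRM geodesic distances
#' to the inputs, by fixed-point iteration: at the current estimate `C`,
#' average the tangent images `M = mean(log(C^{-1/2} S_i C^{-1/2}))` and
#' update `C <- C^{1/2} exp(M) C^{1/2}` until the gradient norm `||M||_F`
#' drops below `tol`. With a unit step this converges for well-conditioned
#' connectome sets; non-convergence raises an error carrying the last
#' gradient norm rather than returning a bad centroid.
#'
#' @param S_list Nonempty list of SPD matrices of a common dimension.
#' @param init Initial estimate: `"arithmetic"` (the elementwise mean,
#'   the usual initializer) or an explicit SPD matrix.
#' @param tol Convergence tolerance on the Frobenius norm of the mean tangent
#'   (default `1e-8`).
#' @param max_iter Maximum number of fixed-point iterations (default 200).
#' @return The Karcher mean, with attributes `iterations` and `grad_norm`.
#' @examples
#' riemann_mean(list(diag(c(1, 4)), diag(c(4, 1))))  # diag(2, 2)
#' @export
riemann_mean <- function(S_list, init = "arithmetic", tol = 1e-8, max_iter = 200) {
  if (!is.list(S_list) || length(S_list) == 0) {
    abort("`S_list` must be a nonempty list of SPD matrices.")
  }
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be > 0.")
  p <- nrow(S_list[[1]])
  for (i in seq_along(S_list)) {
    assert_spd(S_list[[i]], sprintf("S_list[[%d]]", i))
    if (nrow(S_list[[i]]) != p) abort("All matrices must share one dimension.")
  }
  if (length(S_list) == 1) {
    C <- symmetrize(S_list[[1]])
    attr(C, "iterations") <- 0L
    attr(C, "grad_norm") <- 0
    return(C)
  }
  C <- if (is.character(init) && identical(init, "arithmetic")) {
    symmetrize(Reduce(`+`, S_list) / length(S_list))
  } else {
    assert_spd(init, "init")
    symmetrize(init)
  }
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    W <- spd_invsqrt(C)
    H <- spd_sqrt(C)
    M <- Reduce(`+`, lapply(S_list, function(S) spd_log(symmetrize(W %*% S %*% W)))) /
      length(S_list)
    grad_norm <- sqrt(sum(M^2))
    if (grad_norm < tol) {
      attr(C, "iterations") <- iter - 1L
      attr(C, "grad_norm") <- grad_norm
      return(C)
    }
    C <- symmetrize(H %*% sym_exp(M) %*% H)
  }
  abort(sprintf(
    "Karcher mean did not converge in %d iterations; last gradient norm %.3e (tol %.1e).",
    max_iter, grad_norm, tol
  ))
}

# ---- TSV round-trip -------------------------------------------------------

#' Read / write a numeric matrix as TSV
#'
#' Matrices are stored as tab-separated text at 17 significant digits, the
#' precision at which an IEEE double round-trips bit-exactly. An optional
#' header row carries region labels.
#'
#' @param M Numeric matrix to write.
#' @param path File path.
#' @param col_names Logical: write/expect a header row of column labels.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(M, path, col_names = !is.null(colnames(M))) {
  if (!is.matrix(M) || !is.numeric(M)) abort("`M` must be a numeric matrix.")
  lines <- apply(M, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                         collapse = "\t"))
  if (col_names) {
    labs <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
    lines <- c(paste(labs, collapse = "\t"), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, col_names = NA) {
  first <- readLines(path, n = 1)
  has_header <- if (is.na(col_names)) {
    any(is.na(suppressWarnings(as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]]))))
  } else {
    isTRUE(col_names)
  }
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          check.names = FALSE, colClasses = "numeric")
  M <- as.matrix(df)
  if (has_header) rownames(M) <- NULL else dimnames(M) <- NULL
  M
}
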