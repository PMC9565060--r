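## Saaty's random consistency index, n = 1..15.
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

#' Random consistency index
#'
#' Saaty's random index RI used in the consistency ratio CR = CI / RI.
#'
#' @param n Matrix order, 1 to 15.
#' @return The RI value.
#' @export
saaty_ri <- function(n) {
  if (n < 1 || n > length(SAATY_RI))
    stop("random index is tabulated for orders 1..", length(SAATY_RI),
         " (got n = ", n, ")", call. = FALSE)
  SAATY_RI[n]
}

#' Construct a pairwise judgment matrix
#'
#' Validates a positive reciprocal pairwise-comparison matrix: square with
#' unit diagonal and `a_ij * a_ji = 1` within `1e-9`.  Entries are typically
#' drawn from the Saaty 1-9 scale and its reciprocals, but any positive
#' entries are accepted.
#'
#' @param m Numeric square matrix.
#' @param labels Optional element labels (defaults to existing dimnames).
#' @return The matrix with class `judgment_matrix`.
#' @export
judgment_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2 || ncol(m) != n)
    stop("judgment matrix must be square with n >= 2", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("judgment matrix entries must be positive", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-9))
    stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (any(abs(m * t(m) - 1) > 1e-9))
    stop("judgment matrix is not reciprocal (a_ij * a_ji != 1)",
         call. = FALSE)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  class(m) <- c("judgment_matrix", class(m))
  m
}

#' Principal-eigenvector priority weights
#'
#' Computes the normalized principal eigenvector of a positive reciprocal
#' judgment matrix by power iteration.  Positive matrices have a simple
#' dominant eigenvalue (Perron-Frobenius), so the iteration converges to the
#' priority vector; convergence is declared when the normalized vector moves
#' by less than `tol` in the max norm.
#'
#' @param A A [judgment_matrix()] (or a matrix passing its validation).
#' @param tol Convergence tolerance on the weight vector.
#' @param max_iter Iteration cap.
#' @return Nonnegative weight vector summing to 1, named after `A`'s rows.
#' @export
principal_weights <- function(A, tol = 1e-12, max_iter = 10000L) {
  if (!inherits(A, "judgment_matrix")) A <- judgment_matrix(A)
  n <- nrow(A)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w_new <- as.vector(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      names(w_new) <- rownames(A)
      return(w_new)
    }
    w <- w_new
  }
  stop("power iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Consistency test of a judgment matrix
#'
#' Computes the maximum characteristic root lambda_max = sum_k (A w)_k /
#' (n w_k), the consistency index CI = (lambda_max - n) / (n - 1), and the
#' consistency ratio CR = CI / RI against Saaty's random index.  A matrix is
#' acceptable when CR < 0.1; 2x2 reciprocal matrices are always consistent
#' (CR defined as 0).
#'
#' @param A A [judgment_matrix()].
#' @param w Priority vector; defaults to [principal_weights()] of `A`.
#' @return A `consistency_report`: list with `n`, `lambda_max`, `ci`, `ri`,
#'   `cr`, `acceptable`.
#' @export
consistency <- function(A, w = principal_weights(A)) {
  if (!inherits(A, "judgment_matrix")) A <- judgment_matrix(A)
  n <- nrow(A)
  lambda_max <- sum(as.vector(A %*% w) / (n * w))
  ci <- if (n > 1) (lambda_max - n) / (n - 1) else 0
  ri <- saaty_ri(n)
  cr <- if (n <= 2) 0 else ci / ri
  structure(list(n = n, lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 acceptable = cr < 0.1),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> n = %d, lambda_max = %.6f, CI = %.6f, RI = %.2f, CR = %.6f (%s)\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' Combine hierarchy levels into global leaf weights
#'
#' Multiplies each parent's weight into its children's within-parent weights,
#' yielding global weights over the leaves (each summing block preserves the
#' parent mass, so the result sums to 1).
#'
#' @param parent_w Named weight vector over parents, summing to 1.
#' @param child_w Named list mapping each parent id to its children's named
#'   weight vector (each summing to 1).
#' @return Named global weight vector over all leaves.
#' @export
combine_levels <- function(parent_w, child_w) {
  if (is.null(names(parent_w)))
    stop("parent weights must be named", call. = FALSE)
  check_weights(parent_w, "parent weights")
  out <- numeric(0)
  for (p in names(parent_w)) {
    cw <- child_w[[p]]
    if (is.null(cw))
      stop("no child weight vector for parent ", p, call. = FALSE)
    check_weights(cw, paste("child weights of", p))
    out <- c(out, parent_w[[p]] * cw)
  }
  out
}

check_weights <- function(w, what = "weights", tol = 1e-8) {
  if (any(w < -1e-12))
    stop(what, " contain negative entries", call. = FALSE)
  if (abs(sum(w) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  invisible(w)
}

#' Hierarchy-level (combined) consistency ratio
#'
#' Aggregate consistency of a set of child judgment matrices under parent
#' weights: the ratio of the parent-weighted CI to the parent-weighted RI.
#' This is the standard weighted-index convention for the combined test.
#'
#' @param parent_w Named parent weight vector.
#' @param reports Named list of `consistency_report` objects, one per parent.
#' @return List with `ci`, `ri`, `cr`, `acceptable`.
#' @export
hierarchy_consistency <- function(parent_w, reports) {
  reports <- reports[names(parent_w)]
  if (any(vapply(reports, is.null, logical(1))))
    stop("missing consistency report for a parent", call. = FALSE)
  ci <- sum(parent_w * vapply(reports, `[[`, numeric(1), "ci"))
  ri <- sum(parent_w * vapply(reports, `[[`, numeric(1), "ri"))
  cr <- if (ri > 0) ci / ri else 0
  list(ci = ci, ri = ri, cr = cr, acceptable = cr < 0.1)
}
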