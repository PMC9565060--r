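#' Min-max normalization of one indicator column
#'
#' Positive indicators use `(x - min) / (max - min)`; negative indicators use
#' `(max - x) / (max - min)`.  A constant column (max == min) carries no
#' discriminating information and is mapped to all 1s, which yields maximal
#' entropy and hence entropy weight 0.
#'
#' @param x Numeric vector of raw values over segments.
#' @param direction `"positive"` or `"negative"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_column <- function(x, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1, length(x)))
  if (direction == "positive") (x - rng[1]) / (rng[2] - rng[1])
  else (rng[2] - x) / (rng[2] - rng[1])
}

## Center of the ideal band of a bidirectional indicator (midpoint of its
## grade-I interval); used to fold bidirectional columns into distances.
bidirectional_center <- function(spec) {
  interval_midpoint(grade_branches(spec, "I")[[1]])
}

#' Normalize a segments-by-indicators data matrix
#'
#' Applies [normalize_column()] per indicator according to its direction.
#' Bidirectional indicators are first folded to the distance `|x - c|` from
#' the center `c` of their ideal band and then treated as negative
#' (closer to the band is better); categorical indicators are treated as
#' positive (higher category value is better).
#'
#' @param X Numeric matrix or data frame, segments in rows, indicator ids as
#'   column names.
#' @param system A `river_system` from [load_system()].
#' @return Normalized numeric matrix with values in `[0, 1]`.
#' @export
normalize_matrix <- function(X, system) {
  X <- as_data_matrix(X, system)
  R <- X
  for (id in colnames(X)) {
    spec <- system$indicators[[id]]
    x <- X[, id]
    if (spec$direction == "bidirectional") {
      x <- abs(x - bidirectional_center(spec))
      R[, id] <- normalize_column(x, "negative")
    } else if (spec$direction == "negative") {
      R[, id] <- normalize_column(x, "negative")
    } else {
      R[, id] <- normalize_column(x, "positive")
    }
  }
  R
}

## Validate and coerce a raw data matrix against the system.
as_data_matrix <- function(X, system) {
  if (is.data.frame(X)) {
    seg_col <- which(vapply(X, is.character, logical(1)))
    if (length(seg_col) == 1L) {
      rownames(X) <- X[[seg_col]]
      X <- X[, -seg_col, drop = FALSE]
    }
    X <- as.matrix(X)
  }
  if (!is.numeric(X)) stop("data matrix must be numeric", call. = FALSE)
  if (anyNA(X)) stop("data matrix has missing cells", call. = FALSE)
  ids <- indicator_ids(system)
  if (is.null(colnames(X)))
    stop("data matrix needs indicator ids as column names", call. = FALSE)
  missing <- setdiff(ids, colnames(X))
  unknown <- setdiff(colnames(X), ids)
  if (length(missing))
    stop("data matrix is missing indicators: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(unknown))
    stop("data matrix has unknown indicators: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  X[, ids, drop = FALSE]
}

#' Shifted-proportion entropy of normalized indicator columns
#'
#' For each indicator, proportions over the n segments are
#' `f_j = (1 + r_j) / sum_j (1 + r_j)` (the +1 shift keeps zero-normalized
#' cells in play), and the entropy is `H' = -sum f ln f / ln n`, so
#' `H'` lies in `[0, 1]` with 1 for a uniform (e.g. constant) column.
#'
#' @param R Normalized matrix from [normalize_matrix()] (segments x
#'   indicators, values in `[0, 1]`).
#' @return List with `proportions` (same shape as `R`) and `entropy`
#'   (per-indicator named vector).
#' @export
entropy_values <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n < 2)
    stop("entropy is undefined for fewer than 2 segments (ln 1 = 0)",
         call. = FALSE)
  if (any(R < -1e-12 | R > 1 + 1e-12))
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  f <- apply(R, 2, function(r) (1 + r) / sum(1 + r))
  H <- apply(f, 2, function(p) -sum(p * log(p)) / log(n))
  list(proportions = f, entropy = H)
}

#' Entropy weights from per-indicator entropy values
#'
#' `w_i = (1 - H'_i) / (m - sum H')` over the m indicators; weights are
#' nonnegative, sum to 1, and an indicator with maximal entropy (`H' = 1`,
#' e.g. a constant column) receives weight exactly 0.
#'
#' @param H Per-indicator entropy values in `[0, 1]`.
#' @return Named weight vector summing to 1.
#' @export
entropy_weights <- function(H) {
  if (any(H < -1e-9 | H > 1 + 1e-9))
    stop("entropy values must lie in [0, 1]", call. = FALSE)
  H <- pmin(pmax(H, 0), 1)
  denom <- length(H) - sum(H)
  if (denom <= 0)
    stop("all columns are constant: no information to weight", call. = FALSE)
  (1 - H) / denom
}

#' Entropy weighting of a raw data matrix
#'
#' Convenience wrapper running normalization, shifted-proportion entropy and
#' the entropy-weight formula in one step.
#'
#' @inheritParams normalize_matrix
#' @return An `entropy_result`: list with `normalized`, `proportions`,
#'   `entropy` and `weights`.
#' @export
entropy_weighting <- function(X, system) {
  R <- normalize_matrix(X, system)
  ev <- entropy_values(R)
  structure(list(normalized = R, proportions = ev$proportions,
                 entropy = ev$entropy, weights = entropy_weights(ev$entropy)),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result> ", nrow(x$normalized), " segments x ",
      ncol(x$normalized), " indicators\n", sep = "")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}
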