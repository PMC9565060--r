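## Which side of an extreme grade is its pole (the ideal point for grade I,
## the worst point for grade V), for single-branch indicators.
pole_side <- function(direction, grade) {
  stopifnot(grade %in% c("I", "V"))
  best_high <- direction %in% c("positive", "categorical")
  if (grade == "I") { if (best_high) "upper" else "lower" }
  else             { if (best_high) "lower" else "upper" }
}

## Finite width of the grade adjacent to an extreme grade (II for I, IV for
## V), used to borrow a scale for unbounded or single-point extreme grades.
## `branch` selects the corresponding branch for bidirectional indicators.
adjacent_width <- function(spec, grade, branch = 1L) {
  adj <- if (grade == "I") "II" else "IV"
  br <- grade_branches(spec, adj)
  iv <- br[[min(branch, length(br))]]
  w <- interval_width(iv)
  if (!is.finite(w) || w <= 0)
    stop("indicator ", spec$id, ": cannot borrow a width from grade ", adj,
         call. = FALSE)
  w
}

## Membership parameters for one interval branch.
branch_params <- function(spec, grade, iv, branch = 1L) {
  w <- interval_width(iv)
  if (grade %in% c("II", "III", "IV") && spec$direction != "categorical") {
    if (w == 0)
      stop("indicator ", spec$id, ": zero-width interior grade ", grade,
           call. = FALSE)
    if (!is.finite(w))
      stop("indicator ", spec$id, ": unbounded interior grade ", grade,
           call. = FALSE)
    return(list(a1 = interval_midpoint(iv), a2 = 4 / w^2, saturate = "none"))
  }
  if (spec$direction == "categorical")      # unit-width peak at the category
    return(list(a1 = iv$lower, a2 = 4, saturate = "none"))
  ## extreme grades I and V
  side <- if (spec$direction == "bidirectional") {
    if (grade == "I") return(list(a1 = interval_midpoint(iv),
                                  a2 = 4 / w^2, saturate = "none"))
    ## worst pole of each off-band branch is its outer endpoint
    if (branch == 1L) "lower" else "upper"
  } else pole_side(spec$direction, grade)
  if (is_unbounded(iv)) {
    bw <- adjacent_width(spec, grade, branch)
    fin <- if (is.infinite(iv$upper)) iv$lower else iv$upper
    a1 <- if (side == "upper") fin + bw else fin - bw
    return(list(a1 = a1, a2 = 4 / bw^2,
                saturate = if (side == "upper") "above" else "below"))
  }
  if (w == 0) {                             # single-point extreme grade
    bw <- adjacent_width(spec, grade, branch)
    return(list(a1 = iv$lower, a2 = 4 / bw^2,
                saturate = if (side == "upper") "above" else "below"))
  }
  a1 <- if (side == "upper") iv$upper else iv$lower
  list(a1 = a1, a2 = 4 / w^2,
       saturate = if (side == "upper") "above" else "below")
}

#' Cauchy membership parameters of a grade
#'
#' Derives the parameters `(a1, a2)` of the Cauchy-shaped membership function
#' `r(x) = 1 / (1 + a2 (x - a1)^2)` for one grade of one indicator.  Interior
#' grades (II-IV) peak at the interval midpoint with `a2 = 4 / width^2`, so
#' the membership is exactly 0.5 at both interval boundaries.  Extreme grades
#' (I and V) peak at their pole endpoint - the ideal point for grade I and
#' the worst point for grade V, as oriented by the indicator direction - and
#' saturate at 1 beyond the pole.  Unbounded and single-point extreme grades
#' borrow their width from the adjacent grade; categorical indicators use a
#' unit-width peak at each category value.  Bidirectional indicators get one
#' parameter set per interval branch.
#'
#' @param spec An [indicator_spec()].
#' @param grade Grade label `"I"`..`"V"`.
#' @return A `membership_params` object: list with `grade` and `branches`, a
#'   list of `(a1, a2, saturate)` triples where `saturate` is `"none"`,
#'   `"above"` or `"below"`.
#' @export
cauchy_params <- function(spec, grade) {
  grade <- match.arg(grade, GRADES)
  br <- grade_branches(spec, grade)
  branches <- lapply(seq_along(br), function(k)
    branch_params(spec, grade, br[[k]], k))
  structure(list(grade = grade, branches = branches),
            class = "membership_params")
}

branch_membership <- function(x, p) {
  if (p$saturate == "above" && x >= p$a1) return(1)
  if (p$saturate == "below" && x <= p$a1) return(1)
  1 / (1 + p$a2 * (x - p$a1)^2)
}

#' Five-grade membership vector of a value
#'
#' Evaluates the Cauchy membership of `x` in each of the five grades of an
#' indicator (taking the maximum over interval branches for bidirectional
#' indicators).  `x` must lie in the indicator's graded domain.
#'
#' @param x Numeric value in indicator units.
#' @param spec An [indicator_spec()].
#' @return Named numeric vector of 5 memberships in `(0, 1]`.
#' @export
membership_vector <- function(x, spec) {
  classify_crisp(x, spec)   # domain validation
  r <- vapply(GRADES, function(g) {
    p <- cauchy_params(spec, g)
    max(vapply(p$branches, function(b) branch_membership(x, b), numeric(1)))
  }, numeric(1))
  r
}

#' Affiliation matrix of one segment
#'
#' Stacks the [membership_vector()] of each indicator value into the
#' indicators x grades affiliation matrix R of a single river segment.
#'
#' @param values Named numeric vector, one value per system indicator.
#' @param system A `river_system`.
#' @return Numeric matrix (indicators x 5 grades) with rows in system order.
#' @export
build_affiliation <- function(values, system) {
  ids <- indicator_ids(system)
  if (is.null(names(values))) {
    if (length(values) != length(ids))
      stop("unnamed value vector of wrong length", call. = FALSE)
    names(values) <- ids
  }
  missing <- setdiff(ids, names(values))
  if (length(missing))
    stop("missing values for indicators: ",
         paste(missing, collapse = ", "), call. = FALSE)
  R <- t(vapply(ids, function(id)
    membership_vector(values[[id]], system$indicators[[id]]),
    numeric(length(GRADES))))
  dimnames(R) <- list(ids, GRADES)
  R
}

## Worst grade among the argmax set (conservative tie-break).
argmax_grade <- function(d) GRADES[max(which(d == max(d)))]

#' Compose an affiliation matrix with a weight vector
#'
#' Weighted-average composition `D = W . R` (ordinary matrix product; the
#' standard operator when `W` sums to 1, preserving every indicator's
#' influence), or the max-min operator `D_g = max_i min(W_i, R_ig)` for
#' comparison.  The grade is assigned by maximum affiliation; exact ties go
#' to the worse (higher-numbered) grade.
#'
#' @param W Weight vector over the rows of `R`, summing to 1.
#' @param R Affiliation matrix (rows x 5 grades).
#' @param operator `"weighted_average"` (default) or `"max_min"`.
#' @param layer Label stored on the result (`"indicator"`, `"criterion"`,
#'   `"target"`).
#' @return An `evaluation_vector`: list with `memberships` (length 5),
#'   `normalized` (memberships scaled to sum 1), `grade` and `layer`.
#' @export
fuzzy_compose <- function(W, R,
                          operator = c("weighted_average", "max_min"),
                          layer = "target") {
  operator <- match.arg(operator)
  R <- as.matrix(R)
  if (length(W) != nrow(R))
    stop("weight vector length ", length(W), " does not match ", nrow(R),
         " affiliation rows", call. = FALSE)
  check_weights(W, "composition weights", tol = 1e-6)
  D <- if (operator == "weighted_average") as.vector(W %*% R)
       else apply(R, 2, function(col) max(pmin(W, col)))
  names(D) <- colnames(R)
  structure(list(memberships = D, normalized = D / sum(D),
                 grade = argmax_grade(D), layer = layer,
                 operator = operator),
            class = "evaluation_vector")
}

#' @export
print.evaluation_vector <- function(x, digits = 4, ...) {
  cat("<evaluation_vector> layer ", x$layer, ", grade ", x$grade, "\n",
      sep = "")
  print(round(x$memberships, digits))
  invisible(x)
}

#' Layer-wise fuzzy evaluation of one segment
#'
#' Runs the full fuzzy evaluation of a single river segment: the indicator
#' layer assigns each indicator the grade of maximum membership; the
#' criterion layer composes each criterion's member rows with its fused
#' indicator weights renormalized within the criterion; the target layer
#' composes all rows with the global fused weights.
#'
#' @param values Named numeric vector of indicator values for one segment.
#' @param weights Named fused weight vector over all indicators (sum 1).
#' @param system A `river_system`.
#' @param operator Composition operator, see [fuzzy_compose()].
#' @return A `segment_evaluation`: list with `affiliation` (the R matrix),
#'   `indicator` (data frame of per-indicator grades and memberships),
#'   `criterion` (named list of `evaluation_vector`) and `target`
#'   (`evaluation_vector`).
#' @export
evaluate_layers <- function(values, weights, system,
                            operator = "weighted_average") {
  ids <- indicator_ids(system)
  if (is.null(names(weights))) {
    if (length(weights) != length(ids))
      stop("unnamed weight vector of wrong length", call. = FALSE)
    names(weights) <- ids
  }
  R <- build_affiliation(values, system)
  ind_grades <- apply(R, 1, argmax_grade)
  ind_df <- data.frame(id = ids, grade = unname(ind_grades[ids]),
                       round(R[ids, , drop = FALSE], 6),
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
  crit <- lapply(system$hierarchy$criteria, function(cr) {
    w <- weights[cr$indicators]
    fuzzy_compose(w / sum(w), R[cr$indicators, , drop = FALSE],
                  operator = operator, layer = "criterion")
  })
  target <- fuzzy_compose(weights[ids] / sum(weights[ids]),
                          R[ids, , drop = FALSE],
                          operator = operator, layer = "target")
  structure(list(affiliation = R, indicator = ind_df, criterion = crit,
                 target = target),
            class = "segment_evaluation")
}

#' @export
print.segment_evaluation <- function(x, digits = 4, ...) {
  cat("<segment_evaluation> target grade:", x$target$grade, "\n")
  cat("Criterion grades:",
      paste(names(x$criterion), vapply(x$criterion, `[[`, character(1),
                                       "grade"),
            sep = "=", collapse = ", "), "\n")
  cat("Indicator grades:\n")
  print(stats::setNames(x$indicator$grade, x$indicator$id))
  invisible(x)
}
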