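#' Fuse subjective (AHP) and objective (entropy) weights
#'
#' Weighted-average fusion `fused = lambda * ahp + (1 - lambda) * entropy`.
#' The default `lambda = 0.5` is the plain arithmetic mean of the two weight
#' systems, which balances expert judgment against data dispersion.
#'
#' @param ahp_w,ent_w Weight vectors over the same indicators (same length;
#'   names, if present, must agree).
#' @param lambda Fusion coefficient in `[0, 1]`; 1 reproduces the AHP
#'   weights, 0 the entropy weights.
#' @return Fused weight vector.
#' @export
fuse_weights <- function(ahp_w, ent_w, lambda = 0.5) {
  if (length(ahp_w) != length(ent_w))
    stop("AHP and entropy weight vectors differ in length", call. = FALSE)
  if (!is.null(names(ahp_w)) && !is.null(names(ent_w)) &&
      !identical(names(ahp_w), names(ent_w)))
    stop("AHP and entropy weight names disagree", call. = FALSE)
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  lambda * ahp_w + (1 - lambda) * ent_w
}

#' Aggregate indicator weights to the criterion layer
#'
#' A criterion's weight is the sum of its member indicators' weights, so the
#' criterion layer carries the same total mass as the indicator layer.
#'
#' @param w Named weight vector over indicators.
#' @param system A `river_system`.
#' @return Named weight vector over criteria.
#' @export
aggregate_criterion_weights <- function(w, system) {
  ids <- indicator_ids(system)
  if (is.null(names(w))) {
    if (length(w) != length(ids))
      stop("unnamed weight vector of wrong length", call. = FALSE)
    names(w) <- ids
  }
  missing <- setdiff(ids, names(w))
  if (length(missing))
    stop("weights missing for indicators: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(system$hierarchy$criteria,
         function(cr) sum(w[cr$indicators]), numeric(1))
}

#' Criticality ranks of weights
#'
#' Descending-weight ranks computed at a fixed decimal precision; exact ties
#' at that precision share the smaller rank number and skip the following
#' ranks (competition ranking, as used in published weight tables).
#'
#' @param w Nonnegative weight vector.
#' @param digits Precision at which ties are detected (default 4, the
#'   precision of the published table).
#' @return Integer rank vector (named like `w`).
#' @export
rank_criticality <- function(w, digits = 4) {
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  wr <- round(w, digits)
  r <- rank(-wr, ties.method = "min")
  storage.mode(r) <- "integer"
  stats::setNames(r, names(w))
}

#' Build the two-level weight table
#'
#' Assembles the indicator- and criterion-layer weight table: AHP, entropy
#' and fused weights plus criticality ranks at both levels.  Criterion-level
#' entries are sums over member indicators (including the fused column, which
#' therefore equals the sum of fused member weights rather than the fusion of
#' the criterion-level AHP and entropy sums).
#'
#' @param ahp_w,ent_w Named weight vectors over the system's indicators.
#' @param system A `river_system`.
#' @param lambda Fusion coefficient, see [fuse_weights()].
#' @return A `weight_table`: list of data frames `indicators` and `criteria`
#'   with columns `id`, (`criterion`,) `ahp`, `entropy`, `comprehensive`,
#'   `criticality`, plus attributes `lambda` and `fused` (named fused
#'   vector).
#' @export
build_weight_table <- function(ahp_w, ent_w, system, lambda = 0.5) {
  ids <- indicator_ids(system)
  ahp_w <- ahp_w[ids]; ent_w <- ent_w[ids]
  if (anyNA(ahp_w) || anyNA(ent_w))
    stop("AHP/entropy weights must cover all system indicators",
         call. = FALSE)
  fused <- fuse_weights(ahp_w, ent_w, lambda)
  crit_of <- vapply(system$indicators, `[[`, character(1), "criterion")[ids]
  ind_df <- data.frame(
    id = ids, criterion = unname(crit_of),
    ahp = unname(ahp_w), entropy = unname(ent_w),
    comprehensive = unname(fused),
    criticality = unname(rank_criticality(fused)),
    stringsAsFactors = FALSE)
  crit_df <- data.frame(
    id = criterion_ids(system),
    ahp = unname(aggregate_criterion_weights(ahp_w, system)),
    entropy = unname(aggregate_criterion_weights(ent_w, system)),
    comprehensive = unname(aggregate_criterion_weights(fused, system)),
    stringsAsFactors = FALSE)
  crit_df$criticality <- unname(rank_criticality(
    stats::setNames(crit_df$comprehensive, crit_df$id)))
  structure(list(indicators = ind_df, criteria = crit_df),
            class = "weight_table", lambda = lambda, fused = fused)
}

#' Fused weights of a weight table
#' @param wt A `weight_table`.
#' @return Named fused indicator weight vector.
#' @export
fused_weights <- function(wt) attr(wt, "fused")

#' Write a weight table as CSV
#'
#' One file mirroring the published layout: criterion rows first, then
#' indicator rows, with AHP, entropy, comprehensive and criticality columns.
#'
#' @param wt A `weight_table`.
#' @param path Output CSV path.
#' @param digits Optional display rounding (default: full precision).
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(wt, path, digits = NULL) {
  crit <- cbind(level = "criterion", wt$criteria[, "id", drop = FALSE],
                criterion = NA_character_,
                wt$criteria[, c("ahp", "entropy", "comprehensive",
                                "criticality")])
  ind <- cbind(level = "indicator", wt$indicators[, "id", drop = FALSE],
               criterion = wt$indicators$criterion,
               wt$indicators[, c("ahp", "entropy", "comprehensive",
                                 "criticality")])
  out <- rbind(crit, ind)
  if (!is.null(digits))
    for (cl in c("ahp", "entropy", "comprehensive"))
      out[[cl]] <- round(out[[cl]], digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.weight_table <- function(x, digits = 4, ...) {
  cat("<weight_table> lambda =", attr(x, "lambda"), "\n\nCriterion layer:\n")
  cd <- x$criteria; cd[2:4] <- round(cd[2:4], digits)
  print(cd, row.names = FALSE)
  cat("\nIndicator layer:\n")
  id <- x$indicators; id[3:5] <- round(id[3:5], digits)
  print(id, row.names = FALSE)
  invisible(x)
}
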