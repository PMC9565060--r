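#' Run the full multifunctional-river evaluation pipeline
#'
#' Orchestrates the stages end to end: system validation, AHP weighting with
#' consistency testing, entropy weighting of the data matrix, weight fusion,
#' affiliation matrices, weighted composition and maximum-affiliation
#' grading at the indicator, criterion and target layers.
#'
#' Either `judgments` (a list with a criterion-level [judgment_matrix()] and
#' one within-criterion matrix per criterion) or a precomputed `ahp_weights`
#' vector must be supplied; likewise `entropy_wts` may inject precomputed
#' objective weights (e.g. a published column) in place of the entropy
#' computation.  Injecting both published columns is the "skip mode" used to
#' reproduce a printed weight table exactly.
#'
#' @param data Segments x indicators matrix (or data frame with a segment-id
#'   column) of raw indicator values.
#' @param system A `river_system`.
#' @param judgments Judgment matrices (`list(criterion = , indicators = )`),
#'   e.g. from [xiaoqing_judgment_matrices()] or a scenario.
#' @param ahp_weights Optional named global AHP weight vector over all
#'   indicators, bypassing `judgments`.
#' @param entropy_wts Optional named entropy weight vector, bypassing the
#'   entropy computation.
#' @param lambda Fusion coefficient, see [fuse_weights()].
#' @param operator Composition operator, see [fuzzy_compose()].
#' @param require_consistency Abort if any judgment matrix has CR >= 0.1.
#' @return A `river_evaluation`: list with `weight_table`, `consistency`
#'   (per-matrix reports plus the combined hierarchy ratio), `segments`
#'   (named list of [evaluate_layers()] results), `grades` (data frame of
#'   criterion and target grades per segment) and `config`.
#' @examples
#' sc <- make_scenario(seed = 1)
#' ev <- run_evaluation(sc$values, judgments = sc$judgments)
#' ev$grades
#' @export
run_evaluation <- function(data, system = load_system(), judgments = NULL,
                           ahp_weights = NULL, entropy_wts = NULL,
                           lambda = 0.5, operator = "weighted_average",
                           require_consistency = TRUE) {
  X <- as_data_matrix(data, system)
  ids <- indicator_ids(system)

  reports <- NULL
  if (is.null(ahp_weights)) {
    if (is.null(judgments))
      stop("supply either 'judgments' or 'ahp_weights'", call. = FALSE)
    mats <- c(list(criterion = judgments$criterion), judgments$indicators)
    ws <- lapply(mats, principal_weights)
    reports <- Map(consistency, mats, ws)
    for (nm in names(reports))
      if (require_consistency && !reports[[nm]]$acceptable)
        stop("AHP stage: judgment matrix '", nm,
             "' fails the consistency test (CR = ",
             sprintf("%.4f", reports[[nm]]$cr), " >= 0.1)", call. = FALSE)
    ahp_weights <- combine_levels(ws$criterion,
                                  ws[names(ws) != "criterion"])
    reports$hierarchy <- hierarchy_consistency(
      ws$criterion, reports[names(ws$criterion)])
  }
  ahp_weights <- ahp_weights[ids]

  ent <- NULL
  if (is.null(entropy_wts)) {
    ent <- entropy_weighting(X, system)
    entropy_wts <- ent$weights
  }
  entropy_wts <- entropy_wts[ids]

  wt <- build_weight_table(ahp_weights, entropy_wts, system, lambda)
  fused <- fused_weights(wt)
  segs <- lapply(seq_len(nrow(X)), function(i)
    evaluate_layers(X[i, ], fused, system, operator = operator))
  names(segs) <- rownames(X) %||% paste0("S", seq_len(nrow(X)))

  grades <- data.frame(
    segment = names(segs),
    do.call(rbind, lapply(segs, function(s)
      vapply(s$criterion, `[[`, character(1), "grade"))),
    target = vapply(segs, function(s) s$target$grade, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(weight_table = wt, consistency = reports,
                 entropy = ent, segments = segs, grades = grades,
                 config = list(lambda = lambda, operator = operator,
                               system = system$name)),
            class = "river_evaluation")
}

#' Constraint indicators of an evaluation
#'
#' Indicators assigned a bad or poor grade (IV or V) in a segment limit that
#' segment's functioning; this lists them per segment.
#'
#' @param ev A `river_evaluation`.
#' @return Named list (one character vector of indicator ids per segment).
#' @export
constraint_indicators <- function(ev) {
  lapply(ev$segments, function(s)
    s$indicator$id[s$indicator$grade %in% c("IV", "V")])
}

#' Human-readable evaluation report
#'
#' Prints per-segment membership tables and grades for the three layers,
#' followed by the constraint indicators (those graded IV or V) of each
#' segment.  Returns the report lines invisibly.
#'
#' @param ev A `river_evaluation`.
#' @param digits Display rounding of memberships.
#' @return Character vector of report lines, invisibly.
#' @export
report <- function(ev, digits = 4) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Multifunctional river evaluation (lambda = ", ev$config$lambda,
      ", operator = ", ev$config$operator, ")")
  if (!is.null(ev$consistency)) {
    add("Judgment-matrix consistency ratios:")
    for (nm in setdiff(names(ev$consistency), "hierarchy"))
      add("  ", nm, ": CR = ", sprintf("%.4f", ev$consistency[[nm]]$cr))
    add("  combined hierarchy CR = ",
        sprintf("%.4f", ev$consistency$hierarchy$cr))
  }
  cons <- constraint_indicators(ev)
  for (seg in names(ev$segments)) {
    s <- ev$segments[[seg]]
    add("")
    add("Segment ", seg, ": target grade ", s$target$grade,
        " [", paste(sprintf("%s=%.*f", GRADES, digits,
                            s$target$memberships), collapse = ", "), "]")
    for (cr in names(s$criterion))
      add("  ", cr, ": grade ", s$criterion[[cr]]$grade,
          " [", paste(sprintf("%.*f", digits,
                              s$criterion[[cr]]$memberships),
                      collapse = ", "), "]")
    add("  constraint indicators: ",
        if (length(cons[[seg]])) paste(cons[[seg]], collapse = ", ")
        else "(none)")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write evaluation artifacts to a directory
#'
#' Stores the weight table, the per-segment layer results (memberships and
#' grades for the indicator, criterion and target layers), the grade summary
#' and a JSON manifest of the run configuration.
#'
#' @param ev A `river_evaluation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(ev, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weight_table(ev$weight_table, file.path(dir, "weight_table.csv"))
  utils::write.csv(ev$grades, file.path(dir, "grades.csv"),
                   row.names = FALSE)
  for (seg in names(ev$segments)) {
    s <- ev$segments[[seg]]
    layers <- rbind(
      data.frame(layer = "indicator", id = s$indicator$id,
                 grade = s$indicator$grade,
                 s$indicator[, GRADES], check.names = FALSE),
      do.call(rbind, lapply(names(s$criterion), function(cr)
        data.frame(layer = "criterion", id = cr,
                   grade = s$criterion[[cr]]$grade,
                   t(s$criterion[[cr]]$memberships), check.names = FALSE))),
      data.frame(layer = "target", id = "target",
                 grade = s$target$grade, t(s$target$memberships),
                 check.names = FALSE))
    utils::write.csv(layers,
                     file.path(dir, paste0("segment_", seg, ".csv")),
                     row.names = FALSE)
  }
  writeLines(paste0('{"lambda": ', ev$config$lambda, ', "operator": "',
                    ev$config$operator, '", "system": "', ev$config$system,
                    '"}'),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.river_evaluation <- function(x, ...) {
  cat("<river_evaluation> ", length(x$segments), " segments, lambda = ",
      x$config$lambda, ", operator = ", x$config$operator, "\n", sep = "")
  print(x$grades, row.names = FALSE)
  invisible(x)
}
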