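#' Construct an indicator specification
#'
#' An indicator specification carries the identity, direction and five-grade
#' classification criteria of one assessment indicator, together with its
#' position in the hierarchy (criterion and sub-criterion membership).
#'
#' @param id Indicator id (e.g. `"C1"`).
#' @param name Human-readable indicator name.
#' @param unit Measurement unit as printed in the classification table.
#' @param direction One of `"positive"` (larger is better), `"negative"`
#'   (smaller is better), `"bidirectional"` (best inside a central band) or
#'   `"categorical"` (ordinal category values).
#' @param grades Named list over grades `I`..`V`; each element is a list of
#'   one or more [grade_interval()] branches (bidirectional indicators have
#'   two branches for the off-band grades).
#' @param criterion,subcriterion Parent ids in the hierarchy.
#' @return An object of class `indicator_spec`.
#' @export
indicator_spec <- function(id, name, unit, direction, grades,
                           criterion, subcriterion) {
  direction <- match.arg(direction,
                         c("positive", "negative", "bidirectional",
                           "categorical"))
  if (!identical(sort(names(grades)), sort(GRADES)))
    stop("indicator ", id, ": grades must be exactly ",
         paste(GRADES, collapse = ", "), call. = FALSE)
  grades <- grades[GRADES]
  spec <- structure(list(id = id, name = name, unit = unit,
                         direction = direction, grades = grades,
                         criterion = criterion, subcriterion = subcriterion),
                    class = "indicator_spec")
  validate_indicator_spec(spec)
  spec
}

## All interval branches of a grade, as a list of grade_interval.
grade_branches <- function(spec, grade) spec$grades[[grade]]

## Validation: disjointness and (for non-categorical indicators) gap-free
## contiguous coverage over the union of branches.
validate_indicator_spec <- function(spec) {
  id <- spec$id
  ivs <- list(); lab <- character(0)
  for (g in GRADES) {
    br <- grade_branches(spec, g)
    if (length(br) < 1 || length(br) > 2)
      stop("indicator ", id, " grade ", g,
           ": each grade needs 1 or 2 interval branches", call. = FALSE)
    for (iv in br) { ivs <- c(ivs, list(iv)); lab <- c(lab, g) }
  }
  if (spec$direction == "categorical") {
    pts <- vapply(ivs, function(iv) {
      if (iv$lower != iv$upper)
        stop("indicator ", id, ": categorical grades must be single values",
             call. = FALSE)
      iv$lower
    }, numeric(1))
    if (anyDuplicated(pts))
      stop("indicator ", id, ": duplicated category value", call. = FALSE)
    return(invisible(spec))
  }
  ord <- order(vapply(ivs, `[[`, numeric(1), "lower"),
               vapply(ivs, `[[`, numeric(1), "upper"))
  ivs <- ivs[ord]; lab <- lab[ord]
  for (k in seq_len(length(ivs) - 1L)) {
    a <- ivs[[k]]; b <- ivs[[k + 1L]]
    if (a$upper > b$lower ||
        (a$upper == b$lower && a$upper_closed && b$lower_closed))
      stop("indicator ", id, ": grades ", lab[k], " and ", lab[k + 1L],
           " overlap", call. = FALSE)
    if (a$upper < b$lower ||
        (a$upper == b$lower && !a$upper_closed && !b$lower_closed))
      stop("indicator ", id, ": coverage gap between grades ", lab[k],
           " and ", lab[k + 1L], call. = FALSE)
  }
  invisible(spec)
}

#' Load an indicator system from a structured configuration
#'
#' Reads a YAML configuration defining the assessment hierarchy (criteria,
#' sub-criteria, indicators) and the five-grade classification criteria of
#' every indicator, validates it (grade completeness, interval disjointness
#' and coverage, parent references) and returns the assembled system.  The
#' packaged default encodes the 22-indicator, 4-criterion multifunctional
#' river configuration.
#'
#' @param path Path to a YAML system configuration; `NULL` loads the packaged
#'   default.
#' @return An object of class `river_system`: a list with elements
#'   `hierarchy` (criteria and sub-criteria with memberships) and
#'   `indicators` (named list of [indicator_spec()]).
#' @examples
#' sys <- load_system()
#' length(sys$indicators)          # 22
#' classify_crisp(81.2, sys$indicators$C11)
#' @export
load_system <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "xiaoqing_system.yaml",
                        package = "riverfce", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (fld in c("criteria", "subcriteria", "indicators"))
    if (is.null(cfg[[fld]]))
      stop("system config is missing '", fld, "'", call. = FALSE)

  sub2crit <- character(0)
  for (cr in cfg$criteria)
    for (b in cr$subcriteria) {
      if (b %in% names(sub2crit))
        stop("sub-criterion ", b, " listed under two criteria", call. = FALSE)
      sub2crit[[b]] <- cr$id
    }
  sub_ids <- vapply(cfg$subcriteria, `[[`, character(1), "id")
  if (!setequal(sub_ids, names(sub2crit)))
    stop("dangling sub-criterion reference: ",
         paste(setdiff(union(sub_ids, names(sub2crit)),
                       intersect(sub_ids, names(sub2crit))), collapse = ", "),
         call. = FALSE)
  ind2sub <- character(0)
  for (sc in cfg$subcriteria)
    for (ci in sc$indicators) {
      if (ci %in% names(ind2sub))
        stop("indicator ", ci, " listed under two sub-criteria", call. = FALSE)
      ind2sub[[ci]] <- sc$id
    }

  specs <- list()
  for (ind in cfg$indicators) {
    if (is.null(ind2sub[[ind$id]]) || is.na(ind2sub[[ind$id]]))
      stop("indicator ", ind$id, " has no parent sub-criterion",
           call. = FALSE)
    grades <- lapply(ind$grades, function(g) lapply(as.list(g), parse_interval))
    sub <- ind2sub[[ind$id]]
    if (!is.null(ind$subcriterion) && !identical(ind$subcriterion, sub))
      stop("indicator ", ind$id, " declares sub-criterion ",
           ind$subcriterion, " but the hierarchy lists it under ", sub,
           call. = FALSE)
    specs[[ind$id]] <- indicator_spec(
      id = ind$id, name = ind$name, unit = ind$unit,
      direction = ind$direction, grades = grades,
      criterion = sub2crit[[sub]], subcriterion = sub)
  }
  if (!setequal(names(ind2sub), names(specs)))
    stop("missing indicator definition: ",
         paste(setdiff(names(ind2sub), names(specs)), collapse = ", "),
         call. = FALSE)
  specs <- specs[unlist(lapply(cfg$subcriteria, `[[`, "indicators"))]

  hierarchy <- list(
    criteria = stats::setNames(lapply(cfg$criteria, function(cr)
      list(id = cr$id, name = cr$name, subcriteria = cr$subcriteria,
           indicators = unlist(lapply(cfg$subcriteria, function(sc)
             if (sc$id %in% cr$subcriteria) sc$indicators)))),
      vapply(cfg$criteria, `[[`, character(1), "id")),
    subcriteria = stats::setNames(lapply(cfg$subcriteria, function(sc)
      list(id = sc$id, name = sc$name, criterion = sub2crit[[sc$id]],
           indicators = sc$indicators)), sub_ids))

  structure(list(name = cfg$name %||% "river_system",
                 hierarchy = hierarchy, indicators = specs,
                 source = path),
            class = "river_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indicator ids of a system, in configuration order
#' @param system A `river_system`.
#' @return Character vector of indicator ids.
#' @export
indicator_ids <- function(system) names(system$indicators)

#' Criterion ids of a system
#' @param system A `river_system`.
#' @return Character vector of criterion ids.
#' @export
criterion_ids <- function(system) names(system$hierarchy$criteria)

#' Crisp grade classification
#'
#' Returns the unique grade whose interval (or union of interval branches)
#' contains `x`.  Values beyond the outermost finite boundary fall into the
#' unbounded extreme grade; values outside a fully bounded ladder (or, for
#' categorical indicators, off the listed category values) raise an error.
#'
#' @param x Finite numeric value in indicator units.
#' @param spec An [indicator_spec()].
#' @return A grade label among `"I"`..`"V"`.
#' @export
classify_crisp <- function(x, spec) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("x must be a single finite number", call. = FALSE)
  for (g in GRADES)
    for (iv in grade_branches(spec, g))
      if (interval_contains(iv, x)) return(g)
  stop("value ", x, " is outside the graded domain of ", spec$id,
       call. = FALSE)
}

#' @export
print.river_system <- function(x, ...) {
  cat("<river_system> ", x$name, ": ",
      length(x$hierarchy$criteria), " criteria, ",
      length(x$hierarchy$subcriteria), " sub-criteria, ",
      length(x$indicators), " indicators\n", sep = "")
  invisible(x)
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat("<indicator_spec> ", x$id, " (", x$name, "), ", x$direction,
      ", unit ", x$unit, "\n", sep = "")
  for (g in GRADES)
    cat("  ", g, ": ",
        paste(vapply(grade_branches(x, g), format_interval, character(1)),
              collapse = " U "), "\n", sep = "")
  invisible(x)
}
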