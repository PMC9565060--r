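## Sampling interval of one grade branch: finite branches are used as-is;
## unbounded branches are capped at the membership model's virtual bound
## (shared boundary plus the width borrowed from the adjacent grade), so
## generated data stay inside the informative range of the memberships.
sampling_interval <- function(spec, grade, branch = 1L) {
  iv <- grade_branches(spec, grade)[[branch]]
  if (!is_unbounded(iv)) return(c(iv$lower, iv$upper))
  bw <- adjacent_width(spec, grade, branch)
  if (is.infinite(iv$upper)) c(iv$lower, iv$lower + bw)
  else c(iv$upper - bw, iv$upper)
}

#' Generate indicator values with planted grades
#'
#' Draws one value per cell of a planted segments x indicators grade table,
#' guaranteed to classify back to the planted grade.  `"midpoint"` placement
#' is deterministic (interval midpoints; category values and single-point
#' grades give the point itself; the first, lower branch of a bidirectional
#' grade).  `"uniform"` placement samples uniformly inside the interval,
#' staying clear of the boundaries by a relative margin, and picks a branch
#' at random for bidirectional grades.  Unbounded grades are sampled inside
#' their virtual bound.
#'
#' @param planted Character matrix or data frame of grade labels
#'   (`"I"`..`"V"`), segments in rows, indicator ids as column names.
#' @param system A `river_system`.
#' @param seed Integer seed; draws are reproducible per seed.
#' @param placement `"midpoint"` or `"uniform"`.
#' @param margin Relative distance kept from interval boundaries under
#'   uniform placement.
#' @return Numeric matrix of indicator values (segments x indicators).
#' @export
generate_values <- function(planted, system, seed = 1L,
                            placement = c("midpoint", "uniform"),
                            margin = 1e-6) {
  placement <- match.arg(placement)
  planted <- as.matrix(planted)
  ids <- indicator_ids(system)
  if (is.null(colnames(planted))) colnames(planted) <- ids
  if (!all(colnames(planted) %in% ids))
    stop("planted grade table has unknown indicators", call. = FALSE)
  if (!all(planted %in% GRADES))
    stop("planted grades must be among ", paste(GRADES, collapse = ", "),
         call. = FALSE)
  X <- matrix(NA_real_, nrow(planted), ncol(planted),
              dimnames = dimnames(planted))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(planted))) for (id in colnames(planted)) {
      spec <- system$indicators[[id]]
      g <- planted[i, id]
      branches <- grade_branches(spec, g)
      k <- if (placement == "uniform" && length(branches) > 1L)
        sample.int(length(branches), 1L) else 1L
      rng <- sampling_interval(spec, g, k)
      w <- rng[2] - rng[1]
      X[i, id] <- if (placement == "midpoint" || w == 0) mean(rng)
                  else stats::runif(1, rng[1] + margin * w,
                                    rng[2] - margin * w)
    }
  })
  ## planted grades must classify back exactly
  for (i in seq_len(nrow(X))) for (id in colnames(X))
    stopifnot(classify_crisp(X[i, id], system$indicators[[id]]) ==
                planted[i, id])
  X
}

## Saaty 1-9 scale values and reciprocals.
saaty_scale <- function() {
  v <- 1:9
  sort(unique(c(v, 1 / v)))
}

#' Generate a near-consistent judgment matrix
#'
#' Builds a reciprocal pairwise-comparison matrix around a known priority
#' vector: `a_ij = (w_i / w_j) * exp(eps_ij)` with independent
#' `eps_ij ~ Normal(0, noise_sigma^2)` for `i < j`, reciprocals below the
#' diagonal and 1 on it.  With `noise_sigma = 0` the matrix is exactly
#' consistent and the principal eigenvector recovers `true_w`.  Optional
#' snapping maps each upper-triangle entry to the nearest value of the 1-9
#' scale (or its reciprocal).
#'
#' @param true_w Positive weight vector summing to 1.
#' @param noise_sigma Standard deviation of the log-scale perturbation.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param snap Snap entries to the Saaty 1-9 scale set.
#' @return A [judgment_matrix()].
#' @export
generate_judgment_matrix <- function(true_w, noise_sigma = 0, seed = NULL,
                                     snap = FALSE) {
  if (any(true_w <= 0)) stop("true_w must be positive", call. = FALSE)
  true_w <- true_w / sum(true_w)
  n <- length(true_w)
  build <- function() {
    A <- outer(true_w, true_w, `/`)
    if (noise_sigma > 0) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        A[i, j] <- A[i, j] * exp(stats::rnorm(1, 0, noise_sigma))
        A[j, i] <- 1 / A[i, j]
      }
    }
    if (snap) {
      sc <- saaty_scale()
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        A[i, j] <- sc[which.min(abs(sc - A[i, j]))]
        A[j, i] <- 1 / A[i, j]
      }
    }
    diag(A) <- 1
    A
  }
  A <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  judgment_matrix(A, labels = names(true_w))
}

#' Synthetic evaluation scenario with planted structure
#'
#' Builds a complete, reproducible test scenario: a planted grade table, the
#' matching value matrix, and a set of judgment matrices (criterion level
#' plus one per criterion) generated around the packaged reference AHP
#' weights.  The default planting is a downstream degradation ladder -
#' segment s is planted at grade level s for every indicator - except that
#' the ecological-flow-satisfaction indicator (C2, when present) is planted
#' excellent everywhere, emulating a river whose flow requirement is met in
#' all segments (and exercising the constant-column / zero-entropy-weight
#' path).
#'
#' @param system A `river_system`.
#' @param n_segments Number of river segments (grades clamp at V).
#' @param seed Integer seed driving values and judgment noise.
#' @param placement Value placement, see [generate_values()].
#' @param noise_sigma Log-scale noise of the judgment matrices; 0 gives
#'   exactly consistent matrices.
#' @param snap Snap judgment entries to the 1-9 scale.
#' @param segment_names Optional segment labels; defaults to the five
#'   Xiaoqing River administrative sections when `n_segments == 5`.
#' @return A `river_scenario`: list with `seed`, `placement`, `noise_sigma`,
#'   `planted`, `values`, `judgments` (list with `criterion` matrix and
#'   `indicators` list), `true_ahp` (the generating weights).
#' @export
make_scenario <- function(system = load_system(), n_segments = 5, seed = 1L,
                          placement = "midpoint", noise_sigma = 0,
                          snap = FALSE, segment_names = NULL) {
  seed <- as.integer(seed)
  ids <- indicator_ids(system)
  if (is.null(segment_names))
    segment_names <- if (n_segments == 5)
      c("Jinan", "Binzhou", "Zibo", "Dongying", "Weifang")
    else paste0("S", seq_len(n_segments))
  planted <- matrix(GRADES[pmin(seq_len(n_segments), 5L)],
                    n_segments, length(ids),
                    dimnames = list(segment_names, ids))
  if ("C2" %in% ids) planted[, "C2"] <- "I"
  values <- generate_values(planted, system, seed = seed,
                            placement = placement)
  ref <- xiaoqing_reference_weights()
  judgments <- xiaoqing_judgment_matrices(system, noise_sigma = noise_sigma,
                                          seed = seed + 1L, snap = snap)
  structure(list(seed = seed, placement = placement,
                 noise_sigma = noise_sigma, planted = planted,
                 values = values, judgments = judgments,
                 true_ahp = stats::setNames(ref$indicators$ahp,
                                            ref$indicators$id)),
            class = "river_scenario")
}

#' @export
print.river_scenario <- function(x, ...) {
  cat("<river_scenario> ", nrow(x$values), " segments x ", ncol(x$values),
      " indicators; placement ", x$placement, ", seed ", x$seed,
      ", judgment noise sigma ", x$noise_sigma, "\n", sep = "")
  print(x$planted)
  invisible(x)
}

#' Serialize / load a scenario directory
#'
#' `write_scenario()` stores the planted grades and values as CSV, every
#' judgment matrix as CSV, and a JSON manifest with the seed and parameters;
#' `read_scenario()` loads it back.
#'
#' @param scenario A `river_scenario`.
#' @param dir Target directory (created if needed).
#' @return `dir` (write) or a `river_scenario`-like list (read), invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scenario$planted, file.path(dir, "planted_grades.csv"))
  utils::write.csv(scenario$values, file.path(dir, "values.csv"))
  jm_dir <- file.path(dir, "judgments")
  dir.create(jm_dir, showWarnings = FALSE)
  utils::write.csv(unclass(scenario$judgments$criterion),
                   file.path(jm_dir, "criterion.csv"))
  for (nm in names(scenario$judgments$indicators))
    utils::write.csv(unclass(scenario$judgments$indicators[[nm]]),
                     file.path(jm_dir, paste0(nm, ".csv")))
  manifest <- list(seed = scenario$seed, placement = scenario$placement,
                   noise_sigma = scenario$noise_sigma)
  writeLines(paste0('{"seed": ', manifest$seed,
                    ', "placement": "', manifest$placement,
                    '", "noise_sigma": ', manifest$noise_sigma, '}'),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  read_mat <- function(p) {
    d <- utils::read.csv(p, row.names = 1, check.names = FALSE)
    as.matrix(d)
  }
  manifest <- yaml::read_yaml(file.path(dir, "manifest.json"))
  jm_dir <- file.path(dir, "judgments")
  ind_files <- setdiff(list.files(jm_dir, pattern = "\\.csv$"),
                       "criterion.csv")
  judgments <- list(
    criterion = judgment_matrix(read_mat(file.path(jm_dir, "criterion.csv"))),
    indicators = stats::setNames(
      lapply(ind_files, function(f)
        judgment_matrix(read_mat(file.path(jm_dir, f)))),
      sub("\\.csv$", "", ind_files)))
  structure(list(seed = manifest$seed, placement = manifest$placement,
                 noise_sigma = manifest$noise_sigma,
                 planted = read_mat(file.path(dir, "planted_grades.csv")),
                 values = read_mat(file.path(dir, "values.csv")),
                 judgments = judgments),
            class = "river_scenario")
}
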