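#' Packaged reference weight table (printed values)
#'
#' Loads the published two-level weight table of the 22-indicator
#' multifunctional river configuration: AHP, entropy and comprehensive
#' weights plus criticality ranks at the indicator and criterion layers, as
#' printed (4 decimals).  These printed columns are the reference inputs for
#' reproducing the fused-weight structure and for reconstructing judgment
#' matrices.
#'
#' @return List of data frames `indicators` and `criteria` with columns
#'   `id`, (`criterion`,) `ahp`, `entropy`, `comprehensive`, `criticality`.
#' @export
xiaoqing_reference_weights <- function() {
  path <- system.file("extdata", "xiaoqing_weights.csv",
                      package = "riverfce", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(indicators = d[d$level == "indicator",
                      c("id", "criterion", "ahp", "entropy",
                        "comprehensive", "criticality")],
       criteria = d[d$level == "criterion",
                    c("id", "ahp", "entropy", "comprehensive",
                      "criticality")])
}

#' Reconstructed judgment matrices for the packaged configuration
#'
#' The original pairwise judgment matrices behind the published AHP weights
#' are not available; this reconstructs exactly consistent matrices from the
#' printed AHP weight columns (`a_ij = w_i / w_j`, at the criterion level and
#' within each criterion), optionally perturbed by log-normal noise or
#' snapped to the 1-9 scale via [generate_judgment_matrix()].  With zero
#' noise, [principal_weights()] on these matrices recovers the printed AHP
#' column (up to its 4-decimal rounding) and every CR is 0.
#'
#' @param system A `river_system` (defaults to the packaged one).
#' @param noise_sigma Log-scale noise, see [generate_judgment_matrix()].
#' @param seed Seed for the noise draws.
#' @param snap Snap entries to the 1-9 scale.
#' @return List with `criterion` (4x4 [judgment_matrix()]) and `indicators`
#'   (named list of within-criterion judgment matrices).
#' @export
xiaoqing_judgment_matrices <- function(system = load_system(),
                                       noise_sigma = 0, seed = NULL,
                                       snap = FALSE) {
  ref <- xiaoqing_reference_weights()
  crit_w <- stats::setNames(ref$criteria$ahp, ref$criteria$id)
  crit_w <- crit_w / sum(crit_w)
  ind_w <- stats::setNames(ref$indicators$ahp, ref$indicators$id)
  seeds <- if (is.null(seed)) vector("list", 1 + length(crit_w))
           else as.list(seed + seq_len(1 + length(crit_w)) - 1L)
  out <- list(criterion = generate_judgment_matrix(
    crit_w, noise_sigma = noise_sigma, seed = seeds[[1]], snap = snap))
  out$indicators <- stats::setNames(lapply(seq_along(crit_w), function(k) {
    cr <- names(crit_w)[k]
    members <- system$hierarchy$criteria[[cr]]$indicators
    w <- ind_w[members] / sum(ind_w[members])
    generate_judgment_matrix(w, noise_sigma = noise_sigma,
                             seed = seeds[[k + 1]], snap = snap)
  }), names(crit_w))
  out
}
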