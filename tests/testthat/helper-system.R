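## Shared fixtures: the packaged system and printed reference weights.
SYS <- load_system()
REF <- xiaoqing_reference_weights()
REF_AHP <- setNames(REF$indicators$ahp, REF$indicators$id)
REF_ENT <- setNames(REF$indicators$entropy, REF$indicators$id)

ALL_GRADES <- c("I", "II", "III", "IV", "V")

## Grade assigned by maximum membership with worse-grade tie-break.
fuzzy_grade <- function(x, spec) {
  m <- membership_vector(x, spec)
  ALL_GRADES[max(which(m == max(m)))]
}

## Random reciprocal judgment matrix with log-normal upper triangle.
random_reciprocal <- function(n, sdlog = 1) {
  A <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- exp(rnorm(1, 0, sdlog))
    A[j, i] <- 1 / A[i, j]
  }
  A
}

## Dense-eigendecomposition oracle for priority weights and lambda_max.
eigen_oracle <- function(A) {
  ev <- eigen(A)
  k <- which.max(Re(ev$values))
  w <- Re(ev$vectors[, k])
  list(w = w / sum(w), lambda = Re(ev$values[k]))
}

## Write a deep-copied, corrupted variant of the packaged system config and
## return its path (for load-time validation tests).
corrupt_system_yaml <- function(edit) {
  cfg <- yaml::read_yaml(system.file("extdata", "xiaoqing_system.yaml",
                                     package = "riverfce"))
  cfg <- edit(cfg)
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(cfg, path)
  path
}
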