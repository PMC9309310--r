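# Independent oracles and small fixture builders used across the suite.

# Govardovskii A1 template, re-implemented independently of the package
# (different parameterization: works in normalized frequency u = lmax/l and
# accumulates the four alpha-band terms in a loop).
oracle_govardovskii <- function(lambda, lmax) {
  u <- lmax / lambda
  A_coef <- c(69.7, 28, -14.9)
  b_coef <- c(0.8795 + 0.0459 * exp(-((lmax - 300)^2) / 11940), 0.922, 1.104)
  denom <- 0.674
  for (k in 1:3) denom <- denom + exp(A_coef[k] * (b_coef[k] - u))
  alpha <- 1 / denom
  beta <- 0.26 * exp(-(((lambda - (189 + 0.315 * lmax)) /
                          (-40.5 + 0.195 * lmax))^2))
  alpha + beta
}

# Law-of-cosines bond angle oracle.
oracle_angle <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p3)^2))
  b <- sqrt(sum((p1 - p2)^2))
  c <- sqrt(sum((p3 - p2)^2))
  acos(pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c)))) * 180 / pi
}

# Brute-force additive five-sites oracle over explicit residue states.
oracle_lws <- function(residues) {
  anc <- c("164" = "S", "181" = "H", "261" = "Y", "269" = "T", "292" = "A")
  sub <- c("164" = "A", "181" = "Y", "261" = "F", "269" = "A", "292" = "S")
  del <- c("164" = -7, "181" = -28, "261" = -8, "269" = -15, "292" = -27)
  560 + sum(vapply(names(anc), function(s) {
    if (residues[[s]] == sub[[s]]) del[[s]] else 0
  }, numeric(1)))
}

rand_rotation_matrix <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Tiny 2-frame generic trajectory for plumbing tests.
toy_trajectory <- function(n_atoms = 5, n_frames = 2, seed = 42) {
  set.seed(seed)
  base <- matrix(runif(n_atoms * 3, 0, 10), n_atoms, 3)
  coords <- array(0, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- base
  trajectory(paste0("A", seq_len(n_atoms)), coords)
}

lws_profile <- function(residues) {
  tuning_site_profile(residues, pigment_id = "toy", opsin_class = "lws")
}

extdata <- function(name) {
  system.file("extdata", name, package = "salmopsin", mustWork = TRUE)
}
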