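# Shared fixtures (memoized: the template phantom is expensive enough to
# build once per test run) and independent brute-force oracles.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

fx_template <- function() memo("template", function() make_template_phantom())

fx_case_with_dose <- function(style = "helical") {
  memo(paste0("case_", style), function() {
    tp <- fx_template()
    tp$dose <- synth_dose(tp, phantom_spec(dose_style = style))
    tp
  })
}

# small random dose + mask on a random grid (for metric-oracle checks)
random_grid_case <- function(seed, max_shape = 20L) {
  set.seed(seed)
  shape <- sample(3:max_shape, 3, replace = TRUE)
  spacing <- runif(3, 0.8, 5)
  g <- grid_geometry(runif(3, -50, 50), spacing, shape)
  dose <- image_volume(array(runif(prod(shape), 0, 60), shape), g, "DOSE")
  mvals <- array(runif(prod(shape)) < 0.6, shape)
  if (!any(mvals)) mvals[1] <- TRUE
  list(dose = dose, mask = binary_mask(mvals, g, "random"), geometry = g)
}

# ---- brute-force voxel-loop oracles (independent of the implementation) ----

oracle_v_at_dose <- function(dose, mask, x) {
  dv <- dose$values[mask$values]
  100 * sum(dv >= x) / length(dv)
}

oracle_mean <- function(dose, mask) mean(dose$values[mask$values])

oracle_integral_dose <- function(dose, mask) {
  s <- 0
  vox_l <- prod(dose$geometry$spacing) / 1e6
  idx <- which(mask$values)
  for (i in idx) s <- s + dose$values[i] * vox_l
  s
}

oracle_dice <- function(a, b) {
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}

oracle_paddick <- function(dose, target, rx, frac = 0.95) {
  piv <- dose$values >= frac * rx
  tv <- sum(target$values); pv <- sum(piv)
  if (pv == 0) return(0)
  sum(piv & target$values)^2 / (tv * pv)
}

# exact two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# step-down Holm decisions by direct enumeration of the sequential rule
oracle_holm_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) rej[ord[k]] <- TRUE else break
  }
  rej
}
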