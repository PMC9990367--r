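# Shared fixtures and independent oracles used across the test files.
# Oracles here are deliberately naive (enumeration, exhaustive scan,
# closed forms) and never call the implementation paths they check.

# a protocol with no interventions, for flat/constant renders
flat_protocol <- function(duration = 10) {
  protocol("flat", list(protocol_event("BASELINE", 0)), duration = duration)
}

# constant-concentration series: all fluxes zero, pinned initial state
flat_series <- function(lac = 1, glc = 2, duration = 10, dt = 0.5) {
  p0 <- kinetic_params(j_hk_vmax = 0, glut_vmax = 0, mct_vmax = 0)
  simulate_concentrations(p0, flat_protocol(duration), dt = dt,
                          init = c(glc, lac))
}

single_cell_scene <- function(shape = c(40, 40), intensity = 120,
                              background = 5) {
  scene_phantom(shape,
                data.frame(cy = shape[1] / 2, cx = shape[2] / 2,
                           ry = 5, rx = 6, intensity = intensity,
                           knockout = TRUE),
                background = background)
}

# two-component Gaussian mixture image (for threshold tests)
mixture_image <- function(seed, shape = c(64, 64), mu = c(20, 120),
                          sd = c(4, 15), p_fore = 0.3) {
  set.seed(seed)
  n <- prod(shape)
  fg <- runif(n) < p_fore
  v <- ifelse(fg, rnorm(n, mu[2], sd[2]), rnorm(n, mu[1], sd[1]))
  matrix(pmax(v, 0.1), shape[1], shape[2])
}

# exhaustive cross-entropy scan over all midpoints of adjacent sorted
# intensities; returns the minimizing threshold
li_bruteforce <- function(image) {
  v <- sort(as.numeric(image))
  u <- unique(v)
  cand <- (u[-1] + u[-length(u)]) / 2
  cs <- cumsum(v); tot <- cs[length(v)]
  obj <- vapply(cand, function(th) {
    nb <- findInterval(th, v)
    sb <- cs[nb]; sf <- tot - sb
    -(sb * log(sb / nb) + sf * log(sf / (length(v) - nb)))
  }, numeric(1))
  cand[which.min(obj)]
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
perm_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Kruskal-Wallis H by direct evaluation of the rank-sum formula
kw_bruteforce <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  rk <- rank(vals)
  gid <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(rk, gid, mean)
  ns <- tapply(rk, gid, length)
  h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  tie_tab <- table(vals)
  h / (1 - sum(tie_tab^3 - tie_tab) / (N^3 - N))
}

# quick two-group trace cohort readouts (slice-level values), shared by
# statistics/power tests
cohort_readouts <- function(spec, protocol, sensor = laconic_sensor(),
                            dt = 2, trace_noise_sd = 0.005, ...) {
  coh <- generate_cohort(spec, protocol, sensor = sensor, dt = dt,
                         trace_noise_sd = trace_noise_sd, ...)
  cfgA <- analysis_config()
  do.call(rbind, lapply(names(coh$traces), function(id) {
    est <- analyze_trace(coh$traces[[id]], coh$protocol, cfgA)
    ti <- coh$truth[coh$truth$id == id, ]
    data.frame(id = id, group = ti$group, mouse = ti$mouse, slice = ti$slice,
               basal = est$basal, amplitude = est$amplitude,
               slope = est$slope, stringsAsFactors = FALSE)
  }))
}
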