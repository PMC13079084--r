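# Shared builders for test problems. Tracer windows are chosen so random
# three-source systems are well conditioned (F14C separates peat from the
# modern-like sources; d13C separates the atmosphere-like source).

noise_free_sources <- function(f14c = c(peat = 0.4, modern = 1.0)) {
  Map(function(nm, f) end_member(nm, d13c = c(-28, 0), f14c = c(f, 0)),
      names(f14c), as.list(unname(f14c)))
}

outgassing_problem <- function(mix_f14c, mix_sd = 0,
                               src_f14c = c(peat = 0.4, modern = 1.0)) {
  mixing_problem(
    "outgassing",
    unname(noise_free_sources(src_f14c)),
    mixture_obs("test-lake", d13c = c(-25, 0), f14c = c(mix_f14c, mix_sd))
  )
}

random_three_source_system <- function() {
  S <- rbind(
    d13c = c(stats::runif(1, -32, -24), stats::runif(1, -32, -24),
             stats::runif(1, -12, -8)),
    f14c = c(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.9, 1.1),
             stats::runif(1, 0.95, 1.05))
  )
  colnames(S) <- c("peat", "modern", "atmosphere")
  S
}

random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Independent oracle for the annual-mass arithmetic: convert every factor
# to SI step by step, tracking units explicitly.
unit_tracked_annual_mass <- function(flux_mmol_m2_d, area_km2, fraction) {
  mol_m2_d <- flux_mmol_m2_d / 1000          # mmol -> mol
  g_m2_d <- mol_m2_d * 12.011                # mol C -> g C
  m2 <- area_km2 * 1000 * 1000               # km^2 -> m^2
  g_d <- g_m2_d * m2
  g_yr <- g_d * 365
  g_yr * fraction / 1e9                      # g -> Gg
}
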