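# Independent oracles used by the tests; these never call the code
# paths they check.

# Brute-force mass-action scan for the ADP-metal 1:1 equilibrium:
# iterative grid refinement of the complex concentration down to the
# requested resolution, minimizing |(A0-x)(M0-x) - Kd x|.
oracle_complex_scan <- function(a0, m0, kd, resolution = 1e-6) {
  hi <- min(a0, m0)
  if (hi == 0) return(0)
  lo <- 0
  repeat {
    x <- seq(lo, hi, length.out = 1001)
    res <- abs((a0 - x) * (m0 - x) - kd * x)
    i <- which.min(res)
    step <- x[2] - x[1]
    if (step <= resolution) return(x[i])
    lo <- max(0, x[i] - 2 * step)
    hi <- min(min(a0, m0), x[i] + 2 * step)
  }
}

# Standard substrate / inhibitor designs reused across tests: levels
# spread geometrically around the relevant constant.
span_levels <- function(center, factors = c(0.25, 0.5, 1, 2, 4))
  center * factors

# One synthetic dead-end evidence set following the published pattern
# template (analog competitive vs its own substrate, NC or MT vs the
# other), from random rate-law truths. Returns the mechanism call of
# the full pipeline.
pipeline_mechanism_call <- function(vmax, ka, kb, ki_ox, ki_cr,
                                    alpha_mt) {
  bp <- bisubstrate_params(vmax, ka, kb)
  grid <- gen_bisubstrate_grid(bp,
                               a_levels = span_levels(ka, c(0.2, 0.5, 1, 2, 5)),
                               b_levels = span_levels(kb, c(0.3, 0.8, 1.5, 3, 10)))
  iv <- classify_initial_velocity(reciprocal_lines(grid))
  mk_grid <- function(mode, km, ki, alpha = NULL)
    gen_inhibition_grid(
      inhibition_params(vmax, km, ki, mode, alpha = alpha),
      s_levels = span_levels(km, c(0.25, 0.5, 1, 2, 4, 8)),
      i_levels = ki * c(0, 0.5, 1, 2))
  ev <- list(
    initial_velocity = iv,
    oxalate_vs_A = classify_inhibition(mk_grid("C", ka, ki_ox)),
    oxalate_vs_B = classify_inhibition(mk_grid("MT", kb, ki_ox,
                                               alpha = alpha_mt)),
    adpcr_vs_A = classify_inhibition(mk_grid("NC", ka, ki_cr)),
    adpcr_vs_B = classify_inhibition(mk_grid("C", kb, ki_cr)))
  infer_mechanism(ev)
}
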