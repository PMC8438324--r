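# Shared fixtures: canonical parameter sets used across test files.

lv_demo <- function() lv_params(a = 1, b = 0.2, c = 0.5, d = 0.5)

# base Allee/injury set; the predator death rate c selects the regime
allee_demo <- function(c = 0.4) {
  allee_params(a = 0.01, K = 10, L = 1, c = c, d = 0.5, g = 0,
               response = functional_response(b = 0.1))
}

# tumor-immune set with d_eff = rho*s/mu_A = 0.2 > g: predator-prey side,
# coexistence at C* = mu_E/((d_eff - g) b) = 11.1 < K_C
ti_demo <- function(g = 0.02) {
  ti_params(r = 0.5, K_C = 50, response = functional_response(b = 0.05),
            s = 0.4, mu_A = 1, rho = 0.5, mu_E = 0.1, g = g)
}
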