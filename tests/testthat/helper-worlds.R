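# Shared small worlds for unit tests. Kept tiny: these back fast unit tests,
# not the acceptance simulations.

tiny_stack <- function(seed = 7, n_layers = 3, nrow = 50, ncol = 50) {
  simulate_climate_stack(n_layers, nrow, ncol, autocorr_length = 5,
                         seed = seed)
}

# a deterministic 2-layer stack with hand-set values on a 2x2 grid
hand_stack <- function() {
  l1 <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  l2 <- matrix(c(4, 3, 2, 1), 2, 2, byrow = TRUE)
  climate_stack(list(l1, l2), c("a", "b"))
}

# wrap a raw matrix (summing to 1 over non-NA) as a suitability_surface
surface_from_raw <- function(raw, model = NULL) {
  structure(list(raw = raw, logistic = raw / max(raw, na.rm = TRUE),
                 c = 1, model = model, nrow = nrow(raw), ncol = ncol(raw),
                 mask = !is.na(raw)),
            class = "suitability_surface")
}

light_config <- function(fc = "L", rm = 1, nb = 2500)
  sdm_config(fc = fc, rm = rm, n_background = nb)
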