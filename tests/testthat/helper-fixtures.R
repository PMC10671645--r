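## shared fixtures: the reference physiology is loaded once per test run
ref_phys <- suppressMessages(load_physiology())

rel_dev <- function(x, y) abs(x - y) / abs(y)

## sup-norm relative deviation between two state x time matrices,
## normalized per time point by the largest reference concentration
sup_rel_dev <- function(x, ref) {
  scale <- apply(abs(ref), 2, max)
  max(abs(x - ref) / rep(pmax(scale, 1e-300), each = nrow(ref)))
}
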