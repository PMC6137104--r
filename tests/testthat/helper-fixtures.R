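# Shared fixtures, built in code. Unit tests use a coarser 1024-channel
# grid over the same 50 ns window as the 4096-channel default; fit quality
# is count-limited, not channel-limited.
small_irf <- function(n = 1024, dt = 0.0488) make_irf(0.25, 2, n, dt)

test_donor <- function() donor_spec(c(0.2, 0.8), c(1.5, 4.1))

single_donor <- function(tau = 4) donor_spec(1, tau)

# deterministic interdye-distance triplets for multi-variant fixtures
variant_distances <- function(n = 10) variant_network_distances()[seq_len(n)]

# tiny two-domain frame for structure tests: beads at explicit coordinates
mini_frame <- function(xyz, residues, domains = NULL) {
  tibble::tibble(residue = residues,
                 element = "BEAD",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 mass = 1)
}
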