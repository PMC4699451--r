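# Shared fixtures: everything is generated in code at test time.

# A small, fast simulation setup (default active-zone physics, fewer events).
quick_sim_config <- function(..., stop_events = 800L) {
  sim_config(stop_events = stop_events, ...)
}

# Build a histogram_data object directly from known edges and density
# (used for self-fit checks against exactly evaluated model curves).
manual_histogram <- function(edges, density) {
  h <- edges[2L] - edges[1L]
  structure(list(bin_edges = edges,
                 counts = round(density * h * 1e6),
                 density = density,
                 mids = edges[-1L] - h / 2),
            class = "histogram_data")
}

# Closed-form mean first-passage time for diffusion on an interval of
# length L with one absorbing and one reflecting end, start position
# averaged uniformly: E[T] = L^2 / (3 D).
mfpt_uniform <- function(L, D) L^2 / (3 * D)
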