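# shared fixtures, built in code

# small, fast grid for unit tests (256 bins x 195.2 ps = same 50 ns window)
small_config <- function(...) {
  sim_config(n_bins = 256L, bin_width_ps = 195.2, ...)
}

# noiseless Gaussian-pulse IRF (no reference-dye tail, no dark background)
gaussian_irf <- function(config = sim_config(), channel = 4L) {
  cfg <- config
  cfg$irf_reference_lifetime_ps <- 0
  cfg$dark_offset <- 0
  simulate_irf(cfg, noiseless = TRUE, channel = channel)
}

# delta-function IRF kernel on an n-bin grid
delta_kernel <- function(n) c(1, rep(0, n - 1L))

# shrunken cohort spec (2 animals/group, 2 weeks) for fast pipeline tests
shrunk_spec <- function(n = 2L, weeks = c(1, 16)) {
  s <- default_cohort_spec()
  s$group_sizes <- s$group_sizes[s$group_sizes$week %in% weeks, ]
  s$group_sizes$AMC <- n
  s$group_sizes$MI <- n
  s$params <- s$params[s$params$week %in% weeks, ]
  s
}

tiny_cohort <- function(seed = 42L, channels = 4L, rois = "LVP",
                        config = small_config(), spec = shrunk_spec()) {
  generate_cohort(spec, config = config, seed = seed,
                  channels = channels, rois = rois)
}
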