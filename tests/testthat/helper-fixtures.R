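# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

bare_params <- function(noise = 0.05)
  render_params(ridge_height_nm = preblur_ridge_height(0.6),
                noise_sd_nm = noise)

# a straight horizontal rod of given length, rendered at bare-DNA height
straight_rod_image <- function(length_nm = 328, noise = 0, height_nm = 0.6) {
  pr <- render_params(ridge_height_nm = preblur_ridge_height(height_nm),
                      noise_sd_nm = noise)
  render_afm(rbind(c(0, 0), c(length_nm, 0)), pr, seed = 7)
}

# native-resolution WLC ensemble (traces at the generator segment length,
# where the discrete chain laws are exact)
native_wlc_traces <- function(n_chains = 300, n_segments = 114, seg_len = 8,
                              lp = 56, seed = 101) {
  memo(sprintf("native_%d_%d_%g_%g_%d", n_chains, n_segments, seg_len, lp,
               seed), {
    seeds <- seed + seq_len(n_chains)
    lapply(seeds, function(s)
      as_trace(sample_wlc_2d(n_segments, seg_len, lp, s)))
  })
}

# small rendered bare-DNA ensemble traced end to end
traced_bare_ensemble <- function(n = 8, seed = 2024) {
  memo(sprintf("bare_%d_%d", n, seed), {
    ens <- make_condition_ensemble(condition_bare_dna(n), seed)
    traces <- list()
    for (e in ens) {
      regs <- segment_molecules(e$image, height_band = c(0.6, 0.6))
      for (rg in regs)
        if (rg$class_hint == "linear")
          traces[[length(traces) + 1L]] <- trace_backbone(e$image, rg, 8)
    }
    list(ensemble = ens, traces = traces)
  })
}
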