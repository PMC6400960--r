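# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_axis <- function() fixture("axis", function() temporal_axis())
fx_irf <- function() fixture("irf", function() gaussian_irf(fx_axis()))
fx_bank512 <- function() fixture("bank512", function() build_hadamard_bank(1024, 512))
fx_bank1024 <- function() fixture("bank1024", function() build_hadamard_bank(1024, 1024))
fx_bank64 <- function() fixture("bank64", function() build_hadamard_bank(64, 64, side = 8))

# small scene: one glyph, level 3, deterministic
fx_scene <- function() fixture("scene", function()
  make_scene(list(make_glyph(3)), level = "3", rng_seed = 7))

# tiny network configuration for fast structural/gradient tests
fx_tiny_cfg <- function(...) {
  net_config(n_gates = 8L, n_meas = 16L, img_side = 8L, gate_pool = 1L,
             res_channels = 3L, recon_c1 = 3L, recon_c2 = 2L,
             recon_k1 = 3L, recon_k3 = 3L, mix_kernel = 3L,
             conv1d_kernel = 3L, conv1d_stride = 2L, conv1d_filters = 2L,
             intensity_gain = 1, batch_size = 4L, max_epochs = 5L,
             rng_seed = 11L, ...)
}
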