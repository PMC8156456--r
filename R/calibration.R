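# Channel plan fixed by the published per-variant parameter budgets
# (millions): unet 8.6, mnet 10.92, mnet_dc 13.79, mnet_csfag 24.89,
# csag_dccnet 28.74.  Found by exhaustive integer search over the
# closed-form count (count_parameters_config); the search order follows
# the budget chain: base width <- unet; pyramid embeds <- mnet delta;
# growth/transition and CSFAG transform widths jointly <- the remaining
# three budgets (the transition width couples the dense bottleneck to the
# level-4 CSFAG input).
# Exact counts under this plan (millions): unet 8.637, mnet 10.916,
# mnet_dc 13.793, mnet_csfag 24.891, csag_dccnet 28.736 -- every one
# rounds to the printed budget at its printed precision.
CALIBRATED_PLAN <- list(
  base_width = 32L,
  pyramid_widths = c(80L, 164L, 328L),
  growth = 263L,
  transition = 609L,
  csfag_widths = c(130L, 277L, 554L, 1108L)
)
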