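# Six-shell anisotropic spherical conductor profile for rat somatosensory
# cortex. SYNTHETIC plausible values (S/m), not a published measured
# profile; edit to taste. Pia at the outer radius; depth = radius deficit.
outer_sigma: 0.10
shells:
  - radius_um: 2100            # subcortical core (isotropic)
    sigma_radial: 0.25
    sigma_tangential: 0.25
  - radius_um: 2500            # layer 6
    sigma_radial: 0.35
    sigma_tangential: 0.25
  - radius_um: 3100            # layer 5
    sigma_radial: 0.40
    sigma_tangential: 0.28
  - radius_um: 3350            # layer 4
    sigma_radial: 0.45
    sigma_tangential: 0.30
  - radius_um: 3850            # layers 2/3
    sigma_radial: 0.35
    sigma_tangential: 0.26
  - radius_um: 4000            # layer 1
    sigma_radial: 0.30
    sigma_tangential: 0.30
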