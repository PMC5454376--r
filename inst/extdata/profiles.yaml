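# Default perturbation profiles for the synthetic peak-list generator.
# Residue numbering: UniProt P08754 (Galpha-i3), protein length 354.
#
# givct: emulates binding of the GBA-containing GIV C-terminal construct —
#   strong global line broadening (median 3-fold intensity attenuation),
#   two tryptophan signals broadened beyond detection, ~15% of residues
#   with significant CSPs concentrated on the SwII/alpha3 cleft and the
#   phosphate-binding elements.
# givpept: the short GBA-motif peptide — same binding site, modest global
#   attenuation (median intensity decrease 15%, i.e. median ratio 1/0.85).
givct:
  reference_residue: 354
  offset_H: 0.09
  offset_N: -1.1
  sigma_H: 0.01
  sigma_N: 0.05
  intensity_cv: 0.05
  intensity_sdlog: 0.4
  attenuation_median: 3.0
  attenuation_sigma: 0.35
  broadened_out: [211, 258]
  csp_median_ppm: 0.15
  csp_sdlog: 0.4
  shifted_fraction_target: 0.15
  core_site_segments: ["G-1/P-loop", "SwI", "SwII"]
  peripheral_site_segments: ["beta1", "alpha3", "alpha3-beta5"]
givpept:
  reference_residue: 354
  offset_H: 0.09
  offset_N: -1.1
  sigma_H: 0.01
  sigma_N: 0.05
  intensity_cv: 0.05
  intensity_sdlog: 0.4
  attenuation_median: 1.1764705882352942
  attenuation_sigma: 0.35
  broadened_out: [211, 258]
  csp_median_ppm: 0.15
  csp_sdlog: 0.4
  shifted_fraction_target: 0.15
  core_site_segments: ["G-1/P-loop", "SwI", "SwII"]
  peripheral_site_segments: ["beta1", "alpha3", "alpha3-beta5"]
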