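# Labeling-geometry preset catalogue (all lengths in nm).
#
# The microtubule wall has outer radius 12.5 (25 nm diameter); a primary +
# secondary IgG stack adds 17.5 of radial linker; DNA-modified secondary
# antibodies add 42 bases of DNA.  The conformation field selects the
# effective fluorophore shell:
#   free     - unexpanded, unanchored label: orientation-averaged ring at
#              structure_radius + orientation_factor * linker
#   extended - gel-anchored, taut linker (dsDNA at 0.34 nm/base)
#   coiled   - ssDNA coiled during gelation (worm-like chain, 0.6 nm/base
#              contour, persistence length 2.5)
# sigma_loc is the localization-precision blur of the rendered profiles;
# 6 is used for the rhodamine (Alexa 532 class) data sets, 9 for the
# DNA/cyanine data sets.  These values pin the simulation parameter set
# used for every quantitative prediction of the forward model.

igg:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 0
  linker_conformation: free
  orientation_factor: 0.65
  expands_structure: true
  expands_linker: true
  sigma_loc: 6.0

igg_pre:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 0
  linker_conformation: extended
  expands_structure: true
  expands_linker: true
  sigma_loc: 6.0

igg_post:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 0
  linker_conformation: extended
  expands_structure: true
  expands_linker: false
  sigma_loc: 6.0

dna42:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 42
  linker_conformation: free
  orientation_factor: 0.60
  expands_structure: true
  expands_linker: true
  sigma_loc: 9.0

dna42_dsdna:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 42
  linker_conformation: extended
  expands_structure: true
  expands_linker: true
  sigma_loc: 9.0

dna42_ssdna:
  structure_radius: 12.5
  linker_igg: 17.5
  dna_bases: 42
  linker_conformation: coiled
  expands_structure: true
  expands_linker: true
  sigma_loc: 9.0

pre_post_mix:
  type: mix
  pre: igg_pre
  post: igg_post
  ratio: 0.1
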