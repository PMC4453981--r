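# Example analysis parameter file. Q in nm^-1, lengths in nm,
# divergence in radians, spread as a fractional FWHM.
wide:
  qmin: 0.05
  qmax: 1.6
rg:
  qmin: 0.0
  qmax: 0.5
  fitmin: 0.1
  fitmax: 0.3
rxs1:
  qmin: 0.3
  qmax: 0.9
  fitmin: 0.35
  fitmax: 0.6
rxs2:
  qmin: 0.6
  qmax: 1.4
  fitmin: 0.7
  fitmax: 1.2
sphere:
  cutoff: 4
  boxside: 0.55
hydrate:
  positions: 26
  cutoff: 11
curve:
  qmax: 1.6
  npoints: 100
  radbins: 400
  smear: false
  wavelength: 0.6
  spread: 0.1
  divergence: 0.016
rfac:
  qmin: 0.1
  qmax: 1.6
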