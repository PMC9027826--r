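# Seven-population rate model of the cortico-cerebello-thalamo-cortical loop.
#
# Each population j obeys
#   tau_j * dr_j/dt = -r_j + S_j( sum_i W[i->j] r_i + background_j + drive_j )
# with the logistic transfer S(x) = max_rate / (1 + exp(-slope * (x - threshold))).
# The external stimulation drive enters at the DCN only.
#
# The parameterization is calibrated so that (i) the unforced deep-cerebellar-
# nuclei population sits at 56.6 spikes/s, (ii) a constant (tDCS-like) DCN
# drive at the reference operating point pushes the thalamocortical
# CTX-nRT-Vim loop across its Hopf bifurcation into a gamma-band (>30 Hz)
# limit cycle, and (iii) with a zero-mean 63 Hz amplitude-modulated drive the
# slower CTX-STN-GPi-Vim loop dominates and the cortical rhythm stays in the
# beta band. Background drives place each population at its stated operating
# rate; they were solved from the operating rates and the weights below, so
# editing either requires re-solving the other.
version: 1
populations:
  CTX: {tau: 0.006, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -50.054651, operating_rate: 40.0}
  VIM: {tau: 0.006, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -75.524651, operating_rate: 40.0}
  NRT: {tau: 0.006, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -90.635616, operating_rate: 2.5}
  DCN: {tau: 0.020, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: 2.655495, operating_rate: 56.6}
  STN: {tau: 0.018, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -50.493293, operating_rate: 55.0}
  GPE: {tau: 0.014, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -16.500000, operating_rate: 50.0}
  GPI: {tau: 0.018, max_rate: 100.0, slope: 0.10, threshold: 0.0, background: -14.500000, operating_rate: 50.0}
reference_rates:
  dcn_baseline: 56.6      # spikes/s, deep cerebellar nuclei at rest
  purkinje: 63.0          # spikes/s, Purkinje-cell reference; motivates the 63 Hz beat
connections:              # sign follows the source population type
  - {from: DCN, to: VIM, weight: 1.70}
  - {from: VIM, to: CTX, weight: 1.15}
  - {from: CTX, to: VIM, weight: 0.40}
  - {from: CTX, to: NRT, weight: 1.05}
  - {from: VIM, to: NRT, weight: 0.30}
  - {from: NRT, to: VIM, weight: -1.30}
  - {from: CTX, to: STN, weight: 1.50}
  - {from: STN, to: GPE, weight: 0.30}
  - {from: GPE, to: STN, weight: -0.15}
  - {from: STN, to: GPI, weight: 0.40}
  - {from: GPE, to: GPI, weight: -0.15}
  - {from: GPI, to: VIM, weight: -0.75}
stimulation:
  dcn_gain_per_mA: 10.0   # model-input units delivered to the DCN per mA
  tdcs_reference_mA: 2.0  # constant-drive operating point
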