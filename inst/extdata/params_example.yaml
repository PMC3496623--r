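# Example gIF network: 3 excitatory + 1 inhibitory neurons.
#
# Units: time in spike durations (one raster step); voltages relative
# to the rest potential (which is also the mean reset value), so the
# threshold is positive; conductances/capacitances/currents in
# mutually consistent arbitrary units.  With C = 1 and g_L = 0.5 the
# leak time is 2 steps; synaptic decay times are 2 steps (exponential
# kernel, profile_degree 0).
"N": 4
C: 1.0
theta: 8.0
E_L: 0.0
E_plus: 65.0
E_minus: -5.0
g_L: 0.5
pop: [E, E, E, I]
G:
  - [0.00, 0.08, 0.05, 0.30]
  - [0.10, 0.00, 0.07, 0.25]
  - [0.06, 0.09, 0.00, 0.20]
  - [0.08, 0.05, 0.10, 0.00]
tau_syn: 2.0
profile_degree: 0
sigma_B: 1.5
sigma_R: 1.0
i_ext: [3.0, 3.0, 3.0, 3.5]
tau_sep: 1
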