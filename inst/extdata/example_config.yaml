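# Reference configuration: one two-input neuron learning a noiseless
# spatio-temporal pattern. All values are the package defaults written out
# explicitly; times are in simulation steps.
n_inputs: 2
n_neurons: 1
w: 10000
ddr: 1
dr_max: 400
inh_max: 100
inh_decay: 1
T: 400
PW: 20
sigma: 0
p_signal: 1
noise_rate: 0
n_presentations: 100
n_simulations: 20
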