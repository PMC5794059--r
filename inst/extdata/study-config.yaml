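# Study configuration: 6-cell colony at the synchronization-study
# parameterisation.  All omitted oscillator keys take the study defaults
# (gamma_A = 23, gamma_H = 0.023, D1 = 100 um^2/s).
experiment: simulate
seed: 1
oscillator:
  gamma_A: 23
  gamma_H: 0.023
  D1: 100
channel_green:
  alpha_TC: 40
  K_TC: 800
  n_TC: 2
  K: 100
  n1: 2
  gamma_R: 1.5
light_schedule:
  - time: 0
    condition: green
colony:
  n_cells: 6
  t_final: 500
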