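n_patients: 2
n_days: 5
scenarios: realistic
window_len: 30
ph: 30
fractions:
- '0.69999999999999996'
- '0.20000000000000001'
- '0.10000000000000001'
archs:
- cnn
- lstm
grid: none
train:
  learning_rate: 0.05
  max_epochs: 18
  patience: 10
  standardize: yes
normalize: yes
quantization:
- dynamic_range
- full_integer
calib_n: 300
out_dir: cgmcast_example_run
seed: 1
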