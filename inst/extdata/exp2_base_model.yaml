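conditions:
- label: seq2
  lineup_format: sequential
  lineup_size: 2
  sampling_constant: 0.5
  n_participants: 408
- label: seq5
  lineup_format: sequential
  lineup_size: 5
  sampling_constant: 0.2
  n_participants: 401
- label: sim2
  lineup_format: simultaneous
  lineup_size: 2
  sampling_constant: 0.5
  n_participants: 393
- label: sim5
  lineup_format: simultaneous
  lineup_size: 5
  sampling_constant: 0.2
  n_participants: 394
parameters:
  dP:
    groups:
    - seq2
    - seq5
    - sim2
    - sim5
  dA:
    groups:
    - all
    - all
    - all
    - all
  b:
    groups:
    - all
    - all
    - all
    - all
  g:
    groups:
    - seq2
    - seq5
    - sim2
    - sim5
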