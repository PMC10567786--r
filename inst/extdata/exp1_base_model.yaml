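conditions:
- label: seq3
  lineup_format: sequential
  lineup_size: 3
  sampling_constant: 0.33333
  n_participants: 382
- label: seq6
  lineup_format: sequential
  lineup_size: 6
  sampling_constant: 0.16667
  n_participants: 393
- label: sim3
  lineup_format: simultaneous
  lineup_size: 3
  sampling_constant: 0.33333
  n_participants: 380
- label: sim6
  lineup_format: simultaneous
  lineup_size: 6
  sampling_constant: 0.16667
  n_participants: 382
parameters:
  dP:
    groups:
    - seq3
    - seq6
    - sim3
    - sim6
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
    - seq3
    - seq6
    - sim3
    - sim6
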