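source_detector_distance_cm: 3.0
optodes:
- id: S1
  row: 1
  col: 1
- id: D1
  row: 1
  col: 2
- id: S2
  row: 1
  col: 3
- id: D2
  row: 1
  col: 4
- id: S3
  row: 1
  col: 5
- id: D3
  row: 1
  col: 6
- id: S4
  row: 1
  col: 7
- id: D4
  row: 1
  col: 8
- id: S5
  row: 1
  col: 9
- id: D5
  row: 1
  col: 10
- id: S6
  row: 1
  col: 11
- id: D6
  row: 2
  col: 1
- id: S7
  row: 2
  col: 2
- id: D7
  row: 2
  col: 3
- id: S8
  row: 2
  col: 4
- id: D8
  row: 2
  col: 5
- id: S9
  row: 2
  col: 6
- id: D9
  row: 2
  col: 7
- id: S10
  row: 2
  col: 8
- id: D10
  row: 2
  col: 9
- id: S11
  row: 2
  col: 10
- id: D11
  row: 2
  col: 11
- id: S12
  row: 3
  col: 1
- id: D12
  row: 3
  col: 2
- id: S13
  row: 3
  col: 3
- id: D13
  row: 3
  col: 4
- id: S14
  row: 3
  col: 5
- id: D14
  row: 3
  col: 6
- id: S15
  row: 3
  col: 7
- id: D15
  row: 3
  col: 8
- id: S16
  row: 3
  col: 9
- id: D16
  row: 3
  col: 10
- id: S17
  row: 3
  col: 11
channels:
- id: C1
  source: S2
  detector: D2
- id: C2
  source: S3
  detector: D2
- id: C3
  source: S3
  detector: D3
- id: C4
  source: S4
  detector: D3
- id: C5
  source: S4
  detector: D4
- id: C6
  source: S5
  detector: D4
- id: C7
  source: S2
  detector: D7
- id: C8
  source: S8
  detector: D2
- id: C9
  source: S3
  detector: D8
- id: C10
  source: S9
  detector: D3
- id: C11
  source: S4
  detector: D9
- id: C12
  source: S10
  detector: D4
- id: C13
  source: S5
  detector: D10
- id: C14
  source: S8
  detector: D7
- id: C15
  source: S8
  detector: D8
- id: C16
  source: S9
  detector: D8
- id: C17
  source: S9
  detector: D9
- id: C18
  source: S10
  detector: D9
- id: C19
  source: S10
  detector: D10
- id: C20
  source: S13
  detector: D7
- id: C21
  source: S8
  detector: D13
- id: C22
  source: S14
  detector: D8
- id: C23
  source: S9
  detector: D14
- id: C24
  source: S15
  detector: D9
- id: C25
  source: S10
  detector: D15
- id: C26
  source: S16
  detector: D10
- id: C27
  source: S13
  detector: D13
- id: C28
  source: S14
  detector: D13
- id: C29
  source: S14
  detector: D14
- id: C30
  source: S15
  detector: D14
- id: C31
  source: S15
  detector: D15
- id: C32
  source: S16
  detector: D15
- id: C33
  source: S1
  detector: D1
- id: C34
  source: S2
  detector: D1
- id: C35
  source: S7
  detector: D6
- id: C36
  source: S7
  detector: D7
- id: C37
  source: S12
  detector: D12
- id: C38
  source: S13
  detector: D12
- id: C39
  source: S1
  detector: D6
- id: C40
  source: S7
  detector: D1
- id: C41
  source: S12
  detector: D6
- id: C42
  source: S7
  detector: D12
- id: C43
  source: S5
  detector: D5
- id: C44
  source: S6
  detector: D5
- id: C45
  source: S11
  detector: D10
- id: C46
  source: S11
  detector: D11
- id: C47
  source: S16
  detector: D16
- id: C48
  source: S17
  detector: D16
- id: C49
  source: S11
  detector: D5
- id: C50
  source: S6
  detector: D11
- id: C51
  source: S11
  detector: D16
- id: C52
  source: S17
  detector: D11
in_use:
- C1
- C2
- C3
- C4
- C5
- C6
- C7
- C8
- C9
- C10
- C11
- C12
- C13
- C14
- C15
- C16
- C17
- C18
- C19
- C20
- C21
- C22
- C23
- C24
- C25
- C26
- C27
- C28
- C29
- C30
- C31
- C32
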