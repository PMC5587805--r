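pos0:
- id: p0.argB_G
  base: G
  confidence: common
  conditions:
    p0_b: R
- id: p0.argA_C
  base: C
  confidence: common
  conditions:
    p0_a: R
- id: p0.proTyr_C
  base: C
  confidence: uncommon
  conditions:
    p0_a: P
    p0_b: 'Y'
- id: p0.small_N
  base: 'N'
  confidence: common
  conditions:
    p0_a:
    - S
    - A
    - G
    p0_b:
    - S
    - A
    - G
- id: p0.fallback
  base: 'N'
  confidence: default
pos1:
- id: p1.minor_large_A
  base: A
  confidence: common
  conditions:
    p1_minor[1]:
    - H
    - K
    - R
    p1_minor[2]:
    - H
    - K
    - R
- id: p1.fallback
  base: 'N'
  confidence: default
pos2:
- id: p2.lys_C
  base: C
  confidence: common
  conditions:
    p2_main: K
- id: p2.asn_T
  base: T
  confidence: common
  conditions:
    p2_main: 'N'
- id: p2.fallback
  base: 'N'
  confidence: default
pos3:
- id: p3.his_C
  base: C
  confidence: common
  conditions:
    p3_main: H
- id: p3.acidic_G
  base: G
  confidence: common
  conditions:
    p3_main:
    - D
    - E
- id: p3.fallback
  base: 'N'
  confidence: default
pos4:
- id: p4.SxR_G
  base: G
  confidence: common
  special: loop_SxR
- id: p4.RxS_C
  base: C
  confidence: common
  special: loop_RxS
- id: p4.fallback
  base: 'N'
  confidence: default
pos5:
- id: p5.mtase_A
  base: A
  confidence: common
  special: always
pos6:
- id: p6.nonspecific
  base: 'N'
  confidence: common
  conditions:
    p6_small:
    - G
    - A
    - S
    p6_asn: 'N'
- id: p6.fallback
  base: 'N'
  confidence: low-confidence
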