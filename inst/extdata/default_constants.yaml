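design:
  ss_default: 30.0
  rt:
    RT1:
      ss:
      - 25.0
      - 35.0
      pi:
      - 30.0
      - 50.0
      sva:
        back: -3.0
        med: 3.0
        front: 9.0
      vertebral_rotation:
        L1: -17.0
        L2: -22.0
        L3: -27.0
        L4: -19.0
        L5: -8.0
    RT2:
      ss:
      - 25.0
      - 35.0
      pi:
      - 30.0
      - 50.0
      sva:
        back: -4.9
        med: 1.1
        front: 7.1
      vertebral_rotation:
        L1: -12.0
        L2: -13.0
        L3: -8.0
        L4: -1.0
        L5: 9.0
    RT3:
      ss:
      - 35.0
      - 45.0
      pi:
      - 40.0
      - 60.0
      sva:
        back: -4.5
        med: 1.5
        front: 7.5
      vertebral_rotation:
        L1: -20.0
        L2: -22.0
        L3: -12.0
        L4: -2.0
        L5: 22.0
    RT4:
      ss:
      - 45.0
      - 55.0
      pi:
      - 50.0
      - 70.0
      sva:
        back: -6.3
        med: -0.3
        front: 6.3
      vertebral_rotation:
        L1: -20.0
        L2: -14.0
        L3: -2.0
        L4: 9.0
        L5: 30.0
geometry:
  endplate_width: 0.05
  hip_drop: 0.09
  lumbar_length:
    L1: 0.035
    L2: 0.035
    L3: 0.035
    L4: 0.035
    L5: 0.035
  lumbar_com_anterior:
    L1: 0.03
    L2: 0.035
    L3: 0.04
    L4: 0.04
    L5: 0.04
  thorax_length: 0.42
  thorax_com_height: 0.231
  thorax_com_anterior: 0.04
  shoulder_height: 0.378
  shoulder_anterior: 0.05
  head_com_height: 0.12
  head_com_anterior: 0.02
  t12_offset_deg: -8.0
  thoracic_rot_limit: 45.0
masses:
  total: 75.0
  fractions:
    head_neck: 0.081
    arms: 0.1
    thorax: 0.216
    L1: 0.0276
    L2: 0.0276
    L3: 0.0276
    L4: 0.0276
    L5: 0.0276
    pelvis: 0.142
    legs: 0.323
muscles:
  multifidus:
    strength: 500.0
    deep_strength: 600.0
    t12_strength: 700.0
    posterior_offset: 0.035
    sacral_origin:
    - -0.04
    - -0.03
  erector_spinae:
    strength: 2200.0
    sacral_origin:
    - -0.04
    - -0.05
    thorax_insertion:
    - -0.095
    - 0.1
  rectus_abdominis:
    strength: 1000.0
    pelvis_origin:
    - 0.115
    - -0.075
    thorax_insertion:
    - 0.07
    - 0.055
  psoas:
    strength: 180.0
    anterior_offset: 0.015
    pelvis_insertion:
    - 0.025
    - -0.1
  abdominal_pressure:
    enabled: no
    extension_moment: 0.0
solver:
  criterion_power: 3.0
  tol: 1.0e-09
  max_iter: 200.0
gravity: 9.81
body_height: 1.76
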