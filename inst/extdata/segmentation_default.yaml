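segments:
- name: hand_left
  side: left
  group: hand
  density_kg_m3: 1000.0
  proximal: wrist_left
  distal: dactylion_left
  axis: z
  planes:
  - origin: wrist_left
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: forearm_left
  side: left
  group: forearm
  density_kg_m3: 1000.0
  proximal: elbow_left
  distal: wrist_left
  axis: z
  planes:
  - origin: elbow_left
    normal:
    - shoulder_right
    - shoulder_left
    side: +
  - origin: wrist_left
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
- name: upper_arm_left
  side: left
  group: upper_arm
  density_kg_m3: 1000.0
  proximal: shoulder_left
  distal: elbow_left
  axis: z
  planes:
  - origin: shoulder_left
    normal:
    - shoulder_right
    - shoulder_left
    side: +
  - origin: elbow_left
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
- name: hand_right
  side: right
  group: hand
  density_kg_m3: 1000.0
  proximal: wrist_right
  distal: dactylion_right
  axis: z
  planes:
  - origin: wrist_right
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
- name: forearm_right
  side: right
  group: forearm
  density_kg_m3: 1000.0
  proximal: elbow_right
  distal: wrist_right
  axis: z
  planes:
  - origin: elbow_right
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
  - origin: wrist_right
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: upper_arm_right
  side: right
  group: upper_arm
  density_kg_m3: 1000.0
  proximal: shoulder_right
  distal: elbow_right
  axis: z
  planes:
  - origin: shoulder_right
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
  - origin: elbow_right
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: head
  side: central
  group: head
  density_kg_m3: 1000.0
  proximal: neck
  distal: vertex
  axis: z
  planes:
  - origin: neck
    normal:
    - mid_hip
    - neck
    side: +
- name: trunk
  side: central
  group: trunk
  density_kg_m3: 940.0
  proximal: neck
  distal: mid_hip
  axis: z
  planes:
  - origin: neck
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: mid_hip
    normal:
    - mid_hip
    - neck
    side: +
  - origin: shoulder_left
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
  - origin: shoulder_right
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: thigh_left
  side: left
  group: thigh
  density_kg_m3: 1000.0
  proximal: hip_left
  distal: knee_left
  axis: z
  planes:
  - origin: mid_hip
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: knee_left
    normal:
    - mid_hip
    - neck
    side: +
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: shank_left
  side: left
  group: shank
  density_kg_m3: 1000.0
  proximal: knee_left
  distal: ankle_left
  axis: z
  planes:
  - origin: knee_left
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: ankle_left
    normal:
    - mid_hip
    - neck
    side: +
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: foot_left
  side: left
  group: foot
  density_kg_m3: 1000.0
  proximal: heel_left
  distal: toe_left
  axis: x
  planes:
  - origin: ankle_left
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: +
- name: thigh_right
  side: right
  group: thigh
  density_kg_m3: 1000.0
  proximal: hip_right
  distal: knee_right
  axis: z
  planes:
  - origin: mid_hip
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: knee_right
    normal:
    - mid_hip
    - neck
    side: +
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
- name: shank_right
  side: right
  group: shank
  density_kg_m3: 1000.0
  proximal: knee_right
  distal: ankle_right
  axis: z
  planes:
  - origin: knee_right
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: ankle_right
    normal:
    - mid_hip
    - neck
    side: +
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
- name: foot_right
  side: right
  group: foot
  density_kg_m3: 1000.0
  proximal: heel_right
  distal: toe_right
  axis: x
  planes:
  - origin: ankle_right
    normal:
    - mid_hip
    - neck
    side: '-'
  - origin: mid_hip
    normal:
    - shoulder_right
    - shoulder_left
    side: '-'
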