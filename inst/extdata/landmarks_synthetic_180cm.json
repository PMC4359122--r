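{
  "vertex": [0, 0, 1.8],
  "floor": [0, 0, 0],
  "neck": [0, 0, 1.566],
  "xiphoid": [0, 0, 1.3548],
  "omphalion": [0, 0, 1.1472],
  "mid_hip": [0, 0, 0.936],
  "shoulder_left": [0, 0.2376, 1.476],
  "elbow_left": [0, 0.5868, 1.476],
  "wrist_left": [0, 0.864, 1.476],
  "dactylion_left": [0, 1.0656, 1.476],
  "hip_left": [0, 0.117, 0.936],
  "knee_left": [0, 0.117, 0.5022],
  "ankle_left": [0, 0.117, 0.117],
  "heel_left": [-0.081, 0.117, 0.0567],
  "toe_left": [0.189, 0.117, 0.0567],
  "shoulder_right": [0, -0.2376, 1.476],
  "elbow_right": [0, -0.5868, 1.476],
  "wrist_right": [0, -0.864, 1.476],
  "dactylion_right": [0, -1.0656, 1.476],
  "hip_right": [0, -0.117, 0.936],
  "knee_right": [0, -0.117, 0.5022],
  "ankle_right": [0, -0.117, 0.117],
  "heel_right": [-0.081, -0.117, 0.0567],
  "toe_right": [0.189, -0.117, 0.0567]
}
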