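{
  "roberts2016": {
    "w0am": -2.27e-4, "w1am": -6.40e-7, "w2am": 1.61e-6, "w3am": 1.43e-4,
    "w4am": 18.2,
    "w0sl": 0.979, "w1sl": 3.45e-4, "w2sl": 1.07e-2, "w3sl": -0.146,
    "w4sl": -6.97e-5
  },
  "swarm_initial_level": {
    "w0am": -1300, "w1am": 105, "w2am": -276, "w3am": 416, "w4am": -7.39e-3,
    "w0sl": 870, "w1sl": -124, "w2sl": 316, "w3sl": 55.1, "w4sl": -7.01e-3
  },
  "swarm_initial_uphill": {
    "w0am": -3270, "w1am": 128, "w2am": -112, "w3am": -1340, "w4am": -5.52e-3,
    "w0sl": 469, "w1sl": -1.84, "w2sl": -233, "w3sl": 2710, "w4sl": -5.91e-3
  },
  "swarm_initial_downhill": {
    "w0am": -2640, "w1am": 70.5, "w2am": -113, "w3am": 376, "w4am": -5.55e-3,
    "w0sl": 1060, "w1sl": 85.2, "w2sl": -293, "w3sl": -41.0, "w4sl": -7.44e-3
  },
  "level": {
    "w0am": 4.49, "w1am": 1.35e-2, "w2am": -4.87e-2, "w3am": -1.39,
    "w4am": -6.64e-4,
    "w0sl": -1.46, "w1sl": -1.44e-2, "w2sl": 3.55e-3, "w3sl": 1.75,
    "w4sl": 2.32e-3
  },
  "uphill": {
    "w0am": 9.31, "w1am": -1.64e-2, "w2am": -0.106, "w3am": -2.10,
    "w4am": 7.68e-4,
    "w0sl": -9.03, "w1sl": 3.95e-2, "w2sl": 0.200, "w3sl": 2.11,
    "w4sl": -2.24e-3
  },
  "downhill": {
    "w0am": -0.894, "w1am": -4.87e-3, "w2am": -8.82e-3, "w3am": 0.877,
    "w4am": 3.02e-2,
    "w0sl": 1.97, "w1sl": 4.37e-4, "w2sl": 4.67e-2, "w3sl": -0.976,
    "w4sl": -1.17e-3
  }
}
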