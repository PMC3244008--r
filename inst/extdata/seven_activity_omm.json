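{
  "type": "omm",
  "labels": ["lying", "cycling", "climbing", "walking", "running", "sitting", "standing"],
  "prior": [0.14094368456068496, 0.079728614539650799, 0.034868446604556999, 0.29178982754137739, 0.01843536642661598, 0.2716146478024748, 0.1626194125246391],
  "tpm": [
    [0.94999999999999996, 0, 0, 0, 0, 0.01, 0.040000000000000001],
    [0.0001, 0.89990000000000003, 0, 0.040000000000000001, 0, 0.01, 0.050000000000000003],
    [0.0001, 0, 0.61990000000000001, 0.25, 0.01, 0.02, 0.10000000000000001],
    [0.0001, 0.01, 0.029999999999999999, 0.79990000000000006, 0.02, 0.070000000000000007, 0.070000000000000007],
    [0.0001, 0.01, 0.01, 0.34999999999999998, 0.39989999999999998, 0.01, 0.22],
    [0.019801980198019802, 0, 0.0099009900990099011, 0.039603960396039604, 0, 0.84158415841584155, 0.089108910891089105],
    [0.01, 0.029999999999999999, 0.01, 0.17999999999999999, 0.029999999999999999, 0.12, 0.62]
  ]
}
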