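# lens=example_center_near
# base_power_D=-3
# addition_D=2.5
radius_mm,power_D
          0,       -0.5
       0.25,       -0.5
        0.5,       -0.5
       0.75,       -0.5
          1,       -0.5
       1.25,       -0.5
        1.5,      -1.75
       1.75,         -3
          2,         -3
       2.25,         -3
        2.5,         -3
       2.75,         -3
          3,         -3
       3.25,         -3
        3.5,         -3
       3.75,         -3
          4,         -3
       4.25,         -3
        4.5,         -3
       4.75,         -3
          5,         -3
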