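#name=archaea_core_53
arc_core_001
arc_core_002
arc_core_003
arc_core_004
arc_core_005
arc_core_006
arc_core_007
arc_core_008
arc_core_009
arc_core_010
arc_core_011
arc_core_012
arc_core_013
arc_core_014
arc_core_015
arc_core_016
arc_core_017
arc_core_018
arc_core_019
arc_core_020
arc_core_021
arc_core_022
arc_core_023
arc_core_024
arc_core_025
arc_core_026
arc_core_027
arc_core_028
arc_core_029
arc_core_030
arc_core_031
arc_core_032
arc_core_033
arc_core_034
arc_core_035
arc_core_036
arc_core_037
arc_core_038
arc_core_039
arc_core_040
arc_core_041
arc_core_042
arc_core_043
arc_core_044
arc_core_045
arc_core_046
arc_core_047
arc_core_048
arc_core_049
arc_core_050
arc_core_051
arc_core_052
arc_core_053
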