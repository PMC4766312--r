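#name=bacteria_essential_112
bac_essential_001
bac_essential_002
bac_essential_003
bac_essential_004
bac_essential_005
bac_essential_006
bac_essential_007
bac_essential_008
bac_essential_009
bac_essential_010
bac_essential_011
bac_essential_012
bac_essential_013
bac_essential_014
bac_essential_015
bac_essential_016
bac_essential_017
bac_essential_018
bac_essential_019
bac_essential_020
bac_essential_021
bac_essential_022
bac_essential_023
bac_essential_024
bac_essential_025
bac_essential_026
bac_essential_027
bac_essential_028
bac_essential_029
bac_essential_030
bac_essential_031
bac_essential_032
bac_essential_033
bac_essential_034
bac_essential_035
bac_essential_036
bac_essential_037
bac_essential_038
bac_essential_039
bac_essential_040
bac_essential_041
bac_essential_042
bac_essential_043
bac_essential_044
bac_essential_045
bac_essential_046
bac_essential_047
bac_essential_048
bac_essential_049
bac_essential_050
bac_essential_051
bac_essential_052
bac_essential_053
bac_essential_054
bac_essential_055
bac_essential_056
bac_essential_057
bac_essential_058
bac_essential_059
bac_essential_060
bac_essential_061
bac_essential_062
bac_essential_063
bac_essential_064
bac_essential_065
bac_essential_066
bac_essential_067
bac_essential_068
bac_essential_069
bac_essential_070
bac_essential_071
bac_essential_072
bac_essential_073
bac_essential_074
bac_essential_075
bac_essential_076
bac_essential_077
bac_essential_078
bac_essential_079
bac_essential_080
bac_essential_081
bac_essential_082
bac_essential_083
bac_essential_084
bac_essential_085
bac_essential_086
bac_essential_087
bac_essential_088
bac_essential_089
bac_essential_090
bac_essential_091
bac_essential_092
bac_essential_093
bac_essential_094
bac_essential_095
bac_essential_096
bac_essential_097
bac_essential_098
bac_essential_099
bac_essential_100
bac_essential_101
bac_essential_102
bac_essential_103
bac_essential_104
bac_essential_105
bac_essential_106
bac_essential_107
bac_essential_108
bac_essential_109
bac_essential_110
bac_essential_111
bac_essential_112
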