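# Placeholder outgroup leaf ids (synthetic stand-ins for the dinoflagellate
# outgroup accession set; real accessions are not bundled).
synthetic_outgroup_ibp_001
synthetic_outgroup_ibp_002
synthetic_outgroup_ibp_003
synthetic_outgroup_ibp_004
synthetic_outgroup_ibp_005
synthetic_outgroup_ibp_006
synthetic_outgroup_ibp_007
synthetic_outgroup_ibp_008
synthetic_outgroup_ibp_009
synthetic_outgroup_ibp_010
synthetic_outgroup_ibp_011
synthetic_outgroup_ibp_012
synthetic_outgroup_ibp_013
synthetic_outgroup_ibp_014
synthetic_outgroup_ibp_015
synthetic_outgroup_ibp_016
synthetic_outgroup_ibp_017
synthetic_outgroup_ibp_018
synthetic_outgroup_ibp_019
synthetic_outgroup_ibp_020
synthetic_outgroup_ibp_021
synthetic_outgroup_ibp_022
synthetic_outgroup_ibp_023
synthetic_outgroup_ibp_024
synthetic_outgroup_ibp_025
synthetic_outgroup_ibp_026
synthetic_outgroup_ibp_027
synthetic_outgroup_ibp_028
synthetic_outgroup_ibp_029
synthetic_outgroup_ibp_030
synthetic_outgroup_ibp_031
synthetic_outgroup_ibp_032
synthetic_outgroup_ibp_033
synthetic_outgroup_ibp_034
synthetic_outgroup_ibp_035
synthetic_outgroup_ibp_036
synthetic_outgroup_ibp_037
synthetic_outgroup_ibp_038
synthetic_outgroup_ibp_039
synthetic_outgroup_ibp_040
synthetic_outgroup_ibp_041
synthetic_outgroup_ibp_042
synthetic_outgroup_ibp_043
synthetic_outgroup_ibp_044
synthetic_outgroup_ibp_045
synthetic_outgroup_ibp_046
synthetic_outgroup_ibp_047
synthetic_outgroup_ibp_048
synthetic_outgroup_ibp_049
synthetic_outgroup_ibp_050
synthetic_outgroup_ibp_051
synthetic_outgroup_ibp_052
synthetic_outgroup_ibp_053
synthetic_outgroup_ibp_054
synthetic_outgroup_ibp_055
synthetic_outgroup_ibp_056
synthetic_outgroup_ibp_057
synthetic_outgroup_ibp_058
synthetic_outgroup_ibp_059
synthetic_outgroup_ibp_060
synthetic_outgroup_ibp_061
synthetic_outgroup_ibp_062
synthetic_outgroup_ibp_063
synthetic_outgroup_ibp_064
synthetic_outgroup_ibp_065
synthetic_outgroup_ibp_066
synthetic_outgroup_ibp_067
synthetic_outgroup_ibp_068
synthetic_outgroup_ibp_069
synthetic_outgroup_ibp_070
synthetic_outgroup_ibp_071
synthetic_outgroup_ibp_072
synthetic_outgroup_ibp_073
synthetic_outgroup_ibp_074
synthetic_outgroup_ibp_075
synthetic_outgroup_ibp_076
synthetic_outgroup_ibp_077
synthetic_outgroup_ibp_078
synthetic_outgroup_ibp_079
synthetic_outgroup_ibp_080
synthetic_outgroup_ibp_081
synthetic_outgroup_ibp_082
synthetic_outgroup_ibp_083
synthetic_outgroup_ibp_084
synthetic_outgroup_ibp_085
synthetic_outgroup_ibp_086
synthetic_outgroup_ibp_087
synthetic_outgroup_ibp_088
synthetic_outgroup_ibp_089
synthetic_outgroup_ibp_090
synthetic_outgroup_ibp_091
synthetic_outgroup_ibp_092
synthetic_outgroup_ibp_093
synthetic_outgroup_ibp_094
synthetic_outgroup_ibp_095
synthetic_outgroup_ibp_096
synthetic_outgroup_ibp_097
synthetic_outgroup_ibp_098
synthetic_outgroup_ibp_099
synthetic_outgroup_ibp_100
synthetic_outgroup_ibp_101
synthetic_outgroup_ibp_102
synthetic_outgroup_ibp_103
synthetic_outgroup_ibp_104
synthetic_outgroup_ibp_105
synthetic_outgroup_ibp_106
synthetic_outgroup_ibp_107
synthetic_outgroup_ibp_108
synthetic_outgroup_ibp_109
synthetic_outgroup_ibp_110
synthetic_outgroup_ibp_111
synthetic_outgroup_ibp_112
synthetic_outgroup_ibp_113
synthetic_outgroup_ibp_114
synthetic_outgroup_ibp_115
synthetic_outgroup_ibp_116
synthetic_outgroup_ibp_117
synthetic_outgroup_ibp_118
synthetic_outgroup_ibp_119
synthetic_outgroup_ibp_120
synthetic_outgroup_ibp_121
synthetic_outgroup_ibp_122
synthetic_outgroup_ibp_123
synthetic_outgroup_ibp_124
synthetic_outgroup_ibp_125
synthetic_outgroup_ibp_126
synthetic_outgroup_ibp_127
synthetic_outgroup_ibp_128
synthetic_outgroup_ibp_129
synthetic_outgroup_ibp_130
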