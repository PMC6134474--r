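set_name	members
subgroup_A_pair	1168,1202
s16_A_pair	1202,1076
outside_pair	1010,1043
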