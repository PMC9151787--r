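song_type,theme_id,population,n_phrase_reps
Purple,1,EA,138
Purple,2,EA,126
Purple,3,EA,90
Purple,4,EA,114
Purple,5,EA,99
Purple,1,NC,125
Purple,2,NC,107
Purple,3,NC,147
Purple,4,NC,138
Purple,5,NC,136
LightPurple,6,EA,104
LightPurple,7,NC,24
LightPurple,8,NC,26
LightPurple,9,EA,113
LightPurple,10,EA,96
LightPurple,11,EA,125
LightPurple,12,EA,114
LightPurple,13,EA,126
LightPurple,9,NC,135
LightPurple,10,NC,109
LightPurple,11,NC,115
LightPurple,12,NC,139
LightPurple,13,NC,136
Brown,14,EA,92
Brown,15,EA,130
Brown,16,EA,114
Brown,17,EA,116
Brown,18,EA,125
Brown,14,NC,126
Brown,15,NC,120
Brown,16,NC,134
Brown,17,NC,94
Brown,18,NC,109
Brown,19,NC,28
LightBrown,20,EA,123
LightBrown,21,EA,117
LightBrown,22,EA,129
LightBrown,23,EA,92
LightBrown,24,EA,147
LightBrown,20,NC,122
LightBrown,21,NC,131
LightBrown,22,NC,113
LightBrown,23,NC,119
LightBrown,24,NC,132
LightBrown,25,NC,22
LightBrown,26,NC,30
LightBrown,27,NC,26
LightBrown,28,EA,78
Teal,29,EA,104
Teal,30,EA,111
Teal,31,EA,147
Teal,32,EA,97
Teal,33,EA,125
Teal,29,NC,93
Teal,30,NC,111
Teal,31,NC,107
Teal,32,NC,134
Teal,33,NC,117
Teal,34,NC,25
Orange,35,EA,94
Orange,36,EA,93
Orange,37,EA,123
Orange,38,EA,145
Orange,35,NC,139
Orange,36,NC,124
Orange,37,NC,113
Orange,38,NC,112
Orange,39,NC,24
Orange,40,NC,27
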