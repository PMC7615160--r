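dimension,level,decrement
mobility,1,0
mobility,2,0.051
mobility,3,0.063
mobility,4,0.212
mobility,5,0.275
self_care,1,0
self_care,2,0.057
self_care,3,0.076
self_care,4,0.181
self_care,5,0.217
usual_activities,1,0
usual_activities,2,0.051
usual_activities,3,0.067
usual_activities,4,0.174
usual_activities,5,0.19
pain_discomfort,1,0
pain_discomfort,2,0.06
pain_discomfort,3,0.075
pain_discomfort,4,0.276
pain_discomfort,5,0.341
anxiety_depression,1,0
anxiety_depression,2,0.079
anxiety_depression,3,0.104
anxiety_depression,4,0.296
anxiety_depression,5,0.301
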