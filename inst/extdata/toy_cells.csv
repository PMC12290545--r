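subject_id,condition,position_class,mean_accuracy,mean_bias,n_trials_retained
T1,sham,boundary,10,-2,9
T1,sham,non_boundary,14,-6,9
T1,slow_3hz,boundary,8,-1,9
T1,slow_3hz,non_boundary,11,-4,9
T1,fast_8hz,boundary,9,-1,9
T1,fast_8hz,non_boundary,13,-3,9
T2,sham,boundary,12,-3,9
T2,sham,non_boundary,16,-7,9
T2,slow_3hz,boundary,9,-2,9
T2,slow_3hz,non_boundary,12,-5,9
T2,fast_8hz,boundary,11,-2,9
T2,fast_8hz,non_boundary,14,-4,9
T3,sham,boundary,11,-2,9
T3,sham,non_boundary,18,-8,9
T3,slow_3hz,boundary,10,-2,9
T3,slow_3hz,non_boundary,13,-5,9
T3,fast_8hz,boundary,10,-1,9
T3,fast_8hz,non_boundary,15,-5,9
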