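activity_id,label,met
walk_commute,Walking to work or shops,3.5
cycle_commute,Cycling to work or shops,4.0
walk_leisure,Leisure-time walking,3.3
cycle_leisure,Leisure-time cycling,4.0
gardening,Gardening,3.8
odd_jobs,Odd jobs around the house,4.5
sports_moderate,Moderate-intensity sports,5.0
sports_vigorous,Vigorous-intensity sports,8.0
household_heavy,Heavy household work,3.0
household_light,Light household work,2.3
standing_light,Light standing activities,2.0
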