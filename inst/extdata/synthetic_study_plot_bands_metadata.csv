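"sample_id","role","species","plot_id","trophic_level","quantity"
"M01","plot",NA,"M01","minerotrophic","SIMULATED"
"M02","plot",NA,"M02","minerotrophic","SIMULATED"
"M03","plot",NA,"M03","minerotrophic","SIMULATED"
"M04","plot",NA,"M04","minerotrophic","SIMULATED"
"M05","plot",NA,"M05","minerotrophic","SIMULATED"
"M06","plot",NA,"M06","minerotrophic","SIMULATED"
"O01","plot",NA,"O01","ombrotrophic","SIMULATED"
"O02","plot",NA,"O02","ombrotrophic","SIMULATED"
"O03","plot",NA,"O03","ombrotrophic","SIMULATED"
"O04","plot",NA,"O04","ombrotrophic","SIMULATED"
"O05","plot",NA,"O05","ombrotrophic","SIMULATED"
"O06","plot",NA,"O06","ombrotrophic","SIMULATED"
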