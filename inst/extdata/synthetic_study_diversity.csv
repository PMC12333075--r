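"plot_id","trophic_level","richness","shannon","simpson"
"M01","minerotrophic",5,1.19325475862451,0.630220051560232
"M02","minerotrophic",6,1.34261754686696,0.68195655222739
"M03","minerotrophic",5,0.887766192131695,0.480373000080247
"M04","minerotrophic",4,1.19327355694615,0.641175322694806
"M05","minerotrophic",5,1.120777986707,0.61637427586896
"M06","minerotrophic",4,1.07892440515689,0.5944327920016
"O01","ombrotrophic",4,1.22265781585834,0.68712199692752
"O02","ombrotrophic",4,1.10812499486366,0.624089584039675
"O03","ombrotrophic",4,1.03475968701897,0.564640127015701
"O04","ombrotrophic",4,1.23535482656486,0.671904305897609
"O05","ombrotrophic",4,0.97519835732279,0.554853266022443
"O06","ombrotrophic",5,1.08555986444748,0.577319827029863
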