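"plot_id","trophic_level","species","cover_pct"
"M01","minerotrophic","Comarum palustre",12.7285417646326
"M01","minerotrophic","Litter",52.4826490997655
"M01","minerotrophic","Menyanthes trifoliata",27.3710357482169
"M01","minerotrophic","Sphagnum angustifolium",2.18082035496618
"M01","minerotrophic","Sphagnum fallax",5.2369530324188
"M02","minerotrophic","Comarum palustre",0.806444369891841
"M02","minerotrophic","Filipendula ulmaria",10.8282143307021
"M02","minerotrophic","Litter",48.2825391118603
"M02","minerotrophic","Menyanthes trifoliata",2.16693570521116
"M02","minerotrophic","Sphagnum angustifolium",20.9363468254313
"M02","minerotrophic","Sphagnum fallax",16.9795196569034
"M03","minerotrophic","Comarum palustre",5.73248860655962
"M03","minerotrophic","Filipendula ulmaria",0.892608932641029
"M03","minerotrophic","Litter",23.4997390739259
"M03","minerotrophic","Sphagnum angustifolium",2.00503808416755
"M03","minerotrophic","Sphagnum fallax",67.8701253027059
"M04","minerotrophic","Filipendula ulmaria",20.7993263965132
"M04","minerotrophic","Litter",52.9363194390634
"M04","minerotrophic","Menyanthes trifoliata",15.1904201329176
"M04","minerotrophic","Sphagnum fallax",11.0739340315059
"M05","minerotrophic","Comarum palustre",7.30249286534081
"M05","minerotrophic","Filipendula ulmaria",36.9180091443788
"M05","minerotrophic","Litter",48.8036414609187
"M05","minerotrophic","Sphagnum angustifolium",6.12086702893207
"M05","minerotrophic","Sphagnum fallax",0.854989500429634
"M06","minerotrophic","Litter",5.72769607852909
"M06","minerotrophic","Menyanthes trifoliata",28.078064361334
"M06","minerotrophic","Sphagnum angustifolium",55.9406002927266
"M06","minerotrophic","Sphagnum fallax",10.2536392674103
"O01","ombrotrophic","Calluna vulgaris",24.9803548262241
"O01","ombrotrophic","Litter",36.6800274391947
"O01","ombrotrophic","Sphagnum fuscum",33.7364547839688
"O01","ombrotrophic","Sphagnum rubellum",4.60316295061234
"O02","ombrotrophic","Calluna vulgaris",12.4779618457198
"O02","ombrotrophic","Litter",49.1593008003267
"O02","ombrotrophic","Sphagnum cuspidatum",4.16607707210263
"O02","ombrotrophic","Sphagnum fuscum",34.1966602818508
"O03","ombrotrophic","Calluna vulgaris",23.4829625553575
"O03","ombrotrophic","Litter",60.390760461936
"O03","ombrotrophic","Sphagnum cuspidatum",4.52217494775044
"O03","ombrotrophic","Sphagnum rubellum",11.604102034956
"O04","ombrotrophic","Calluna vulgaris",47.2261247950618
"O04","ombrotrophic","Litter",17.6170821388387
"O04","ombrotrophic","Rubus chamaemorus",9.75891939476554
"O04","ombrotrophic","Sphagnum rubellum",25.3978736713339
"O05","ombrotrophic","Calluna vulgaris",3.12679644342185
"O05","ombrotrophic","Litter",58.4166585855303
"O05","ombrotrophic","Sphagnum fuscum",7.19225242232516
"O05","ombrotrophic","Sphagnum rubellum",31.2642925487227
"O06","ombrotrophic","Calluna vulgaris",26.3173102610354
"O06","ombrotrophic","Litter",5.22507028707368
"O06","ombrotrophic","Sphagnum cuspidatum",8.60456651869139
"O06","ombrotrophic","Sphagnum fuscum",1.27633438055841
"O06","ombrotrophic","Sphagnum rubellum",58.5767185526411
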