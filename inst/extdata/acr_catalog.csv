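# acrtools ACR catalog, schema v1
number,accession,genus,species,strain,genus_classified,species_classified,strain_tag,transcript_name,source_project,spectral_max,abbreviation,alias,previously_known
1,KX879674,Geminigera,cryophila,CCMP2564,TRUE,TRUE,,CAMNT 0021181457,MMETSP,495,GcACR_457,,FALSE
2,KX879675,Geminigera,cryophila,CCMP2564,TRUE,TRUE,,CAMNT 0021207145,MMETSP,485,GcACR_145,,FALSE
3,KX879676,Geminigera,cryophila,CCMP2564,TRUE,TRUE,,CAMNT 0021218439,MMETSP,515,GcACR_439,,FALSE
4,KX879677,Geminigera,,Caron Lab Isolate,TRUE,FALSE,1,CAMNT 0013945203,MMETSP,475,G1ACR_203,,FALSE
5,KX879678,Geminigera,,Caron Lab Isolate,TRUE,FALSE,1,CAMNT 0013979243,MMETSP,,G1ACR_243,,FALSE
6,KP171708,Guillardia,theta,CCMP2712,TRUE,TRUE,,known previously,,515,GtACR1,,TRUE
7,KP171709,Guillardia,theta,CCMP2712,TRUE,TRUE,,known previously,,470,GtACR2,,TRUE
8,KF992074,Proteomonas,sulcata,CCMP704,TRUE,TRUE,,known previously,,520,PsuACR1,,TRUE
9,KX879679,Proteomonas,sulcata,CCMP704,TRUE,TRUE,,CAMNT 0026648973,MMETSP,515,PsuACR_973,ZipACR,FALSE
10,KX879680,Proteomonas,sulcata,CCMP704,TRUE,TRUE,,CAMNT 0026650433,MMETSP,525,PsuACR_433,,FALSE
11,KX879681,Proteomonas,sulcata,CCMP704,TRUE,TRUE,,IRZA-2061003,1KP,,PsuACR_003,,FALSE
12,KX879682,Rhodomonas,lens,RHODO,TRUE,TRUE,,CAMNT 0019228477,MMETSP,445,RlACR_477,,FALSE
13,KX879683,Rhodomonas,salina,CCMP1319,TRUE,TRUE,,CAMNT 0012794995,MMETSP,515,RsACR_995,,FALSE
14,KX879684,Rhodomonas,,CCMP768,TRUE,FALSE,1,CAMNT 0042060367,MMETSP,515,R1ACR_367,,FALSE
15,KX879685,Rhodomonas,,CCMP768,TRUE,FALSE,1,CAMNT 0042061877,MMETSP,520,R1ACR_877,,FALSE
16,KX879686,Rhodomonas,,CCMP768,TRUE,FALSE,1,CAMNT 0042066447,MMETSP,515,R1ACR_447,,FALSE
17,KX879687,Rhodomonas,,CCMP768,TRUE,FALSE,1,CAMNT 0049477741,MMETSP,515,R1ACR_741,,FALSE
18,KX879688,Rhodomonas,,CCMP768,TRUE,FALSE,1,CAMNT 0049533799,MMETSP,520,R1ACR_799,,FALSE
19,KX879689,Rhodomonas,,CCAC1630,TRUE,FALSE,2,IAYV-2004853,1KP,515,R2ACR_853,,FALSE
20,KX879690,Rhodomonas,,CCAC1630,TRUE,FALSE,2,IAYV-2007142,1KP,490,R2ACR_142,,FALSE
21,KX879691,,,CCMP2293,FALSE,FALSE,1,CAMNT 0022112887,MMETSP,535,C1ACR_887,,FALSE
22,KX879692,,,CCMP2293,FALSE,FALSE,1,CAMNT 0022176023,MMETSP,445,C1ACR_023,,FALSE
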