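experiment_id,agent_a,dose_a,agent_b,dose_b,replicate,is_control,signal
exp01,A,0,NA,0,1,TRUE,1.0713877772341518
exp01,A,0,NA,0,2,TRUE,0.9266590152918267
exp01,A,0,NA,0,3,TRUE,0.9881658310698552
exp01,A,0,NA,0,4,TRUE,0.990333101750125
exp01,A,1.25,NA,0,1,FALSE,0.9685643573900119
exp01,A,1.25,NA,0,2,FALSE,1.011813506728327
exp01,A,2.5,NA,0,1,FALSE,0.909414407343255
exp01,A,2.5,NA,0,2,FALSE,0.9512639745432201
exp01,A,5,NA,0,1,FALSE,0.8124307686925442
exp01,A,5,NA,0,2,FALSE,0.846958651502508
exp01,A,10,NA,0,1,FALSE,0.5154697463906492
exp01,A,10,NA,0,2,FALSE,0.49718164213114463
exp01,A,20,NA,0,1,FALSE,0.2091702828951271
exp01,A,20,NA,0,2,FALSE,0.19776740635372733
exp01,A,40,NA,0,1,FALSE,0.06037190617315778
exp01,A,40,NA,0,2,FALSE,0.05648575166054397
exp02,A,0,NA,0,1,TRUE,1.0233619480882756
exp02,A,0,NA,0,2,TRUE,1.0249067782217958
exp02,A,0,NA,0,3,TRUE,1.0447468600270198
exp02,A,0,NA,0,4,TRUE,1.0139575998206871
exp02,A,1.25,NA,0,1,FALSE,0.9427813050912561
exp02,A,1.25,NA,0,2,FALSE,0.9874936860479755
exp02,A,2.5,NA,0,1,FALSE,0.9026978656058372
exp02,A,2.5,NA,0,2,FALSE,0.8446913969110762
exp02,A,5,NA,0,1,FALSE,0.7934497733623431
exp02,A,5,NA,0,2,FALSE,0.8283408841662552
exp02,A,10,NA,0,1,FALSE,0.4933004863454596
exp02,A,10,NA,0,2,FALSE,0.46340195600322454
exp02,A,20,NA,0,1,FALSE,0.20744435822875315
exp02,A,20,NA,0,2,FALSE,0.18589609818994798
exp02,A,40,NA,0,1,FALSE,0.060197257664750745
exp02,A,40,NA,0,2,FALSE,0.05847258791854635
exp01,A,0,A2,0,1,TRUE,1.0713877772341518
exp01,A,0,A2,0,2,TRUE,0.9266590152918267
exp01,A,0,A2,0,3,TRUE,0.9881658310698552
exp01,A,0,A2,0,4,TRUE,0.990333101750125
exp01,A,1.25,A2,1.25,1,FALSE,0.925833576916911
exp01,A,1.25,A2,1.25,2,FALSE,0.9671746755491233
exp01,A,2.5,A2,2.5,1,FALSE,0.7730022462417668
exp01,A,2.5,A2,2.5,2,FALSE,0.8085743783617372
exp01,A,5,A2,5,1,FALSE,0.5077692304328398
exp01,A,5,A2,5,2,FALSE,0.5293491571890673
exp01,A,10,A2,10,1,FALSE,0.20618789855630407
exp01,A,10,A2,10,2,FALSE,0.19887265685250063
exp01,A,20,A2,20,1,FALSE,0.061520671439554836
exp01,A,20,A2,20,2,FALSE,0.05816688422150636
exp01,A,40,A2,40,1,FALSE,0.01578957546068565
exp01,A,40,A2,40,2,FALSE,0.014773196588155004
exp02,A,0,A2,0,1,TRUE,1.0233619480882756
exp02,A,0,A2,0,2,TRUE,1.0249067782217958
exp02,A,0,A2,0,3,TRUE,1.0447468600270198
exp02,A,0,A2,0,4,TRUE,1.0139575998206871
exp02,A,1.25,A2,1.25,1,FALSE,0.9011880122195713
exp02,A,1.25,A2,1.25,2,FALSE,0.9439277881340818
exp02,A,2.5,A2,2.5,1,FALSE,0.7672931857649616
exp02,A,2.5,A2,2.5,2,FALSE,0.7179876873744148
exp02,A,5,A2,5,1,FALSE,0.4959061083514642
exp02,A,5,A2,5,2,FALSE,0.5177130526039092
exp02,A,10,A2,10,1,FALSE,0.1973201945382263
exp02,A,10,A2,10,2,FALSE,0.1853607824013297
exp02,A,20,A2,20,1,FALSE,0.061013046537681706
exp02,A,20,A2,20,2,FALSE,0.054675322996876066
exp02,A,40,A2,40,1,FALSE,0.015743898158486844
exp02,A,40,A2,40,2,FALSE,0.01529283068640223
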