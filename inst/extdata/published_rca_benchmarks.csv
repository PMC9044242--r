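dataset,threshold,acc,se,sp,f1,g,mcc,auc
DRIVE,150,0.9563,0.8281,0.9771,0.8289,0.8995,0.8056,0.9811
STARE,163,0.9691,0.8612,0.9823,0.8501,0.9198,0.8332,0.9892
CHASE,161,0.9682,0.8520,0.9800,0.8375,0.9138,0.8195,0.9879
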