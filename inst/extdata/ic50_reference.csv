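toxin,channel,ic50,ic50_se,h,h_se
MeKTx13-3,Kv1.1,1.9,0.2,0.9,0.1
MeKTx13-3,Kv1.2,105.9,14.6,1.3,0.3
MeKTx13-3,Kv1.3,8.9,0.9,0.8,0.2
MeKTx13-3,Kv1.4,NA,NA,NA,NA
MeKTx13-3,Kv1.5,NA,NA,NA,NA
MeKTx13-3,Kv1.6,63.4,4.5,1.0,0.1
MeKTx13-3_AAAR,Kv1.1,541.5,48.6,0.7,0.1
MeKTx13-3_AAAR,Kv1.2,208.2,15.2,1.2,0.1
MeKTx13-3_AAAR,Kv1.3,9.1,0.4,0.7,0.2
MeKTx13-3_AAAR,Kv1.4,NA,NA,NA,NA
MeKTx13-3_AAAR,Kv1.5,NA,NA,NA,NA
MeKTx13-3_AAAR,Kv1.6,1522.3,183.4,1.4,0.3
MeKTx13-3_recombinant,Kv1.1,6.7,2.7,NA,NA
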