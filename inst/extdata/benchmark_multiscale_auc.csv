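# Published benchmark: test AUC of the ten retained multivariate models in
# their multi-scale form, for two montane study areas (A and B).
area,model,auc_multiscale
A,1,0.853
A,2,0.856
A,3,0.851
A,4,0.856
A,5,0.845
A,6,0.864
A,7,0.859
A,8,0.848
A,9,0.849
A,10,0.842
B,1,0.975
B,2,0.971
B,3,0.967
B,4,0.970
B,5,0.971
B,6,0.972
B,7,0.969
B,8,0.963
B,9,0.966
B,10,0.967
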