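# Published correction-performance benchmark for real occurrence datasets in
# two montane study areas (A and B). Columns: per-correction averages over
# the top five models (n retained points, test AUC, AUC_diff, MTSS threshold,
# MTSS omission rate) and Schoener's D overlap of the corrected ensemble
# with the unbiased full-random reference ensemble.
area,method,radius,n,auc,auc_diff,mtss,mtss_omission,d
A,RAW,NA,393,0.858,0.008,0.398,0.271,0.810
A,SR,1200,219,0.837,0.009,0.415,0.272,0.841
A,SR,2400,158,0.819,0.009,0.424,0.290,0.858
A,SR,4800,103,0.766,0.023,0.443,0.421,0.892
A,SR,9600,65,0.756,0.034,0.453,0.407,0.921
A,GK,1200,393,0.860,0.009,0.417,0.268,0.822
A,GK,2400,393,0.862,0.009,0.429,0.262,0.835
A,GK,4800,393,0.863,0.009,0.448,0.255,0.860
A,GK,9600,393,0.855,0.009,0.471,0.290,0.892
B,RAW,NA,220,0.972,0.001,0.194,0.085,0.572
B,SR,1200,79,0.958,0.004,0.188,0.126,0.667
B,SR,2400,49,0.943,0.007,0.212,0.115,0.780
B,SR,4800,28,0.905,0.015,0.331,0.190,0.844
B,SR,9600,19,0.904,0.015,0.316,0.150,0.759
B,GK,1200,220,0.971,0.001,0.263,0.085,0.646
B,GK,2400,220,0.971,0.001,0.321,0.085,0.699
B,GK,4800,220,0.971,0.002,0.432,0.082,0.763
B,GK,9600,220,0.968,0.002,0.501,0.081,0.768
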