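# Machine-readable transcription of the study's printed per-method
# significant links (three thalamic seeds vs the basal-ganglia motor
# circuit, resting and motor tasks; partial correlation = PC, Gaussian
# process / distance correlation = GPDC, kNN conditional mutual
# information = CMIknn).
# direction: u = undirected/undefined, c = seed drives partner,
# r = partner drives seed. value: printed normalized statistic
# (sign kept where the source prints one; NA where unrecoverable).
seed,task,method,partner,lag,direction,value
M-Tal,resting,PC,S1,0,u,-0.306
M-Tal,resting,PC,Cau,0,u,0.630
M-Tal,resting,PC,Put,0,u,1.000
M-Tal,resting,PC,GPe,0,u,0.562
M-Tal,resting,PC,STN,0,u,0.205
M-Tal,resting,PC,Put,1,c,-0.148
M-Tal,resting,PC,Cau,2,c,-0.391
M-Tal,resting,PC,Cau,2,r,-0.529
M-Tal,resting,GPDC,M1,0,u,0.148
M-Tal,resting,GPDC,S1,0,u,0.148
M-Tal,resting,GPDC,Cau,0,u,0.519
M-Tal,resting,GPDC,Put,0,u,0.870
M-Tal,resting,GPDC,GPe,0,u,0.111
M-Tal,resting,GPDC,Put,1,c,0.037
M-Tal,resting,GPDC,STN,1,r,0.056
M-Tal,resting,GPDC,Cau,2,r,0.333
M-Tal,resting,GPDC,SN,2,r,0.056
M-Tal,resting,CMIknn,M1,0,c,0.188
M-Tal,resting,CMIknn,S1,0,c,0.438
M-Tal,resting,CMIknn,Cau,0,u,0.375
M-Tal,resting,CMIknn,Put,0,u,0.688
M-Tal,resting,CMIknn,GPe,0,u,0.313
M-Tal,resting,CMIknn,STN,0,u,0.313
M-Tal,resting,CMIknn,SN,0,u,0.375
M-Tal,resting,CMIknn,Cau,2,c,0.188
M-Tal,motor,PC,M1,0,u,-0.364
M-Tal,motor,PC,Cau,0,u,0.791
M-Tal,motor,PC,Put,0,u,0.986
M-Tal,motor,PC,GPe,0,u,0.208
M-Tal,motor,PC,STN,0,u,0.205
M-Tal,motor,GPDC,M1,0,u,0.093
M-Tal,motor,GPDC,Cau,0,u,0.815
M-Tal,motor,GPDC,Put,0,u,0.981
M-Tal,motor,GPDC,GPe,0,u,0.407
M-Tal,motor,GPDC,STN,0,u,0.222
M-Tal,motor,GPDC,Cau,2,c,0.167
M-Tal,motor,GPDC,Cau,2,r,0.241
M-Tal,motor,GPDC,GPe,2,c,0.056
M-Tal,motor,CMIknn,M1,0,c,0.188
M-Tal,motor,CMIknn,Cau,0,u,0.313
M-Tal,motor,CMIknn,Put,0,u,0.500
M-Tal,motor,CMIknn,GPe,0,u,0.375
M-Tal,motor,CMIknn,STN,0,u,0.438
M-Tal,motor,CMIknn,Cau,2,c,0.188
IL-Tal,resting,PC,Cau,0,u,0.673
IL-Tal,resting,PC,Put,0,u,0.983
IL-Tal,resting,PC,GPe,0,u,0.505
IL-Tal,resting,PC,STN,0,u,0.632
IL-Tal,resting,GPDC,Cau,0,u,0.778
IL-Tal,resting,GPDC,Put,0,u,0.778
IL-Tal,resting,GPDC,GPe,0,u,0.029
IL-Tal,resting,GPDC,STN,0,u,0.010
IL-Tal,resting,GPDC,GPi,0,u,0.017
IL-Tal,resting,GPDC,GPe,2,c,0.037
IL-Tal,resting,CMIknn,Cau,0,u,0.375
IL-Tal,resting,CMIknn,Put,0,u,0.375
IL-Tal,resting,CMIknn,GPe,0,u,0.375
IL-Tal,resting,CMIknn,STN,0,u,0.250
IL-Tal,resting,CMIknn,GPi,0,u,0.438
IL-Tal,resting,CMIknn,SN,0,c,0.250
IL-Tal,motor,PC,Cau,0,u,0.761
IL-Tal,motor,PC,Put,0,u,0.909
IL-Tal,motor,PC,GPe,0,u,0.558
IL-Tal,motor,PC,STN,0,u,0.626
IL-Tal,motor,GPDC,Cau,0,u,0.500
IL-Tal,motor,GPDC,Put,0,u,0.722
IL-Tal,motor,GPDC,GPe,0,u,0.667
IL-Tal,motor,GPDC,STN,0,u,0.130
IL-Tal,motor,GPDC,GPi,0,u,0.444
IL-Tal,motor,GPDC,Cau,2,c,0.204
IL-Tal,motor,GPDC,GPe,2,c,0.056
IL-Tal,motor,GPDC,M1,2,c,0.056
IL-Tal,motor,GPDC,S1,2,c,0.056
IL-Tal,motor,CMIknn,Cau,0,u,0.375
IL-Tal,motor,CMIknn,Put,0,u,0.375
IL-Tal,motor,CMIknn,GPe,0,u,0.325
IL-Tal,motor,CMIknn,STN,0,u,0.313
IL-Tal,motor,CMIknn,GPi,0,u,0.313
MD-Tal,resting,PC,Put,0,u,0.777
MD-Tal,resting,PC,Cau,1,c,-0.347
MD-Tal,resting,GPDC,Cau,0,u,0.204
MD-Tal,resting,GPDC,Put,0,u,1.000
MD-Tal,resting,GPDC,GPe,0,u,0.093
MD-Tal,resting,GPDC,STN,0,u,0.056
MD-Tal,resting,GPDC,Cau,1,c,0.111
MD-Tal,resting,GPDC,Put,1,c,0.037
MD-Tal,resting,GPDC,GPe,1,c,0.056
MD-Tal,resting,GPDC,STN,1,r,0.037
MD-Tal,resting,GPDC,SN,1,r,0.185
MD-Tal,resting,GPDC,M1,2,r,0.074
MD-Tal,resting,CMIknn,Put,0,u,1.000
MD-Tal,resting,CMIknn,GPe,0,r,0.313
MD-Tal,resting,CMIknn,Cau,1,c,0.250
MD-Tal,motor,PC,Put,0,u,0.724
MD-Tal,motor,PC,GPe,1,c,0.222
MD-Tal,motor,GPDC,M1,0,u,0.074
MD-Tal,motor,GPDC,Cau,0,u,0.241
MD-Tal,motor,GPDC,Put,0,u,0.926
MD-Tal,motor,GPDC,GPe,0,u,0.037
MD-Tal,motor,GPDC,STN,0,u,0.056
MD-Tal,motor,GPDC,GPi,0,u,0.037
MD-Tal,motor,GPDC,SN,0,u,0.056
MD-Tal,motor,GPDC,Put,1,c,0.037
MD-Tal,motor,GPDC,GPe,1,c,0.019
MD-Tal,motor,GPDC,SN,1,r,0.074
MD-Tal,motor,GPDC,Cau,2,c,0.111
MD-Tal,motor,GPDC,Cau,2,r,0.111
MD-Tal,motor,GPDC,M1,2,r,0.111
MD-Tal,motor,CMIknn,S1,0,c,0.188
MD-Tal,motor,CMIknn,Put,0,u,0.563
MD-Tal,motor,CMIknn,Cau,2,c,0.250
MD-Tal,motor,CMIknn,SN,0,r,0.188
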