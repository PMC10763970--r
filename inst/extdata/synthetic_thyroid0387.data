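34.1,F,f,t,f,f,f,t,f,t,f,t,f,f,f,t,f,27.2,f,1.8,f,6.5,t,5.6,f,0.6,t,5.4,SVHC,F[000101]
6.2,M,f,f,f,t,f,t,f,t,f,f,t,f,f,f,f,8.7,f,19.0,f,?,f,7.0,t,?,f,0.4,SVI,-[000102]
10.7,M,t,f,f,f,f,t,f,t,t,f,f,t,f,f,f,3.4,f,14.1,t,?,t,14.6,f,0.4,f,5.1,other,G[000103]
13.2,F,t,f,f,f,f,f,f,f,t,t,f,f,f,f,f,16.0,f,36.4,f,4.7,f,15.8,f,?,t,8.4,STMW,K[000104]
3.0,F,f,f,t,f,t,f,f,f,f,f,f,t,f,f,f,14.2,t,2.4,f,2.4,t,?,f,?,f,24.6,SVI,I[000105]
2.7,M,f,f,t,f,f,t,f,f,f,t,f,f,f,f,f,43.3,f,3.0,f,2.7,f,17.4,t,6.1,f,?,SVHC,-[000106]
7.1,F,f,f,f,f,f,f,f,t,f,f,f,t,f,f,f,7.4,t,31.2,f,6.6,f,4.6,f,6.8,f,4.7,STMW,AK[000107]
?,F,f,f,f,f,f,t,t,f,f,f,t,f,t,f,t,32.5,f,4.5,f,2.0,f,11.0,f,5.6,f,33.6,SVHC,-[000108]
14.5,M,f,f,f,f,f,t,t,f,f,f,f,f,f,f,f,17.5,f,1.7,f,12.0,f,8.6,f,10.7,f,5.6,STMW,F[000109]
14.9,F,t,f,f,f,f,f,t,f,f,f,f,t,f,f,f,7.9,f,7.2,f,1.8,t,6.0,f,3.9,f,?,SVI,R[000110]
13.3,F,f,t,f,t,f,f,t,t,f,f,t,f,f,t,f,6.5,f,?,f,2.0,f,5.2,f,2.5,f,?,SVHC,-[000111]
12.4,F,f,f,f,f,f,f,f,t,f,f,f,f,f,f,f,0.4,f,6.7,f,16.3,f,2.4,f,3.7,t,7.1,STMW,G[000112]
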