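t_obs,event,x,z,c1
1.74,1,1,1,0.1
0.99,1,0,0,-0.1
0.41,1,0,0,-1.5
0.23,1,0,0,-2
1.51,1,0,0,2.5
3.94,1,1,1,0.9
3.21,1,1,0,1.3
4.54,1,1,1,-0.6
7.6,0,1,1,-1.6
5.58,1,0,0,-0.2
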